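make_cs <- function(...) {
  seqs <- c(...)
  clone_set("L", "M", "p1", sprintf("c%02d", seq_along(seqs)), seqs)
}

spectrum_of <- function(cs, min_minor = 1) {
  substitution_spectrum(call_all_sites(cs, min_minor), cs)
}

test_that("substitutions are typed per minor allele against the major base", {
  # 12 A + 3 G at one column: one transition, Ts/Tv undefined
  sp <- spectrum_of(make_cs(rep("A", 12), rep("G", 3)))
  expect_equal(unname(sp$pair_counts["A:G"]), 1)
  expect_equal(sp$ts_count, 1)
  expect_equal(sp$tv_count, 0)
  expect_true(is.na(sp$ts_tv_ratio))
  expect_equal(sp$snp_total, 1)

  # 3 transition + 3 transversion columns -> ratio 1.00
  seqs <- c("AAACCC", "AAACCC", "GGGAAA")
  sp2 <- spectrum_of(make_cs(seqs))
  expect_equal(sp2$ts_count, 3)
  expect_equal(sp2$tv_count, 3)
  expect_equal(sp2$ts_tv_ratio, 1)

  # triallelic column: major A, minors G and T
  sp3 <- spectrum_of(make_cs(rep("A", 8), rep("G", 4), rep("T", 3)))
  expect_equal(unname(sp3$pair_counts["A:G"]), 1)
  expect_equal(unname(sp3$pair_counts["A:T"]), 1)
  expect_equal(sp3$ts_count, 1)
  expect_equal(sp3$tv_count, 1)
  expect_equal(sp3$snp_total, 1)

  # major-allele tie broken by earliest clone: first clone carries C
  sp4 <- spectrum_of(make_cs(rep("C", 5), rep("T", 5)))
  expect_equal(sp4$directed$major, "C")
  expect_equal(sp4$directed$minor, "T")
  sp5 <- spectrum_of(make_cs(rep("T", 5), rep("C", 5)))
  expect_equal(sp5$directed$major, "T")
})

test_that("spectrum totals and Ts/Tv survive reverse complementation", {
  for (seed in 1:20) {
    cs <- random_clone_set(8, 40, seed = 400 + seed)
    sp <- spectrum_of(cs)
    sp_rc <- spectrum_of(revcomp_clone_set(cs))
    expect_equal(sp_rc$ts_count, sp$ts_count)
    expect_equal(sp_rc$tv_count, sp$tv_count)
    expect_equal(sp_rc$ts_tv_ratio, sp$ts_tv_ratio)
    expect_equal(sp_rc$snp_total, sp$snp_total)
    expect_equal(sp$ts_count + sp$tv_count, nrow(sp$directed))
    # snp_total agrees with the diversity module's S
    expect_equal(sp$snp_total, segregating_sites(call_all_sites(cs)))
  }
})

test_that("nucleotide haplotype collapse conserves counts and ordering", {
  h1 <- collapse_nucleotide_haplotypes(make_cs(rep("ACGT", 15)))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 15)
  h2 <- collapse_nucleotide_haplotypes(make_cs("AAAA", "AAAA", "CCCC"))
  expect_equal(h2$count, c(2, 1))
  for (seed in 1:10) {
    cs <- random_clone_set(12, 6, seed = seed, gap_p = 0.08)
    h <- collapse_nucleotide_haplotypes(cs)
    expect_equal(sum(h$count), 12)
    expect_equal(sort(h$count, decreasing = TRUE),
                 oracle_haplotype_sizes(cs))
  }
})

test_that("translation follows the standard code with trailing-codon drop", {
  expect_equal(as.character(translate_fragment("ATGGCT")), "MA")
  expect_equal(as.character(translate_fragment("ATGGCTA")), "MA")
  tr <- translate_fragment("TAA")
  expect_equal(as.character(tr), "*")
  expect_true(attr(tr, "internal_stop"))
  expect_equal(as.character(translate_fragment("AATGGC", frame_offset = 1)),
               "M")
  expect_error(translate_fragment("AC-GTA"), "gaps")
  expect_error(translate_fragment("AC"), "too short")
})

test_that("protein collapse merges synonymous variants and guards frameshifts", {
  # two nucleotide haplotypes differing at a synonymous third position
  haps <- collapse_nucleotide_haplotypes(
    make_cs("ATGGCT", "ATGGCT", "ATGGCC"))
  ph <- collapse_protein_haplotypes(haps)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$count, 3)
  expect_equal(ph$aa_sequence, "MA")

  # nonsynonymous variants stay distinct
  haps2 <- collapse_nucleotide_haplotypes(make_cs("ATGGCT", "ATGTCT"))
  expect_equal(nrow(collapse_protein_haplotypes(haps2)), 2)

  # in-frame deletion translates, frameshifting gap refuses
  haps3 <- collapse_nucleotide_haplotypes(make_cs("ATG---GCT", "ATGAAAGCT"))
  ph3 <- collapse_protein_haplotypes(haps3)
  expect_equal(sort(ph3$aa_sequence), c("MA", "MKA"))
  haps4 <- collapse_nucleotide_haplotypes(make_cs("ATG--AGCT", "ATGAAAGCT"))
  expect_error(collapse_protein_haplotypes(haps4), "frameshift")
})

test_that("the coding-fragment fixture collapses to its planted protein types", {
  fx <- brct_like_clone_sets()
  expect_length(fx$clone_sets, 6)
  expect_equal(sum(vapply(fx$clone_sets, function(cs)
    length(cs$clone_ids), integer(1))), 60)
  pooled <- pool_clone_sets(fx$clone_sets)
  haps <- collapse_nucleotide_haplotypes(pooled)
  ph <- collapse_protein_haplotypes(haps, fx$truth$frame_offset)
  expect_equal(nrow(ph), fx$truth$n_protein_haplotypes)
  expect_equal(ph$label, paste0("h", 1:6))
  expect_equal(ph$count, fx$truth$protein_counts)
  expect_gt(nrow(haps), nrow(ph))  # synonymous variation present
  vp <- variant_aa_positions(ph)
  expect_equal(vp$position, fx$truth$variant_aa_positions)
  expect_false(any(ph$internal_stop))
})

test_that("variant amino-acid positions require two residues", {
  ph_same <- data.frame(label = c("h1", "h2"), aa_sequence = c("MAK", "MAK"),
                        count = c(2, 1), member_haplotypes = c("1", "2"),
                        internal_stop = FALSE)
  expect_equal(nrow(variant_aa_positions(ph_same)), 0)
  ph_diff <- ph_same
  ph_diff$aa_sequence <- c("MAK", "MTK")
  vp <- variant_aa_positions(ph_diff)
  expect_equal(vp$position, 2)
  expect_equal(vp$residues, "A,T")
  ph_bad <- ph_same
  ph_bad$aa_sequence <- c("MAK", "MA")
  expect_error(variant_aa_positions(ph_bad), "unequal")
})
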