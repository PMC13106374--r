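make_cs <- function(...) {
  seqs <- c(...)
  clone_set("L", "M", "p1", sprintf("c%02d", seq_along(seqs)), seqs)
}

test_that("segregating sites count polymorphic columns only", {
  cs <- make_cs(rep("ACGTACGT", 5))
  expect_equal(segregating_sites(call_all_sites(cs)), 0)
  cfg <- sim_config("L", "M", 60, n_plants = 1, n_clones = 10,
                    sites = data.frame(column = c(5, 50), major = NA,
                                       minor = NA, minor_count = 2,
                                       sharing = "specific", plants = "1"))
  cs2 <- simulate_clone_set(cfg, 1, seed = 5)$clone_set
  expect_equal(segregating_sites(call_all_sites(cs2)), 2)
})

test_that("pi matches hand-computed pairwise averages", {
  # two clones differing at 1 of 100 columns
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "T")
  expect_equal(nucleotide_diversity(make_cs(a, b))$pi, 0.01)
  # identical clones
  expect_equal(nucleotide_diversity(make_cs(rep(a, 5)))$pi, 0)
  # 4 clones, pairwise diffs {1,2,0,1,1,2}: pi = (7/6)/4
  cs <- make_cs("AAAA", "AAAT", "AATT", "AAAA")
  nd <- nucleotide_diversity(cs)
  expect_equal(nd$pi, (7 / 6) / 4)
  expect_equal(nd$L_used, 4)
  expect_error(nucleotide_diversity(make_cs("AAAA")), "at least 2")
  expect_error(nucleotide_diversity(make_cs("--", "AA")), "undefined")
})

test_that("pi equals the brute-force all-pairs oracle on random sets", {
  for (seed in 1:50) {
    n <- sample(3:10, 1)
    L <- sample(10:50, 1)
    cs <- random_clone_set(n, L, seed = 1000 + seed, gap_p = 0.03,
                           missing_p = 0.02)
    orc <- tryCatch(oracle_pi_complete(cs), error = function(e) NULL)
    if (is.null(orc) || orc$L_used == 0) next
    nd <- nucleotide_diversity(cs, "complete_deletion")
    expect_equal(nd$pi, orc$pi, tolerance = 1e-12)
    expect_equal(nd$L_used, orc$L_used)
  }
})

test_that("pi agrees with ape's raw pairwise distances", {
  skip_if_not_installed("ape")
  for (seed in 1:10) {
    cs <- random_clone_set(8, 60, seed = seed)
    m <- tolower(seq_matrix(cs))
    d <- ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                       pairwise.deletion = FALSE)
    expect_equal(nucleotide_diversity(cs)$pi, mean(d), tolerance = 1e-12)
  }
})

test_that("pairwise deletion normalizes each pair by its own columns", {
  # clone c3 has a gap at col 1; pairs with c3 use 3 columns, others 4
  cs <- make_cs("AAAA", "AAAT", "-ATT")
  nd <- nucleotide_diversity(cs, "pairwise_deletion")
  # pairs: (1,2): 1/4; (1,3): 2/3; (2,3): 1/3
  expect_equal(nd$pi, mean(c(1 / 4, 2 / 3, 1 / 3)))
  expect_equal(nd$L_used, mean(c(4, 3, 3)))
})

test_that("pi * L is conserved when appending monomorphic callable columns", {
  cs <- random_clone_set(6, 30, seed = 7)
  nd <- nucleotide_diversity(cs)
  ext <- clone_set(cs$locus_id, cs$material_id, cs$plant_id, cs$clone_ids,
                   paste0(cs$sequences, strrep("A", 10)))
  nd2 <- nucleotide_diversity(ext)
  expect_equal(nd2$pi * nd2$L_used, nd$pi * nd$L_used, tolerance = 1e-12)
})

test_that("haplotype statistics follow the corrected heterozygosity form", {
  expect_equal(haplotype_stats(make_cs(rep("ACGT", 15))),
               list(h = 1, Hd = 0, frequencies = 15L))
  hs <- haplotype_stats(make_cs("AAAA", "AAAT", "AATT", "ATTT"))
  expect_equal(hs$h, 4)
  expect_equal(hs$Hd, 1)
  hs2 <- haplotype_stats(make_cs("AAAA", "AAAA", "AAAT", "AATT"))
  expect_equal(hs2$Hd, (4 / 3) * (1 - 0.375))
  expect_equal(hs2$frequencies, c(2L, 1L, 1L))
  # class sizes equal the naive pairwise-equality partition
  for (seed in 1:10) {
    cs <- random_clone_set(10, 8, seed = seed, gap_p = 0.05)
    expect_equal(sort(haplotype_stats(cs)$frequencies, decreasing = TRUE),
                 oracle_haplotype_sizes(cs))
  }
})

test_that("Hd reaches its extremes exactly and duplication follows the closed form", {
  cs <- random_clone_set(6, 20, seed = 3)
  hs <- haplotype_stats(cs)
  # duplicating every clone doubles n; recompute from class sizes directly
  dup <- clone_set(cs$locus_id, cs$material_id, cs$plant_id,
                   c(cs$clone_ids, paste0(cs$clone_ids, "_d")),
                   c(cs$sequences, cs$sequences))
  hs_dup <- haplotype_stats(dup)
  n2 <- 12
  p <- 2 * hs$frequencies / n2
  expect_equal(hs_dup$h, hs$h)
  expect_equal(hs_dup$Hd, (n2 / (n2 - 1)) * (1 - sum(p^2)))
})

test_that("material aggregation uses sample standard deviation", {
  df <- data.frame(locus = "L", material = "M", plant = c("p1", "p2", "p3"),
                   n_clones = 15, S = c(30, 31, 35), h = c(2, 2, 2),
                   Hd = c(1, 2, 3), pi = c(0.1, 0.1, 0.1), L_used = 100)
  agg <- aggregate_by_material(df)
  expect_equal(agg$mean[agg$metric == "S"], 32)
  expect_equal(agg$sd[agg$metric == "S"], sqrt(14 / 2))
  expect_equal(agg$sd[agg$metric == "h"], 0)
  expect_equal(agg$mean[agg$metric == "Hd"], 2)
  expect_equal(agg$sd[agg$metric == "Hd"], 1)
  df$locus[1] <- "other"
  expect_error(aggregate_by_material(df), "grouping error")
})

test_that("pooled-variance t-test matches the textbook form and stats::t.test", {
  r <- student_t_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$df, 4)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  # identical groups and degenerate variances
  expect_equal(student_t_two_tailed(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  r0 <- student_t_two_tailed(c(5, 5), c(5, 5))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  rdeg <- student_t_two_tailed(c(5, 5), c(7, 7))
  expect_true(rdeg$degenerate)
  expect_equal(rdeg$p, 0)
})

test_that("concordance demands one nonzero sign across all loci", {
  mk <- function(locus, material, S_mean) {
    data.frame(locus = locus, material = material, metric = "S",
               mean = S_mean, sd = 0, n_plants = 3)
  }
  s <- rbind(mk("A", "W", 10 + 9.33), mk("A", "Z", 10),
             mk("B", "W", 20 + 58.33), mk("B", "Z", 20),
             mk("C", "W", 5 + 20.33), mk("C", "Z", 5))
  expect_true(concordance_check(s, "S", c("W", "Z"))$concordant)
  s2 <- rbind(mk("A", "W", 11), mk("A", "Z", 10),
              mk("B", "W", 19), mk("B", "Z", 20))
  expect_false(concordance_check(s2, "S", c("W", "Z"))$concordant)
  s3 <- rbind(mk("A", "W", 10), mk("A", "Z", 10),
              mk("B", "W", 21), mk("B", "Z", 20))
  expect_false(concordance_check(s3, "S", c("W", "Z"))$concordant)
  expect_error(concordance_check(s[1:4, ], "S", c("W", "Q")), "missing")
})
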