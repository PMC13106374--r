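# Shipped synthetic fixtures.
#
# Three fixture families mirror the structure of the real study's clone
# libraries (all data are synthetic; the study's clone alignments are not
# public):
#   * "mcm7-like": L = 1129, sparse heterogeneity, one material with
#     (1 shared-by-3, 0 shared-by-2, 3 specific) sites and one with
#     (20, 1, 5);
#   * "psae-like": L = 647, dense heterogeneity, (35, 27, 4) vs
#     (53, 83, 31);
#   * "brct-like": a deterministic 240-bp coding fragment, 60 clones
#     across 6 plants of two materials, collapsing to exactly 6 protein
#     haplotypes with variant amino-acid positions {15, 30, 34, 55, 62, 75}.

.fixture_pair <- function(locus, L, counts_a, counts_b, n_clones, seed,
                          error_rate = 0) {
  mk <- function(material, counts, sub) {
    sites <- plan_sites(L, n_clones, counts[1L], counts[2L], counts[3L],
                        seed = derive_seed(seed, sub))
    sim_config(locus, material, L, n_plants = 3L, n_clones = n_clones,
               sites = sites, error_rate = error_rate)
  }
  list(ZK2 = mk("ZK2", counts_a, 1L), W = mk("W", counts_b, 2L))
}

#' "mcm7-like" fixture configurations
#'
#' Two three-plant materials over a 1129-column alignment with planted
#' sharing structure (ZK2: 1 shared-by-3, 0 shared-by-2, 3 specific;
#' W: 20, 1, 5), 15 clones per plant.
#'
#' @param seed master seed controlling site placement.
#' @param error_rate per-base clone-level error rate (default 0).
#' @return named list of two `SimulationConfig`s (`ZK2`, `W`).
#' @export
mcm7_like_configs <- function(seed = 1129L, error_rate = 0) {
  .fixture_pair("MCM7-like", 1129L, c(1L, 0L, 3L), c(20L, 1L, 5L), 15L,
                seed, error_rate)
}

#' "psae-like" fixture configurations
#'
#' Two three-plant materials over a 647-column alignment with dense planted
#' sharing structure (ZK2: 35 shared-by-3, 27 shared-by-2, 4 specific;
#' W: 53, 83, 31), 15 clones per plant.
#'
#' @inheritParams mcm7_like_configs
#' @return named list of two `SimulationConfig`s (`ZK2`, `W`).
#' @export
psae_like_configs <- function(seed = 647L, error_rate = 0) {
  .fixture_pair("PsaE-like", 647L, c(35L, 27L, 4L), c(53L, 83L, 31L), 15L,
                seed, error_rate)
}

#' "brct-like" coding-fragment fixture
#'
#' A deterministic synthetic 240-bp (80-codon) coding fragment sampled over
#' 60 clones from 6 plants (two materials, three plants each).  Six protein
#' haplotypes are planted by nonsynonymous substitutions so that the
#' variant amino-acid positions are exactly {15, 30, 34, 55, 62, 75}; two
#' additional synonymous nucleotide variants make the nucleotide-haplotype
#' count exceed the protein-haplotype count.
#'
#' @return list with `clone_sets` (6 `CloneSet`s of 10 clones), and
#'   `truth`: `n_protein_haplotypes`, `variant_aa_positions`,
#'   `protein_counts` (descending), `frame_offset`, `reference_aa`.
#' @export
brct_like_clone_sets <- function() {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  n_codon <- 80L
  ref_codons <- with_seed(240L, sample(sense, n_codon, replace = TRUE))
  var_pos <- c(15L, 30L, 34L, 55L, 62L, 75L)
  # for each variant codon, the alphabetically first sense codon coding a
  # different residue
  alt_codon <- vapply(var_pos, function(p) {
    aa0 <- Biostrings::GENETIC_CODE[ref_codons[p]]
    cands <- sense[Biostrings::GENETIC_CODE[sense] != aa0]
    sort(cands)[1L]
  }, character(1))
  names(alt_codon) <- as.character(var_pos)

  variant_seq <- function(changed_at) {
    cod <- ref_codons
    for (p in changed_at) cod[p] <- alt_codon[as.character(p)]
    paste(cod, collapse = "")
  }
  # six planted protein types: reference plus five single/double changes
  prot <- list(P1 = variant_seq(integer(0)),
               P2 = variant_seq(15L),
               P3 = variant_seq(30L),
               P4 = variant_seq(c(34L, 55L)),
               P5 = variant_seq(62L),
               P6 = variant_seq(75L))
  # a synonymous variant of P1 (third-position change at codon 40)
  syn_codon <- {
    aa0 <- Biostrings::GENETIC_CODE[ref_codons[40L]]
    cands <- setdiff(sense[Biostrings::GENETIC_CODE[sense] == aa0],
                     ref_codons[40L])
    if (length(cands)) sort(cands)[1L] else NA_character_
  }
  prot$P1syn <- {
    cod <- ref_codons
    if (!is.na(syn_codon)) cod[40L] <- syn_codon
    paste(cod, collapse = "")
  }

  plan <- list(
    list(material = "ZK2", plant = "p1",
         clones = c(rep("P1", 6L), rep("P1syn", 2L), rep("P2", 2L))),
    list(material = "ZK2", plant = "p2",
         clones = c(rep("P1", 9L), "P3")),
    list(material = "ZK2", plant = "p3", clones = rep("P1", 10L)),
    list(material = "W", plant = "p1",
         clones = c(rep("P1", 4L), rep("P4", 3L), rep("P5", 3L))),
    list(material = "W", plant = "p2",
         clones = c(rep("P2", 4L), rep("P4", 3L), rep("P6", 3L))),
    list(material = "W", plant = "p3",
         clones = c(rep("P1", 3L), rep("P3", 3L), rep("P5", 2L),
                    rep("P6", 2L))))
  clone_sets <- lapply(plan, function(pl) {
    clone_set("XRCC1-BRCT-like", pl$material, pl$plant,
              sprintf("c%02d", seq_along(pl$clones)),
              unlist(prot[pl$clones], use.names = FALSE))
  })
  counts <- sort(table(unlist(lapply(plan, function(pl)
    sub("syn$", "", pl$clones)))), decreasing = TRUE)
  list(clone_sets = clone_sets,
       truth = list(n_protein_haplotypes = 6L,
                    variant_aa_positions = var_pos,
                    protein_counts = sort(as.integer(counts),
                                          decreasing = TRUE),
                    frame_offset = 0L,
                    reference_aa = paste(
                      Biostrings::GENETIC_CODE[ref_codons], collapse = "")))
}
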