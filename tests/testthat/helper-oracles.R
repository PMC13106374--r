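# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (character loops, all-pairs scans) and share no code
# with the package implementation.

# random clone set; gap_p/missing_p inject '-' / 'N' characters
random_clone_set <- function(n, L, seed, gap_p = 0, missing_p = 0,
                             locus = "LOC", material = "M", plant = "p1") {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  if (gap_p > 0) m[runif(n * L) < gap_p] <- "-"
  if (missing_p > 0) m[runif(n * L) < missing_p] <- "N"
  clone_set(locus, material, plant, sprintf("c%02d", seq_len(n)),
            apply(m, 1, paste, collapse = ""))
}

# reverse complement preserving gap / missing states
revcomp_clone_set <- function(cs) {
  rc <- vapply(cs$sequences, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  clone_set(cs$locus_id, cs$material_id, cs$plant_id, cs$clone_ids,
            unname(rc))
}

# oracle: per-column tally and polymorphic call by direct enumeration
oracle_polymorphic_columns <- function(cs, min_minor = 1) {
  chars <- strsplit(cs$sequences, "")
  out <- integer(0)
  for (j in seq_len(cs$alignment_length)) {
    col <- vapply(chars, `[`, character(1), j)
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    if (sum(tab >= min_minor) >= 2) out <- c(out, j)
  }
  out
}

# oracle: nucleotide diversity by naive all-pairs double loop
oracle_pi_complete <- function(cs) {
  chars <- strsplit(cs$sequences, "")
  n <- length(chars)
  L <- cs$alignment_length
  keep <- logical(L)
  for (j in seq_len(L)) {
    keep[j] <- all(vapply(chars, `[`, character(1), j) %in%
                     c("A", "C", "G", "T"))
  }
  total <- 0
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      for (j in which(keep)) {
        if (chars[[i]][j] != chars[[k]][j]) total <- total + 1
      }
    }
  }
  list(pi = 2 * total / (n * (n - 1)) / sum(keep), L_used = sum(keep))
}

# oracle: haplotype partition by pairwise string equality
oracle_haplotype_sizes <- function(cs) {
  seqs <- cs$sequences
  assigned <- rep(NA_integer_, length(seqs))
  cls <- 0
  for (i in seq_along(seqs)) {
    if (is.na(assigned[i])) {
      cls <- cls + 1
      for (j in i:length(seqs)) {
        if (is.na(assigned[j]) && seqs[j] == seqs[i]) assigned[j] <- cls
      }
    }
  }
  sort(as.integer(table(assigned)), decreasing = TRUE)
}

# random ungapped simulation config with a 3-plant sharing structure
random_material_config <- function(seed, L = NULL, n_clones = 15,
                                   with_indels = FALSE) {
  set.seed(seed)
  if (is.null(L)) L <- sample(100:300, 1)
  n3 <- sample(0:5, 1); n2 <- sample(0:5, 1); n1 <- sample(0:5, 1)
  sites <- plan_sites(L, n_clones, n3, n2, n1, seed = seed + 1)
  indels <- empty_indels()
  if (with_indels) {
    # a short deletion avoiding planted site columns
    free <- setdiff(seq_len(L - 4), unlist(lapply(sites$column,
                                                  function(c) (c - 4):c)))
    if (length(free)) {
      s <- free[sample.int(length(free), 1)]
      indels <- data.frame(start = s, end = s + 2,
                           plant = sample(1:3, 1), carriers = 2)
    }
  }
  sim_config("LOC", "M", L, n_plants = 3, n_clones = n_clones,
             sites = sites, indels = indels)
}
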