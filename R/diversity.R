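# Per-clone-set diversity estimators and material-level aggregation.
#
# S counts polymorphic columns (indel events excluded).  pi is the average
# proportion of differing valid bases over all clone pairs, with either
# complete-deletion (default: any gap/missing excludes the column for all
# pairs) or pairwise-deletion gap handling.  Hd uses the small-sample
# corrected form n/(n-1) * (1 - sum p_i^2).

#' Number of segregating (polymorphic) sites
#'
#' @param st a `SiteTable`.
#' @return integer count of polymorphic columns; indel events excluded.
#' @export
segregating_sites <- function(st) {
  stopifnot(inherits(st, "SiteTable"))
  length(st$polymorphic_positions)
}

#' Pairwise nucleotide diversity
#'
#' Computes pi = 2 / (n (n - 1)) * sum_{i<j} d_ij / L.  Under
#' `complete_deletion`, L is the number of columns with a valid base in
#' every clone and d_ij counts differing bases at those columns.  Under
#' `pairwise_deletion`, each pair's difference count is normalized by that
#' pair's own fully-called column count and the per-pair proportions are
#' averaged.
#'
#' @param cs a `CloneSet` with at least two clones.
#' @param gap_mode `"complete_deletion"` (default) or
#'   `"pairwise_deletion"`.
#' @return list with `pi` (per-site fraction) and `L_used` (columns entering
#'   the estimate; for pairwise deletion, the mean per-pair column count).
#' @export
nucleotide_diversity <- function(cs,
                                 gap_mode = c("complete_deletion",
                                              "pairwise_deletion")) {
  stopifnot(inherits(cs, "CloneSet"))
  gap_mode <- match.arg(gap_mode)
  m <- seq_matrix(cs)
  n <- nrow(m)
  if (n < 2L) stop("nucleotide diversity requires at least 2 clones",
                   call. = FALSE)
  valid <- matrix(m %in% VALID_BASES, nrow = n)
  pairs <- utils::combn(n, 2L)
  if (gap_mode == "complete_deletion") {
    keep <- colSums(valid) == n
    L <- sum(keep)
    if (L == 0L) stop("pi undefined: no fully-called columns", call. = FALSE)
    mk <- m[, keep, drop = FALSE]
    d <- vapply(seq_len(ncol(pairs)), function(k)
      sum(mk[pairs[1L, k], ] != mk[pairs[2L, k], ]), numeric(1))
    pi <- (2 / (n * (n - 1))) * sum(d) / L
    list(pi = pi, L_used = as.integer(L))
  } else {
    props <- Ls <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      ok <- valid[i, ] & valid[j, ]
      Lp <- sum(ok)
      if (Lp == 0L) stop("pi undefined: clone pair with no shared called columns",
                         call. = FALSE)
      props[k] <- sum(m[i, ok] != m[j, ok]) / Lp
      Ls[k] <- Lp
    }
    list(pi = mean(props), L_used = mean(Ls))
  }
}

#' Haplotype number, frequencies and haplotype diversity
#'
#' Haplotypes are equivalence classes of exact column-wise identity over the
#' full alignment, with gap and missing characters taking part in identity.
#' Hd = n/(n-1) * (1 - sum p_i^2).
#'
#' @param cs a `CloneSet` with at least two clones.
#' @return list with `h` (haplotype count), `Hd`, and `frequencies`
#'   (integer vector of class sizes, descending).
#' @export
haplotype_stats <- function(cs) {
  stopifnot(inherits(cs, "CloneSet"))
  n <- length(cs$sequences)
  if (n < 2L) stop("haplotype diversity requires at least 2 clones",
                   call. = FALSE)
  freq <- sort(unname(table(cs$sequences)), decreasing = TRUE)
  p <- as.numeric(freq) / n
  list(h = length(freq),
       Hd = (n / (n - 1)) * (1 - sum(p^2)),
       frequencies = as.integer(freq))
}

#' Full per-plant diversity summary
#'
#' Convenience wrapper computing S, h, Hd and pi for one clone set.
#'
#' @param cs a `CloneSet`.
#' @param min_minor_count allele-support threshold for polymorphic calls.
#' @param gap_mode gap handling for pi (see [nucleotide_diversity()]).
#' @return one-row data.frame: locus, material, plant, n_clones, S, h, Hd,
#'   pi, L_used.
#' @export
diversity_stats <- function(cs, min_minor_count = 1L,
                            gap_mode = "complete_deletion") {
  st <- call_all_sites(cs, min_minor_count)
  hap <- haplotype_stats(cs)
  nd <- nucleotide_diversity(cs, gap_mode)
  data.frame(locus = cs$locus_id, material = cs$material_id,
             plant = cs$plant_id, n_clones = length(cs$clone_ids),
             S = segregating_sites(st), h = hap$h, Hd = hap$Hd,
             pi = nd$pi, L_used = nd$L_used, stringsAsFactors = FALSE)
}

#' Aggregate per-plant statistics within a material
#'
#' Mean and sample standard deviation (denominator n - 1) across the
#' biological replicates of one material at one locus, for each of S, h,
#' Hd and pi.
#'
#' @param stats data.frame as returned by [diversity_stats()] (rows =
#'   plants of one material at one locus; at least 2 plants).
#' @return data.frame with one row per metric: locus, material, metric,
#'   mean, sd, n_plants.
#' @export
aggregate_by_material <- function(stats) {
  if (length(unique(stats$locus)) != 1L ||
      length(unique(stats$material)) != 1L) {
    stop("grouping error: aggregate_by_material expects one locus and one material",
         call. = FALSE)
  }
  if (nrow(stats) < 2L) {
    stop("grouping error: at least 2 plants required", call. = FALSE)
  }
  metrics <- c("S", "h", "Hd", "pi")
  do.call(rbind, lapply(metrics, function(mt) {
    v <- stats[[mt]]
    data.frame(locus = stats$locus[1L], material = stats$material[1L],
               metric = mt, mean = mean(v), sd = stats::sd(v),
               n_plants = nrow(stats), stringsAsFactors = FALSE)
  }))
}

#' Two-tailed pooled-variance Student's t-test
#'
#' Classical two-sample Student's t with pooled variance and
#' df = n_a + n_b - 2, two-tailed p-value.  Zero pooled variance is handled
#' explicitly: equal means give t = 0, p = 1; unequal means are reported as
#' p ~ 0 with a degenerate-variance flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p` and logical `degenerate`.
#' @export
student_t_two_tailed <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  dm <- mean(a) - mean(b)
  if (se == 0) {
    if (dm == 0) {
      return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(dm) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- dm / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Multi-locus concordance of a between-material difference
#'
#' The study design accepts a between-material conclusion only when the
#' sign of the material difference is the same, and nonzero, at every
#' locus.
#'
#' @param summaries data.frame of material summaries (rows from
#'   [aggregate_by_material()] over several loci; exactly two materials).
#' @param metric which metric to check (`"S"` or `"pi"`).
#' @param materials optional character vector of length 2 fixing the order
#'   of the difference (material A minus material B); defaults to order of
#'   appearance.
#' @return list of class `ConcordanceResult` with `metric`, `signs` (named
#'   by locus), and `concordant`.
#' @export
concordance_check <- function(summaries, metric = c("S", "pi"),
                              materials = NULL) {
  metric <- match.arg(metric)
  s <- summaries[summaries$metric == metric, , drop = FALSE]
  if (is.null(materials)) materials <- unique(s$material)
  if (length(materials) != 2L) {
    stop("concordance requires exactly two materials", call. = FALSE)
  }
  loci <- unique(s$locus)
  if (length(loci) < 2L) stop("concordance requires >= 2 loci", call. = FALSE)
  signs <- vapply(loci, function(lc) {
    a <- s$mean[s$locus == lc & s$material == materials[1L]]
    b <- s$mean[s$locus == lc & s$material == materials[2L]]
    if (length(a) != 1L || length(b) != 1L) {
      stop("missing material summary for locus ", lc, call. = FALSE)
    }
    sign(a - b)
  }, numeric(1))
  names(signs) <- loci
  structure(list(metric = metric, signs = signs,
                 concordant = all(signs != 0) && length(unique(signs)) == 1L),
            class = "ConcordanceResult")
}
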