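# Cross-plant classification of heterogeneous sites within one material.
#
# Three plants of one material are compared on a common callable-site mask:
# a column is commonly callable only when every clone of every plant carries
# a valid base there (a single gap or missing base anywhere excludes it).
# Polymorphic columns inside the mask are partitioned by how many plants
# show them: shared by all three, shared by exactly two, or plant-specific.
# The total is the union over plants inside the mask, so the three category
# counts always sum to the total.

#' Common callable-site mask across three plants
#'
#' @param sets list of exactly three `CloneSet`s of one material at one
#'   locus, sharing one alignment column space.
#' @return logical vector over columns; `TRUE` where every clone of every
#'   plant has a valid base (A/C/G/T).
#' @export
common_callable_mask <- function(sets) {
  stopifnot(length(sets) == 3L,
            all(vapply(sets, inherits, logical(1), "CloneSet")))
  L <- unique(vapply(sets, `[[`, integer(1), "alignment_length"))
  if (length(L) != 1L) {
    stop("alignment length mismatch across plants: ",
         paste(vapply(sets, `[[`, integer(1), "alignment_length"),
               collapse = ", "), call. = FALSE)
  }
  Reduce(`&`, lapply(sets, function(cs) {
    m <- seq_matrix(cs)
    colSums(matrix(m %in% VALID_BASES, nrow = nrow(m))) == nrow(m)
  }))
}

#' Classify heterogeneous sites across three plants
#'
#' For every commonly callable column, counts in how many of the three
#' plants it is polymorphic, and partitions polymorphic columns into
#' shared-by-3 / shared-by-2 / plant-specific categories.
#'
#' @param tables list of three `SiteTable`s (one per plant, computed from
#'   the clone sets behind `mask`).
#' @param mask logical mask from [common_callable_mask()].
#' @return list of class `CrossPlantSummary` with fields `locus_id`,
#'   `material_id`, `common_callable`, `total_polymorphic`, `shared_by_3`,
#'   `shared_by_2`, `plant_specific`, and `site_assignments` (data.frame:
#'   column, n_plants, plants).
#' @export
classify_sites <- function(tables, mask) {
  stopifnot(length(tables) == 3L,
            all(vapply(tables, inherits, logical(1), "SiteTable")))
  L <- unique(vapply(tables, `[[`, integer(1), "alignment_length"))
  if (length(L) != 1L || length(mask) != L) {
    stop("mask/table mismatch: mask length must equal the shared alignment length",
         call. = FALSE)
  }
  callable_cols <- which(mask)
  plant_ids <- vapply(tables, `[[`, character(1), "plant_id")
  in_plant <- vapply(tables, function(st)
    callable_cols %in% st$polymorphic_positions,
    logical(length(callable_cols)))
  if (length(callable_cols) == 1L) in_plant <- matrix(in_plant, nrow = 1L)
  n_plants <- if (length(callable_cols)) rowSums(in_plant) else integer(0)
  keep <- n_plants >= 1L
  assignments <- data.frame(
    column = callable_cols[keep],
    n_plants = as.integer(n_plants[keep]),
    plants = vapply(which(keep), function(i)
      paste(sort(plant_ids[in_plant[i, ]]), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  structure(
    list(locus_id = tables[[1L]]$locus_id,
         material_id = tables[[1L]]$material_id,
         common_callable = length(callable_cols),
         total_polymorphic = sum(keep),
         shared_by_3 = sum(n_plants == 3L),
         shared_by_2 = sum(n_plants == 2L),
         plant_specific = sum(n_plants == 1L),
         site_assignments = assignments),
    class = "CrossPlantSummary")
}

#' @export
print.CrossPlantSummary <- function(x, ...) {
  cat(sprintf(
    "CrossPlantSummary: %s / %s\n  callable %d, total %d = shared3 %d + shared2 %d + specific %d\n",
    x$locus_id, x$material_id, x$common_callable, x$total_polymorphic,
    x$shared_by_3, x$shared_by_2, x$plant_specific))
  invisible(x)
}

#' One-step cross-plant summary from three clone sets
#'
#' @param sets list of three `CloneSet`s of one material at one locus.
#' @param min_minor_count allele-support threshold for polymorphic calls.
#' @return a `CrossPlantSummary`.
#' @export
cross_plant_summary <- function(sets, min_minor_count = 1L) {
  mask <- common_callable_mask(sets)
  tables <- lapply(sets, call_all_sites, min_minor_count = min_minor_count)
  classify_sites(tables, mask)
}
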