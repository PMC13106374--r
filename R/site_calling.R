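# Per-column state calling and indel-event merging.
#
# A column is polymorphic within a plant when at least two distinct valid
# nucleotides (A/C/G/T) are observed among its clones, each supported by at
# least `min_minor_count` clones (default 1).  Gap and missing states are
# never valid nucleotides; columns where gaps face bases contribute indel
# events, never substitution polymorphism.

#' Call a single alignment column
#'
#' Tallies base, gap and missing states at one column of a clone set and
#' applies the polymorphic-site rule: polymorphic iff at least two distinct
#' valid bases are present, each supported by `min_minor_count` or more
#' clones.
#'
#' @param cs a `CloneSet`.
#' @param column 1-based column index.
#' @param min_minor_count minimum clone support per allele (default 1).
#' @return list of class `SiteCall` with fields `column`, `base_counts`
#'   (named integer vector over A/C/G/T), `gap_count`, `missing_count`,
#'   `distinct_valid_bases`, `is_polymorphic`, `is_fully_called`.
#' @export
call_column <- function(cs, column, min_minor_count = 1L) {
  stopifnot(inherits(cs, "CloneSet"))
  if (length(column) != 1L || column < 1L || column > cs$alignment_length) {
    stop("column out of range [1, ", cs$alignment_length, "]", call. = FALSE)
  }
  chars <- substring(cs$sequences, column, column)
  base_counts <- vapply(VALID_BASES, function(b) sum(chars == b), integer(1))
  gap_count <- sum(chars == GAP_CHAR)
  missing_count <- sum(chars == MISSING_CHAR)
  supported <- sum(base_counts >= min_minor_count & base_counts > 0L)
  structure(
    list(column = as.integer(column),
         base_counts = base_counts,
         gap_count = gap_count,
         missing_count = missing_count,
         distinct_valid_bases = sum(base_counts > 0L),
         is_polymorphic = sum(base_counts > 0L) >= 2L && supported >= 2L,
         is_fully_called = gap_count == 0L && missing_count == 0L),
    class = "SiteCall")
}

#' Call every column of a clone set
#'
#' Produces the per-column call table, the ordered list of polymorphic
#' positions, and the merged indel events (see [merge_indel_events()]).
#'
#' @param cs a `CloneSet`.
#' @param min_minor_count minimum clone support per allele (default 1).
#' @return list of class `SiteTable` with fields `locus_id`, `plant_id`,
#'   `n_clones`, `alignment_length`, `calls` (data.frame with one row per
#'   column: column, A, C, G, T, gaps, missing, distinct_valid_bases,
#'   polymorphic, fully_called), `polymorphic_positions` (sorted integer
#'   vector) and `indel_events`.
#' @export
call_all_sites <- function(cs, min_minor_count = 1L) {
  stopifnot(inherits(cs, "CloneSet"))
  m <- seq_matrix(cs)
  n <- nrow(m)
  counts <- vapply(VALID_BASES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, VALID_BASES))
  gaps <- colSums(m == GAP_CHAR)
  missing <- colSums(m == MISSING_CHAR)
  distinct <- rowSums(counts > 0L)
  supported <- rowSums(counts >= min_minor_count & counts > 0L)
  poly <- distinct >= 2L & supported >= 2L
  calls <- data.frame(column = seq_len(ncol(m)),
                      A = as.integer(counts[, "A"]),
                      C = as.integer(counts[, "C"]),
                      G = as.integer(counts[, "G"]),
                      T = as.integer(counts[, "T"]),
                      gaps = as.integer(gaps),
                      missing = as.integer(missing),
                      distinct_valid_bases = as.integer(distinct),
                      polymorphic = poly,
                      fully_called = gaps == 0L & missing == 0L)
  structure(
    list(locus_id = cs$locus_id,
         plant_id = cs$plant_id,
         material_id = cs$material_id,
         n_clones = n,
         alignment_length = cs$alignment_length,
         calls = calls,
         polymorphic_positions = calls$column[poly],
         indel_events = merge_indel_events(cs)),
    class = "SiteTable")
}

#' @export
print.SiteTable <- function(x, ...) {
  cat(sprintf("SiteTable: %s/%s, %d columns, %d polymorphic, %d indel events\n",
              x$locus_id, x$plant_id, x$alignment_length,
              length(x$polymorphic_positions), nrow(x$indel_events)))
  invisible(x)
}

#' Merge consecutive deletion columns into single indel events
#'
#' A maximal run of consecutive gap columns carried by an identical clone
#' set counts as one event; adjacent gap columns whose carrier sets differ
#' split into separate events.  This treats one multi-column deletion as a
#' single mutational event.
#'
#' @param cs a `CloneSet`.
#' @return data.frame with columns `start_column`, `end_column` (inclusive),
#'   `carrier_clone_ids` (carrier ids joined by `,`, sorted) and
#'   `n_carriers`; zero rows when the alignment has no gaps.
#' @export
merge_indel_events <- function(cs) {
  stopifnot(inherits(cs, "CloneSet"))
  m <- seq_matrix(cs)
  is_gap <- m == GAP_CHAR
  empty <- data.frame(start_column = integer(), end_column = integer(),
                      carrier_clone_ids = character(), n_carriers = integer(),
                      stringsAsFactors = FALSE)
  gap_cols <- which(colSums(is_gap) > 0L)
  if (length(gap_cols) == 0L) return(empty)
  # key identifies the carrier set at each gapped column
  keys <- vapply(gap_cols, function(j)
    paste(sort(cs$clone_ids[is_gap[, j]]), collapse = ","), character(1))
  # split where columns are non-adjacent or the carrier set changes
  brk <- c(TRUE, diff(gap_cols) != 1L | keys[-1L] != keys[-length(keys)])
  grp <- cumsum(brk)
  starts <- tapply(gap_cols, grp, min)
  ends <- tapply(gap_cols, grp, max)
  carriers <- tapply(keys, grp, `[`, 1L)
  data.frame(start_column = as.integer(starts),
             end_column = as.integer(ends),
             carrier_clone_ids = as.character(carriers),
             n_carriers = lengths(strsplit(as.character(carriers), ",",
                                           fixed = TRUE)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a site table as TSV
#'
#' @param st a `SiteTable`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(st, path) {
  stopifnot(inherits(st, "SiteTable"))
  out <- data.frame(locus = st$locus_id, plant = st$plant_id, st$calls)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export merged indel events as TSV
#'
#' @param st a `SiteTable`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_indel_events <- function(st, path) {
  stopifnot(inherits(st, "SiteTable"))
  ev <- st$indel_events
  out <- data.frame(locus = rep(st$locus_id, nrow(ev)),
                    plant = rep(st$plant_id, nrow(ev)),
                    start = ev$start_column, end = ev$end_column,
                    carriers = ev$carrier_clone_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
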