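# CDS-fragment profiling: substitution spectra with Ts/Tv, haplotype
# collapse at the nucleotide and protein level, and variant amino-acid
# positions.
#
# Substitutions are typed per minor allele at each polymorphic column,
# directed relative to the within-plant major allele (no outgroup
# polarization).  Transitions are A<->G and C<->T; the other four unordered
# pairs are transversions.

.PAIR_CLASSES <- c("A:G", "C:T", "A:C", "T:G", "A:T", "G:C")
.TS_CLASSES <- c("A:G", "C:T")

pair_class <- function(b1, b2) {
  key <- paste(pmin(b1, b2), pmax(b1, b2), sep = ":")
  # canonical order within each class follows the conventional listing
  canon <- c("A:G" = "A:G", "C:T" = "C:T", "A:C" = "A:C", "G:T" = "T:G",
             "A:T" = "A:T", "C:G" = "G:C")
  unname(canon[key])
}

#' Substitution spectrum of a clone set
#'
#' At each polymorphic column the major allele is the most frequent valid
#' base; every other observed valid base is a minor allele contributing one
#' typed substitution (major -> minor).  A frequency tie for the major
#' allele is broken in favor of the base carried by the earliest clone (in
#' input order): unlike an alphabetical tie-break, this commutes with
#' complementation, so Ts/Tv and the pair-class spectrum are exactly
#' invariant under reverse-complementing the clone set.
#'
#' @param st `SiteTable` of the clone set.
#' @param cs the `CloneSet` the table was computed from.
#' @return list of class `SubstitutionSpectrum`: `pair_counts` (named
#'   integer vector over A:G, C:T, A:C, T:G, A:T, G:C), `directed`
#'   (data.frame column/major/minor), `ts_count`, `tv_count`,
#'   `ts_tv_ratio` (`NA` when no transversions were typed), `snp_total`
#'   (number of polymorphic columns).
#' @export
substitution_spectrum <- function(st, cs) {
  stopifnot(inherits(st, "SiteTable"), inherits(cs, "CloneSet"))
  cols <- st$polymorphic_positions
  m <- seq_matrix(cs)
  directed <- data.frame(column = integer(), major = character(),
                         minor = character(), stringsAsFactors = FALSE)
  for (col in cols) {
    cts <- unlist(st$calls[st$calls$column == col, VALID_BASES])
    present <- VALID_BASES[cts > 0L]
    top <- present[cts[present] == max(cts[present])]
    major <- if (length(top) == 1L) top
             else unname(m[which(m[, col] %in% top)[1L], col])  # earliest clone
    minors <- setdiff(present, major)
    directed <- rbind(directed,
                      data.frame(column = col, major = major, minor = minors,
                                 stringsAsFactors = FALSE))
  }
  classes <- if (nrow(directed)) pair_class(directed$major, directed$minor)
             else character(0)
  pair_counts <- vapply(.PAIR_CLASSES, function(p) sum(classes == p),
                        integer(1))
  ts <- sum(pair_counts[.TS_CLASSES])
  tv <- sum(pair_counts) - ts
  structure(
    list(pair_counts = pair_counts,
         directed = directed,
         ts_count = ts,
         tv_count = tv,
         ts_tv_ratio = if (tv == 0L) NA_real_ else ts / tv,
         snp_total = length(cols)),
    class = "SubstitutionSpectrum")
}

#' Collapse clones into nucleotide haplotypes
#'
#' Haplotypes are exact-identity classes over the full aligned sequence
#' (gap and missing characters included), sorted by descending count and
#' then lexicographically by sequence.
#'
#' @param cs a `CloneSet`.
#' @return data.frame with columns `sequence`, `count` and
#'   `member_clone_ids` (comma-joined).
#' @export
collapse_nucleotide_haplotypes <- function(cs) {
  stopifnot(inherits(cs, "CloneSet"))
  grp <- split(cs$clone_ids, cs$sequences)
  df <- data.frame(sequence = names(grp),
                   count = lengths(grp),
                   member_clone_ids = vapply(grp, function(ids)
                     paste(sort(ids), collapse = ","), character(1)),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Translate a nucleotide fragment
#'
#' Standard-code translation of complete codons after skipping
#' `frame_offset` leading bases; a trailing partial codon is dropped.
#' Internal stop codons translate as `*` and set the `internal_stop`
#' attribute.  Gaps must be removed beforehand (see
#' [collapse_protein_haplotypes()] for the frameshift guard).
#'
#' @param seq nucleotide string over A/C/G/T (N allowed, translating to X).
#' @param frame_offset 0, 1 or 2 leading bases to skip.
#' @return amino-acid string with attribute `internal_stop` (logical).
#' @export
#' @examples
#' translate_fragment("ATGGCT")   # "MA"
translate_fragment <- function(seq, frame_offset = 0L) {
  stopifnot(length(seq) == 1L, frame_offset %in% 0:2)
  seq <- normalize_sequences(seq)
  if (grepl("-", seq, fixed = TRUE)) {
    stop("gaps must be removed before translation", call. = FALSE)
  }
  body <- substring(seq, frame_offset + 1L)
  n_codon <- nchar(body) %/% 3L
  if (n_codon < 1L) stop("fragment too short to translate", call. = FALSE)
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(body, starts, starts + 2L)
  aa <- vapply(codons, function(cd) {
    if (grepl("N", cd, fixed = TRUE)) return("X")
    unname(Biostrings::GENETIC_CODE[cd])
  }, character(1))
  out <- paste(aa, collapse = "")
  attr(out, "internal_stop") <- grepl("*", out, fixed = TRUE)
  out
}

#' Collapse nucleotide haplotypes into protein haplotypes
#'
#' Translates each nucleotide haplotype under one frame and merges those
#' with identical amino-acid sequences.  Labels `h1..hk` are assigned by
#' descending total clone count, ties broken lexicographically by protein
#' sequence, so labeling is deterministic.
#'
#' Haplotypes containing gap characters are accepted only when every
#' maximal gap run has length divisible by 3 (an in-frame deletion); any
#' other gap pattern would shift the reading frame and is an error.
#'
#' @param haps data.frame from [collapse_nucleotide_haplotypes()].
#' @param frame_offset 0, 1 or 2 (see [translate_fragment()]); for a
#'   fragment starting at 1-based CDS position `s`, use `(s - 1) %% 3`
#'   relative to the fragment's own first base, i.e. 0 when the fragment
#'   starts on a codon boundary.
#' @return data.frame with columns `label`, `aa_sequence`, `count`,
#'   `member_haplotypes` (indices into `haps`, comma-joined) and
#'   `internal_stop`.
#' @export
collapse_protein_haplotypes <- function(haps, frame_offset = 0L) {
  stopifnot(is.data.frame(haps), nrow(haps) >= 1L)
  aa <- character(nrow(haps))
  stop_flag <- logical(nrow(haps))
  for (i in seq_len(nrow(haps))) {
    s <- haps$sequence[i]
    if (grepl("-", s, fixed = TRUE)) {
      runs <- regmatches(s, gregexpr("-+", s))[[1L]]
      if (any(nchar(runs) %% 3L != 0L)) {
        stop("frameshift guard: gap run length not a multiple of 3 in haplotype ",
             i, call. = FALSE)
      }
      s <- gsub("-", "", s, fixed = TRUE)
    }
    tr <- translate_fragment(s, frame_offset)
    aa[i] <- as.character(tr)
    stop_flag[i] <- attr(tr, "internal_stop")
  }
  grp <- split(seq_len(nrow(haps)), aa)
  df <- data.frame(
    aa_sequence = names(grp),
    count = vapply(grp, function(ix) sum(haps$count[ix]), numeric(1)),
    member_haplotypes = vapply(grp, function(ix)
      paste(ix, collapse = ","), character(1)),
    internal_stop = vapply(grp, function(ix) any(stop_flag[ix]), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$aa_sequence), , drop = FALSE]
  rownames(df) <- NULL
  df$label <- paste0("h", seq_len(nrow(df)))
  df[, c("label", "aa_sequence", "count", "member_haplotypes",
         "internal_stop")]
}

#' Variant amino-acid positions among protein haplotypes
#'
#' Lists every fragment position (1-based) where at least two distinct
#' residues are observed across the protein haplotypes, with the residues
#' and the haplotype labels carrying each.
#'
#' @param phaps data.frame from [collapse_protein_haplotypes()] with at
#'   least two haplotypes of equal amino-acid length.
#' @return data.frame with columns `position`, `residues` (comma-joined,
#'   sorted) and `carriers` (per-residue haplotype labels,
#'   `res:lab1+lab2` entries joined by `,`).
#' @export
variant_aa_positions <- function(phaps) {
  stopifnot(is.data.frame(phaps), nrow(phaps) >= 2L)
  lens <- nchar(phaps$aa_sequence)
  if (length(unique(lens)) != 1L) {
    stop("protein haplotypes have unequal lengths", call. = FALSE)
  }
  m <- matrix(unlist(strsplit(phaps$aa_sequence, "", fixed = TRUE)),
              nrow = nrow(phaps), byrow = TRUE)
  pos <- which(apply(m, 2L, function(col) length(unique(col)) >= 2L))
  if (length(pos) == 0L) {
    return(data.frame(position = integer(), residues = character(),
                      carriers = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(pos, function(p) {
    res <- sort(unique(m[, p]))
    carriers <- vapply(res, function(r)
      paste0(r, ":", paste(phaps$label[m[, p] == r], collapse = "+")),
      character(1))
    data.frame(position = p, residues = paste(res, collapse = ","),
               carriers = paste(carriers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
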