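# Clone-set container, FASTA I/O and coordinate conventions.
#
# A CloneSet is the atomic analysis unit: all cloned amplicon sequences from
# one plant at one locus, pre-aligned to a common column space.  Sequences
# are stored normalized: uppercase, U -> T, every IUPAC ambiguity code
# (including N) collapsed to the single MISSING state 'N', '-' the GAP state.

VALID_BASES <- c("A", "C", "G", "T")
GAP_CHAR <- "-"
MISSING_CHAR <- "N"
.IUPAC_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize aligned nucleotide strings
#'
#' Uppercases, maps U to T, collapses all IUPAC ambiguity codes (N, R, Y, S,
#' W, K, M, B, D, H, V) to the single missing-data state `N`, and keeps `-`
#' as the gap state.  Any other character is an error.
#'
#' @param x character vector of aligned sequences.
#' @return character vector of the same length, normalized.
#' @keywords internal
normalize_sequences <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  for (code in setdiff(.IUPAC_AMBIG, "N")) {
    x <- gsub(code, MISSING_CHAR, x, fixed = TRUE)
  }
  bad <- grepl(sprintf("[^%sN-]", paste(VALID_BASES, collapse = "")), x)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTN-]", "", x[bad]), "")))
    stop("invalid sequence characters: ", paste(chars, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Construct a clone set
#'
#' Bundles one plant's aligned clone sequences for one locus.  All sequences
#' must have equal length; clone ids must be unique.  Sequences are
#' normalized (see [normalize_sequences()]).
#'
#' @param locus_id,material_id,plant_id identifiers (scalar character).
#' @param clone_ids character vector of unique clone identifiers.
#' @param sequences character vector of aligned sequences, parallel to
#'   `clone_ids`.
#' @return an object of class `CloneSet` with fields `locus_id`,
#'   `material_id`, `plant_id`, `clone_ids`, `sequences`,
#'   `alignment_length`.
#' @export
#' @examples
#' cs <- clone_set("MCM7", "ZK2", "p1", c("c1", "c2"), c("ACGT", "ACGA"))
#' cs$alignment_length
clone_set <- function(locus_id, material_id, plant_id, clone_ids, sequences) {
  stopifnot(length(clone_ids) == length(sequences), length(clone_ids) >= 1)
  if (anyDuplicated(clone_ids)) {
    stop("duplicate clone ids in clone set ", locus_id, "/", plant_id,
         call. = FALSE)
  }
  sequences <- normalize_sequences(as.character(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    off <- clone_ids[lens != lens[1L]]
    stop("alignment error in ", locus_id, "/", plant_id,
         ": unequal sequence lengths for records ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  structure(
    list(locus_id = as.character(locus_id),
         material_id = as.character(material_id),
         plant_id = as.character(plant_id),
         clone_ids = as.character(clone_ids),
         sequences = unname(sequences),
         alignment_length = lens[1L]),
    class = "CloneSet")
}

#' @export
print.CloneSet <- function(x, ...) {
  cat(sprintf("CloneSet: locus %s, material %s, plant %s\n  %d clones x %d columns\n",
              x$locus_id, x$material_id, x$plant_id,
              length(x$clone_ids), x$alignment_length))
  invisible(x)
}

#' Clone set as a character matrix
#'
#' @param cs a `CloneSet`.
#' @return character matrix, one row per clone (rownames = clone ids), one
#'   column per alignment column.
#' @export
seq_matrix <- function(cs) {
  m <- matrix(unlist(strsplit(cs$sequences, "", fixed = TRUE), use.names = FALSE),
              nrow = length(cs$sequences), byrow = TRUE)
  rownames(m) <- cs$clone_ids
  m
}

# ---- sample manifest -------------------------------------------------------

#' Create a sample manifest from record-id parsing rules
#'
#' Record ids are resolved to (locus, material, plant, clone) either by
#' splitting on a delimiter (default `|`, field order
#' locus|material|plant|clone) or via an explicit lookup table read with
#' [read_manifest()].
#'
#' @param delim field delimiter in FASTA record ids.
#' @param fields order of the four fields within the id.
#' @param table optional data.frame with columns `record_id`, `locus`,
#'   `material`, `plant`, `clone`; when given, ids are resolved by lookup
#'   and the delimiter scheme is ignored.
#' @return an object of class `SampleManifest`.
#' @export
sample_manifest <- function(delim = "|",
                            fields = c("locus", "material", "plant", "clone"),
                            table = NULL) {
  stopifnot(setequal(fields, c("locus", "material", "plant", "clone")))
  if (!is.null(table)) {
    need <- c("record_id", "locus", "material", "plant", "clone")
    if (!all(need %in% names(table))) {
      stop("manifest table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(table$record_id)) {
      stop("manifest error: duplicated record ids", call. = FALSE)
    }
  }
  structure(list(delim = delim, fields = fields, table = table),
            class = "SampleManifest")
}

#' Read a tab-separated sample manifest
#'
#' @param path TSV file with columns record_id, locus, material, plant,
#'   clone (header required).
#' @return a `SampleManifest` resolving ids by table lookup.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  sample_manifest(table = tab)
}

#' Resolve FASTA record ids to sample tuples
#'
#' @param ids character vector of record ids.
#' @param manifest a `SampleManifest`.
#' @return data.frame with columns record_id, locus, material, plant, clone.
#' @keywords internal
resolve_record_ids <- function(ids, manifest) {
  stopifnot(inherits(manifest, "SampleManifest"))
  if (!is.null(manifest$table)) {
    idx <- match(ids, manifest$table$record_id)
    if (anyNA(idx)) {
      stop("manifest error: unresolvable record ids: ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    out <- manifest$table[idx, c("locus", "material", "plant", "clone")]
  } else {
    parts <- strsplit(ids, manifest$delim, fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L)) {
      stop("manifest error: record ids not matching '",
           paste(manifest$fields, collapse = manifest$delim), "' scheme: ",
           paste(ids[nf != 4L], collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, parts)
    colnames(m) <- manifest$fields
    out <- as.data.frame(m[, c("locus", "material", "plant", "clone"),
                           drop = FALSE])
  }
  data.frame(record_id = ids, out, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- FASTA I/O -------------------------------------------------------------

#' Read clone-set alignments from a multi-FASTA file
#'
#' Reads an aligned multi-FASTA (wrapped or unwrapped) and groups records
#' into one `CloneSet` per (locus, plant).  Record ids are resolved through
#' the manifest; unresolvable ids are an error, as are unequal sequence
#' lengths within a clone set.
#'
#' @param path FASTA file of aligned clone sequences.
#' @param manifest a `SampleManifest`; defaults to the
#'   `locus|material|plant|clone` id scheme.
#' @return list of `CloneSet` objects, ordered by (locus, plant) of first
#'   appearance.
#' @export
read_clone_alignment <- function(path, manifest = sample_manifest()) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  # id is everything up to the first whitespace (FASTA description dropped)
  ids <- sub("\\s.*$", "", ids)
  info <- resolve_record_ids(ids, manifest)
  info$seq <- as.character(seqs)
  key <- paste(info$locus, info$plant, sep = "\r")
  out <- lapply(split(info, factor(key, levels = unique(key))), function(g) {
    mat <- unique(g$material)
    if (length(mat) != 1L) {
      stop("manifest error: clone set ", g$locus[1L], "/", g$plant[1L],
           " maps to multiple materials: ", paste(mat, collapse = ", "),
           call. = FALSE)
    }
    clone_set(g$locus[1L], mat, g$plant[1L], g$clone, g$seq)
  })
  unname(out)
}

#' Write clone sets to an aligned multi-FASTA file
#'
#' Record ids follow the `locus|material|plant|clone` scheme.  Sequences
#' are written unwrapped so that output is byte-stable.
#'
#' @param sets a `CloneSet` or list of `CloneSet`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clone_alignment <- function(sets, path) {
  if (inherits(sets, "CloneSet")) sets <- list(sets)
  ids <- unlist(lapply(sets, function(cs)
    paste(cs$locus_id, cs$material_id, cs$plant_id, cs$clone_ids, sep = "|")))
  seqs <- unlist(lapply(sets, `[[`, "sequences"))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 20001L)
  invisible(path)
}

#' Pool several clone sets into one
#'
#' Concatenates the clones of multiple same-length clone sets (e.g. all
#' plants of both materials) into a single set for pooled haplotype
#' analyses.  Clone ids are prefixed `material|plant|` to stay unique.
#'
#' @param sets list of `CloneSet`s with equal alignment lengths.
#' @param locus_id,material_id,plant_id identifiers of the pooled set;
#'   default to the first set's locus and `"pooled"`.
#' @return a `CloneSet`.
#' @export
pool_clone_sets <- function(sets, locus_id = sets[[1L]]$locus_id,
                            material_id = "pooled", plant_id = "pooled") {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "CloneSet")))
  ids <- unlist(lapply(sets, function(cs)
    paste(cs$material_id, cs$plant_id, cs$clone_ids, sep = "|")))
  seqs <- unlist(lapply(sets, `[[`, "sequences"))
  clone_set(locus_id, material_id, plant_id, ids, seqs)
}

# ---- QC gate ---------------------------------------------------------------

#' Validate a clone set against the per-plant clone-count gate
#'
#' The study design requires at least 15 independent clones per plant per
#' locus (so three biological replicates give >= 45 clone sequences per
#' locus).  This reports rather than raises.
#'
#' @param cs a `CloneSet`.
#' @param min_clones minimum clone count per plant (default 15).
#' @return list of class `ValidationReport` with fields `passed`,
#'   `clone_count`, `min_clones_required`, `messages`.
#' @export
validate_clone_set <- function(cs, min_clones = 15L) {
  stopifnot(inherits(cs, "CloneSet"))
  n <- length(cs$clone_ids)
  msgs <- character()
  if (n < min_clones) {
    msgs <- c(msgs, sprintf("clone set %s/%s has %d clones, below minimum %d",
                            cs$locus_id, cs$plant_id, n, min_clones))
  }
  structure(list(passed = n >= min_clones,
                 clone_count = n,
                 min_clones_required = as.integer(min_clones),
                 messages = msgs),
            class = "ValidationReport")
}

# ---- coordinates -----------------------------------------------------------

#' Length of a coordinate interval
#'
#' User-facing positions are 1-based; interval lengths use half-open
#' semantics, i.e. `end - start`.  Under this convention a CDS fragment
#' written as 171-411 spans 240 bp.
#'
#' @param start,end non-negative integer coordinates with `end > start`.
#' @return integer interval length in base pairs.
#' @export
#' @examples
#' interval_length(171, 411)  # 240
interval_length <- function(start, end) {
  if (length(start) != 1L || length(end) != 1L ||
      !is.finite(start) || !is.finite(end) ||
      start != trunc(start) || end != trunc(end) || start < 0 || end < 0) {
    stop("start and end must be single non-negative integers", call. = FALSE)
  }
  if (end <= start) {
    stop("empty or inverted interval: end must exceed start", call. = FALSE)
  }
  as.integer(end - start)
}
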