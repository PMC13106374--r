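# Pipeline orchestration and report assembly.
#
# run_pipeline() ties the stages together for a two-material comparison:
# QC gate -> per-plant site calling and diversity -> material aggregation
# with pooled-variance t-tests -> cross-plant classification (Table-1
# layout) -> substitution spectra -> multi-locus concordance.  All tables
# can be written as locale-independent TSV with a provenance config hash.

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; fields mirror [run_pipeline()]'s `config`
#'   argument.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical (sorted-key) JSON serialization; used to
#' cross-reference every emitted table with the run that produced it.
#'
#' @param config a configuration list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(
    jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                     force = TRUE, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

#' Emit a Table-1-style cross-plant summary
#'
#' Fixed column order (gene, material, common callable, total, shared-by-3,
#' shared-by-2, plant-specific).  The category-sum identity
#' `total == shared3 + shared2 + specific` is re-verified before anything
#' is written; a violation aborts rather than silently emitting.
#'
#' @param summaries list of `CrossPlantSummary` objects (typically one per
#'   material per locus).
#' @param path optional TSV output file.
#' @return data.frame in Table-1 layout (invisibly written to `path` when
#'   given).
#' @export
emit_table1 <- function(summaries, path = NULL) {
  if (inherits(summaries, "CrossPlantSummary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "CrossPlantSummary"))
    if (s$total_polymorphic != s$shared_by_3 + s$shared_by_2 + s$plant_specific) {
      stop("internal consistency error: category counts do not sum to total for ",
           s$locus_id, "/", s$material_id, call. = FALSE)
    }
    data.frame(gene = s$locus_id, material = s$material_id,
               common_callable = s$common_callable,
               total_polymorphic = s$total_polymorphic,
               shared_by_3 = s$shared_by_3,
               shared_by_2 = s$shared_by_2,
               plant_specific = s$plant_specific,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(format(out, trim = TRUE, scientific = FALSE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the full two-material comparison pipeline
#'
#' `config` is a list with fields:
#' \describe{
#'   \item{fasta, manifest}{input alignment and optional manifest TSV path
#'     (alternative to `simulations`).}
#'   \item{simulations}{named list of `SimulationConfig`s (one per
#'     material per locus) to generate inputs instead of reading FASTA.}
#'   \item{seed}{master seed for simulation inputs.}
#'   \item{min_clones}{per-plant clone-count gate (default 15).}
#'   \item{min_minor_count}{allele-support threshold (default 1).}
#'   \item{gap_mode}{`"complete_deletion"` (default) or
#'     `"pairwise_deletion"`.}
#'   \item{out_dir}{optional output directory for TSV/JSON artifacts.}
#' }
#'
#' @param config configuration list (see Details) or path to a YAML file.
#' @return list of class `RunReport`: `per_plant` (diversity table),
#'   `per_material` (mean/sd per metric), `tests` (pooled t per locus and
#'   metric between the two materials), `table1` (data.frame),
#'   `cross_plant` (list of `CrossPlantSummary`), `spectra`,
#'   `concordance` (per metric, when >= 2 loci), `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  min_clones <- config$min_clones %||% 15L
  min_minor <- config$min_minor_count %||% 1L
  gap_mode <- config$gap_mode %||% "complete_deletion"

  if (!is.null(config$simulations)) {
    sims <- lapply(config$simulations, simulate_material,
                   seed = config$seed %||% 1L)
    sets <- unlist(lapply(sims, `[[`, "clone_sets"), recursive = FALSE)
  } else if (!is.null(config$fasta)) {
    manifest <- if (!is.null(config$manifest)) read_manifest(config$manifest)
                else sample_manifest()
    sets <- read_clone_alignment(config$fasta, manifest)
  } else {
    stop("config must provide either 'simulations' or 'fasta'",
         call. = FALSE)
  }

  # QC gate: abort on any clone set below the per-plant minimum
  for (cs in sets) {
    vr <- validate_clone_set(cs, min_clones)
    if (!vr$passed) {
      stop("QC failure [validation stage]: ",
           paste(vr$messages, collapse = "; "), call. = FALSE)
    }
  }

  tables <- lapply(sets, call_all_sites, min_minor_count = min_minor)
  per_plant <- do.call(rbind, lapply(sets, diversity_stats,
                                     min_minor_count = min_minor,
                                     gap_mode = gap_mode))
  rownames(per_plant) <- NULL

  key <- paste(per_plant$locus, per_plant$material, sep = "\r")
  per_material <- do.call(rbind, lapply(split(per_plant, key),
                                        aggregate_by_material))
  rownames(per_material) <- NULL

  materials <- unique(per_plant$material)
  loci <- unique(per_plant$locus)
  tests <- NULL
  if (length(materials) == 2L) {
    rows <- list()
    for (lc in loci) {
      for (mt in c("S", "h", "Hd", "pi")) {
        a <- per_plant[per_plant$locus == lc &
                         per_plant$material == materials[1L], mt]
        b <- per_plant[per_plant$locus == lc &
                         per_plant$material == materials[2L], mt]
        if (length(a) >= 2L && length(b) >= 2L) {
          tt <- student_t_two_tailed(a, b)
          rows[[length(rows) + 1L]] <-
            data.frame(locus = lc, metric = mt,
                       material_a = materials[1L],
                       material_b = materials[2L],
                       t = tt$t, df = tt$df, p = tt$p,
                       degenerate = tt$degenerate,
                       stringsAsFactors = FALSE)
        }
      }
    }
    tests <- do.call(rbind, rows)
  }

  # cross-plant classification per (locus, material) with exactly 3 plants
  xp <- list()
  for (lc in loci) {
    for (mat in materials) {
      sel <- vapply(sets, function(cs)
        cs$locus_id == lc && cs$material_id == mat, logical(1))
      if (sum(sel) == 3L) {
        xp[[paste(lc, mat, sep = "/")]] <-
          cross_plant_summary(sets[sel], min_minor_count = min_minor)
      }
    }
  }
  table1 <- if (length(xp)) emit_table1(xp) else NULL

  spectra <- lapply(seq_along(sets), function(i)
    substitution_spectrum(tables[[i]], sets[[i]]))
  names(spectra) <- vapply(sets, function(cs)
    paste(cs$locus_id, cs$material_id, cs$plant_id, sep = "/"), character(1))

  concordance <- NULL
  if (length(loci) >= 2L && length(materials) == 2L) {
    concordance <- list(S = concordance_check(per_material, "S", materials),
                        pi = concordance_check(per_material, "pi", materials))
  }

  hash <- config_hash(config[setdiff(names(config), "simulations")])
  report <- structure(
    list(per_plant = per_plant, per_material = per_material, tests = tests,
         table1 = table1, cross_plant = xp, spectra = spectra,
         concordance = concordance, config_hash = hash),
    class = "RunReport")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tables(report, config$out_dir)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run report's tables as TSV/JSON
#'
#' Every file carries the config hash in a leading comment line; numeric
#' formatting is locale-independent with `.` as decimal separator.
#'
#' @param report a `RunReport`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# config_hash=", report$config_hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, dec = ".")
    written <<- c(written, path)
  }
  emit(report$per_plant, "per_plant_diversity.tsv")
  emit(report$per_material, "per_material_summary.tsv")
  if (!is.null(report$tests)) emit(report$tests, "material_tests.tsv")
  if (!is.null(report$table1)) emit(report$table1, "cross_plant_table.tsv")
  spec_rows <- do.call(rbind, lapply(names(report$spectra), function(nm) {
    sp <- report$spectra[[nm]]
    data.frame(set = nm, t(sp$pair_counts), ts = sp$ts_count,
               tv = sp$tv_count,
               ts_tv = ifelse(is.na(sp$ts_tv_ratio), "NA",
                              format(sp$ts_tv_ratio)),
               snp_total = sp$snp_total, check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(spec_rows)) emit(spec_rows, "substitution_spectra.tsv")
  summary <- list(config_hash = report$config_hash,
                  n_clone_sets = nrow(report$per_plant),
                  loci = unique(report$per_plant$locus),
                  materials = unique(report$per_plant$material))
  if (!is.null(report$concordance)) {
    summary$concordant <- lapply(report$concordance, `[[`, "concordant")
  }
  json_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(written, json_path))
}
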