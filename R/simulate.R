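# Seeded clone-set simulator with planted variant structure.
#
# The simulator emulates the data structure of a clone-library amplicon
# study: per-plant clone sets with planted biallelic substitution sites
# having a cross-plant sharing structure (shared by all three plants,
# shared by a designated pair, or plant-specific), optional multi-column
# deletion events, and independent per-base error noise standing in for
# sporadic PCR/cloning artifacts.  Every draw is reproducible: a single
# master seed derives one substream for the reference sequence and one per
# plant, so adding a plant never perturbs earlier plants.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation code never disturbs the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a substream seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index, kept inside
#' 32-bit integer range.  Stream 0 is the reference sequence; stream p is
#' plant p.
#'
#' @param master integer master seed.
#' @param index non-negative stream index.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(index) * 30269 + 17) %% 2147483647)
}

#' Build a simulation configuration
#'
#' @param locus_id,material_id identifiers for the simulated clone sets.
#' @param L alignment length (columns).
#' @param n_plants number of plants (default 3; cross-plant truth requires
#'   3).
#' @param n_clones clones per plant (default 15).
#' @param sites data.frame of planted biallelic substitution sites with
#'   columns `column`, `major` (base or NA = reference base), `minor`
#'   (base or NA = drawn uniformly from the other three), `minor_count`
#'   (clones carrying the minor allele, per carrier plant), `sharing`
#'   (`"shared3"`, `"shared2"` or `"specific"`) and `plants`
#'   (comma-joined plant indices; filled as `"1,2,3"` for shared3).
#' @param indels data.frame of planted deletion events with columns
#'   `start`, `end`, `plant` (index) and `carriers` (clone count).
#' @param error_rate per-base per-clone probability of a uniform miscall
#'   to one of the three other bases (applied last, recorded in truth).
#' @param missing_rate per-base probability of replacing a called base
#'   with the missing state `N`.
#' @param gc GC weight of the random reference (0.5 = uniform).
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(locus_id, material_id, L,
                       n_plants = 3L, n_clones = 15L,
                       sites = empty_sites(), indels = empty_indels(),
                       error_rate = 0, missing_rate = 0, gc = 0.5) {
  stopifnot(L >= 1L, n_plants >= 1L, n_clones >= 2L,
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1, gc > 0, gc < 1)
  sites <- as.data.frame(sites)
  indels <- as.data.frame(indels)
  if (nrow(sites)) {
    if (anyDuplicated(sites$column)) {
      stop("planted site columns must be distinct", call. = FALSE)
    }
    if (any(sites$column < 1L | sites$column > L)) {
      stop("planted site column outside [1, L]", call. = FALSE)
    }
    if (any(sites$minor_count < 1L | sites$minor_count >= n_clones)) {
      stop("infeasible config: minor_count must be in [1, n_clones - 1]",
           call. = FALSE)
    }
    if (!all(sites$sharing %in% c("shared3", "shared2", "specific"))) {
      stop("unknown sharing class", call. = FALSE)
    }
    sites$plants <- as.character(sites$plants)
    sites$plants[sites$sharing == "shared3"] <-
      paste(seq_len(n_plants), collapse = ",")
    pl <- strsplit(sites$plants, ",", fixed = TRUE)
    npl <- lengths(pl)
    if (any(sites$sharing == "shared2" & npl != 2L) ||
        any(sites$sharing == "specific" & npl != 1L)) {
      stop("plants field inconsistent with sharing class", call. = FALSE)
    }
    idx <- suppressWarnings(as.integer(unlist(pl)))
    if (anyNA(idx) || any(idx < 1L | idx > n_plants)) {
      stop("sharing class references nonexistent plant", call. = FALSE)
    }
  }
  if (nrow(indels)) {
    stopifnot(all(indels$start >= 1L), all(indels$end <= L),
              all(indels$start <= indels$end),
              all(indels$plant >= 1L & indels$plant <= n_plants),
              all(indels$carriers >= 1L & indels$carriers < n_clones))
    indel_cols <- unlist(mapply(seq, indels$start, indels$end,
                                SIMPLIFY = FALSE))
    if (nrow(sites) && length(intersect(sites$column, indel_cols))) {
      stop("planted site columns must be disjoint from indel columns",
           call. = FALSE)
    }
  }
  structure(list(locus_id = as.character(locus_id),
                 material_id = as.character(material_id),
                 L = as.integer(L), n_plants = as.integer(n_plants),
                 n_clones = as.integer(n_clones),
                 sites = sites, indels = indels,
                 error_rate = error_rate, missing_rate = missing_rate,
                 gc = gc),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf("SimulationConfig: %s/%s, L=%d, %d plants x %d clones, %d sites, %d indels, eps=%g\n",
              x$locus_id, x$material_id, x$L, x$n_plants, x$n_clones,
              nrow(x$sites), nrow(x$indels), x$error_rate))
  invisible(x)
}

#' @rdname sim_config
#' @export
empty_sites <- function() {
  data.frame(column = integer(), major = character(), minor = character(),
             minor_count = integer(), sharing = character(),
             plants = character(), stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
empty_indels <- function() {
  data.frame(start = integer(), end = integer(), plant = integer(),
             carriers = integer(), stringsAsFactors = FALSE)
}

#' Plan a random site table with a given sharing structure
#'
#' Draws distinct columns and per-site minor-clone counts for a requested
#' number of shared-by-3, shared-by-2 and plant-specific sites.  Shared-by-2
#' pair and specific plant are drawn uniformly.  Minor-clone counts are
#' drawn uniformly on `[1, floor(n_clones / 2)]` (the study gives no
#' per-site minor-allele frequency distribution; this default is an
#' assumption, documented as such).
#'
#' @param L alignment length.
#' @param n_clones clones per plant.
#' @param n_shared3,n_shared2,n_specific category counts to plant.
#' @param n_plants number of plants (default 3).
#' @param seed integer seed for the draw.
#' @return sites data.frame suitable for [sim_config()].
#' @export
plan_sites <- function(L, n_clones, n_shared3, n_shared2, n_specific,
                       n_plants = 3L, seed = 1L) {
  total <- n_shared3 + n_shared2 + n_specific
  stopifnot(total <= L)
  if (total == 0L) return(empty_sites())
  with_seed(seed, {
    cols <- sort(sample.int(L, total))
    sharing <- sample(rep(c("shared3", "shared2", "specific"),
                          c(n_shared3, n_shared2, n_specific)))
    plants <- vapply(sharing, function(sh) {
      switch(sh,
             shared3 = paste(seq_len(n_plants), collapse = ","),
             shared2 = paste(sort(sample.int(n_plants, 2L)), collapse = ","),
             specific = as.character(sample.int(n_plants, 1L)))
    }, character(1))
    kmax <- max(1L, n_clones %/% 2L)
    data.frame(column = cols, major = NA_character_, minor = NA_character_,
               minor_count = sample.int(kmax, total, replace = TRUE),
               sharing = sharing, plants = unname(plants),
               stringsAsFactors = FALSE)
  })
}

# Resolve the reference sequence and the major/minor bases of each site;
# stream 0 of the master seed.
.resolve_reference <- function(cfg, seed) {
  with_seed(derive_seed(seed, 0L), {
    w <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
           T = (1 - cfg$gc) / 2)
    ref <- sample(VALID_BASES, cfg$L, replace = TRUE, prob = w[VALID_BASES])
    sites <- cfg$sites
    if (nrow(sites)) {
      for (i in seq_len(nrow(sites))) {
        if (is.na(sites$major[i])) sites$major[i] <- ref[sites$column[i]]
        ref[sites$column[i]] <- sites$major[i]
        if (is.na(sites$minor[i])) {
          sites$minor[i] <- sample(setdiff(VALID_BASES, sites$major[i]), 1L)
        }
        if (sites$minor[i] == sites$major[i]) {
          stop("planted minor allele equals major allele at column ",
               sites$column[i], call. = FALSE)
        }
      }
    }
    list(reference = ref, sites = sites)
  })
}

# Generate one plant's clone matrix from the resolved reference; stream
# `plant` of the master seed.  Returns the CloneSet plus realized truth.
.simulate_plant <- function(cfg, resolved, plant, seed) {
  n <- cfg$n_clones
  with_seed(derive_seed(seed, plant), {
    m <- matrix(rep(resolved$reference, each = n), nrow = n)
    sites <- resolved$sites
    planted_cols <- integer(0)
    if (nrow(sites)) {
      for (i in seq_len(nrow(sites))) {
        carriers_of <- as.integer(strsplit(sites$plants[i], ",",
                                           fixed = TRUE)[[1L]])
        if (plant %in% carriers_of) {
          ix <- sample.int(n, sites$minor_count[i])
          m[ix, sites$column[i]] <- sites$minor[i]
          planted_cols <- c(planted_cols, sites$column[i])
        }
      }
    }
    indels <- cfg$indels
    realized_indels <- list()
    if (nrow(indels)) {
      for (i in seq_len(nrow(indels))) {
        if (indels$plant[i] == plant) {
          ix <- sample.int(n, indels$carriers[i])
          m[ix, indels$start[i]:indels$end[i]] <- GAP_CHAR
          realized_indels[[length(realized_indels) + 1L]] <-
            data.frame(start = indels$start[i], end = indels$end[i],
                       plant = plant, carrier_clones = paste(sort(ix),
                                                             collapse = ","))
        }
      }
    }
    if (cfg$missing_rate > 0) {
      base_cells <- which(m %in% VALID_BASES)
      hit <- base_cells[stats::runif(length(base_cells)) < cfg$missing_rate]
      m[hit] <- MISSING_CHAR
    }
    errors <- data.frame(plant = integer(), clone = integer(),
                         column = integer(), from = character(),
                         to = character(), stringsAsFactors = FALSE)
    if (cfg$error_rate > 0) {
      base_cells <- which(m %in% VALID_BASES)
      hit <- base_cells[stats::runif(length(base_cells)) < cfg$error_rate]
      if (length(hit)) {
        from <- m[hit]
        to <- vapply(from, function(b)
          sample(setdiff(VALID_BASES, b), 1L), character(1))
        m[hit] <- to
        errors <- data.frame(plant = plant,
                             clone = ((hit - 1L) %% n) + 1L,
                             column = ((hit - 1L) %/% n) + 1L,
                             from = unname(from), to = unname(to),
                             stringsAsFactors = FALSE)
      }
    }
    cs <- clone_set(cfg$locus_id, cfg$material_id, sprintf("p%d", plant),
                    sprintf("c%02d", seq_len(n)),
                    apply(m, 1L, paste, collapse = ""))
    list(clone_set = cs,
         planted_columns = sort(unique(planted_cols)),
         realized_indels = if (length(realized_indels))
           do.call(rbind, realized_indels) else NULL,
         errors = errors)
  })
}

#' Simulate one plant's clone set
#'
#' @param cfg a `SimulationConfig`.
#' @param plant plant index in `1..n_plants`.
#' @param seed master seed (the reference sequence and every plant derive
#'   their own substreams from it).
#' @return list with `clone_set` and partial truth (`planted_columns`,
#'   `realized_indels`, `errors`, `reference`, `sites`).
#' @export
simulate_clone_set <- function(cfg, plant, seed) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            plant >= 1L, plant <= cfg$n_plants)
  resolved <- .resolve_reference(cfg, seed)
  out <- .simulate_plant(cfg, resolved, plant, seed)
  out$reference <- resolved$reference
  out$sites <- resolved$sites
  out
}

#' Simulate a full material (all plants) with ground truth
#'
#' Plants shared-by-3 sites in every plant, shared-by-2 sites in their
#' designated pair, and specific sites in one plant, then applies indels,
#' missing-data injection and error noise per plant.  Identical
#' `(config, seed)` gives byte-identical output.
#'
#' @param cfg a `SimulationConfig`.
#' @param seed master seed.
#' @return list with `clone_sets` (list of `CloneSet`, one per plant) and
#'   `truth` (class `SimulationTruth`): resolved `sites`, `reference`,
#'   per-plant `planted_columns`, expected `categories`
#'   (shared3/shared2/specific/total), `realized_indels`, `errors`, and
#'   the generating `config`/`seed`.
#' @export
simulate_material <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  resolved <- .resolve_reference(cfg, seed)
  per_plant <- lapply(seq_len(cfg$n_plants), function(p)
    .simulate_plant(cfg, resolved, p, seed))
  sites <- resolved$sites
  categories <- c(shared3 = sum(sites$sharing == "shared3"),
                  shared2 = sum(sites$sharing == "shared2"),
                  specific = sum(sites$sharing == "specific"),
                  total = nrow(sites))
  truth <- structure(
    list(sites = sites,
         reference = resolved$reference,
         planted_columns = lapply(per_plant, `[[`, "planted_columns"),
         categories = categories,
         realized_indels = do.call(rbind, lapply(per_plant, `[[`,
                                                 "realized_indels")),
         errors = do.call(rbind, lapply(per_plant, `[[`, "errors")),
         config = cfg, seed = seed),
    class = "SimulationTruth")
  list(clone_sets = lapply(per_plant, `[[`, "clone_set"), truth = truth)
}

#' Expected summary statistics implied by the planted truth
#'
#' In exact mode (`error_rate = 0`, `missing_rate = 0`) returns, per plant,
#' the expected segregating-site count and the analytic nucleotide
#' diversity `pi = sum_sites 2 k (n - k) / (n (n - 1)) / L_used` (with
#' `L_used` the columns free of realized gaps in that plant), plus the
#' expected cross-plant category counts.  With noise, the planted values
#' are lower bounds and the expected injected-error count
#' `n_plants * n_clones * L * error_rate` is reported instead.
#'
#' @param truth a `SimulationTruth` from [simulate_material()].
#' @return list with `mode` (`"exact"` or `"bounds"`), `per_plant`
#'   (data.frame: plant, S, pi, L_used), `categories`, `common_callable`
#'   and, in bounds mode, `expected_error_count`.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "SimulationTruth"))
  cfg <- truth$config
  exact <- cfg$error_rate == 0 && cfg$missing_rate == 0
  n <- cfg$n_clones
  gap_cols_by_plant <- lapply(seq_len(cfg$n_plants), function(p) {
    ri <- truth$realized_indels
    if (is.null(ri)) return(integer(0))
    ri <- ri[ri$plant == p, , drop = FALSE]
    if (!nrow(ri)) return(integer(0))
    sort(unique(unlist(mapply(seq, ri$start, ri$end, SIMPLIFY = FALSE))))
  })
  per_plant <- do.call(rbind, lapply(seq_len(cfg$n_plants), function(p) {
    cols <- truth$planted_columns[[p]]
    L_used <- cfg$L - length(gap_cols_by_plant[[p]])
    k <- truth$sites$minor_count[match(cols, truth$sites$column)]
    pi <- sum(2 * k * (n - k) / (n * (n - 1))) / L_used
    data.frame(plant = p, S = length(cols), pi = pi, L_used = L_used)
  }))
  all_gap <- sort(unique(unlist(gap_cols_by_plant)))
  out <- list(mode = if (exact) "exact" else "bounds",
              per_plant = per_plant,
              categories = truth$categories,
              common_callable = cfg$L - length(all_gap))
  if (!exact) {
    out$expected_error_count <-
      cfg$n_plants * cfg$n_clones * cfg$L * cfg$error_rate
  }
  out
}
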