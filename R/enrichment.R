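#' Construct a probe set
#'
#' @param name Set name.
#' @param probe_ids Character vector of probe IDs (deduplicated).
#' @param source_tag One of `clock`, `cell_estimator`, `mQTL`,
#'   `feature_class`, `circadian`, `expression_linked`, `custom`.
#' @return Object of class `"probe_set"`.
#' @export
probe_set <- function(name, probe_ids,
                      source_tag = c("custom", "clock", "cell_estimator",
                                     "mQTL", "feature_class", "circadian",
                                     "expression_linked")) {
  source_tag <- match.arg(source_tag)
  structure(list(name = name, probe_ids = unique(as.character(probe_ids)),
                 source_tag = source_tag),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set %s [%s]: %d probes>\n",
              x$name, x$source_tag, length(x$probe_ids)))
  invisible(x)
}

#' Read / write probe-set collections as CSV
#'
#' The CSV has columns `set_name`, `probe_id` (one row per membership).
#'
#' @param path CSV path.
#' @return Named list of [probe_set()] objects.
#' @export
read_probe_sets <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  stopifnot(all(c("set_name", "probe_id") %in% names(df)))
  sets <- lapply(split(df$probe_id, df$set_name), function(ids) ids)
  mapply(probe_set, names(sets), sets, SIMPLIFY = FALSE)
}

#' @rdname read_probe_sets
#' @param sets Named list of [probe_set()] objects.
#' @export
write_probe_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set_name = s$name, probe_id = s$probe_ids,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Published cardinalities of the reference probe sets
#'
#' Sizes of the epigenetic-clock and immune-cell-estimator probe sets used
#' for stability enrichment (Horvath multi-tissue, Hannum blood, Levine
#' PhenoAge, PC clock, DunedinPACE, EPIC IDOL-6, EPIC IDOL-Extended).
#'
#' @return Named integer vector of set sizes.
#' @export
reference_set_sizes <- function() {
  c(Horvath = 353L, Hannum = 89L, PhenoAge = 513L, PCClock = 78464L,
    DunedinPACE = 173L, IDOL6 = 450L, IDOLExtended = 1200L)
}

#' Fabricate reference-sized probe sets from a probe universe
#'
#' Real clock/estimator manifests are not bundled; for synthetic cohorts this
#' samples membership uniformly from the supplied universe at the published
#' cardinalities (capped at the universe size).
#'
#' @param probe_ids Probe universe.
#' @param sizes Named sizes (default [reference_set_sizes()]).
#' @param seed Integer seed.
#' @return Named list of [probe_set()] objects (tagged synthetic membership).
#' @export
make_reference_probe_sets <- function(probe_ids, sizes = reference_set_sizes(),
                                      seed = 1L) {
  set.seed(as.integer(seed))
  tags <- c(Horvath = "clock", Hannum = "clock", PhenoAge = "clock",
            PCClock = "clock", DunedinPACE = "clock",
            IDOL6 = "cell_estimator", IDOLExtended = "cell_estimator")
  out <- lapply(names(sizes), function(nm) {
    n <- min(sizes[[nm]], length(probe_ids))
    probe_set(nm, sample(probe_ids, n),
              source_tag = if (nm %in% names(tags)) tags[[nm]] else "custom")
  })
  stats::setNames(out, names(sizes))
}

#' Rank probes by stability
#'
#' Returns the ranking statistic used by the enrichment stage: included
#' probes (ICC at or above `exclude_below`, converged fits only when the
#' table carries a `converged` flag) in descending ICC order, ties broken by
#' probe ID so the ranking is deterministic.
#'
#' @param icc An ICC table slice for one scenario, or a named numeric vector.
#' @param exclude_below Exclusion threshold; strict `<` excluded.
#' @return Named numeric vector of statistics, sorted descending.
#' @export
rank_probes <- function(icc, exclude_below = 0.01) {
  if (is.data.frame(icc)) {
    keep <- if ("converged" %in% names(icc)) icc$converged else TRUE
    icc <- stats::setNames(icc$icc21[keep], icc$probe_id[keep])
  }
  icc <- icc[icc >= exclude_below]
  if (!length(icc)) stop("no probes remain after exclusion")
  icc[order(-icc, names(icc))]
}

#' Weighted running-sum enrichment score
#'
#' The preranked Kolmogorov-Smirnov-style statistic: walking down the ranked
#' list, the running sum rises by `|stat|^weight / sum(|stat in set|^weight)`
#' at set members and falls by `1 / (N - |S|)` at non-members; the score is
#' the signed maximal deviation from zero, in `[-1, 1]`.
#'
#' @param stats Named statistic vector; re-sorted descending (ties by name)
#'   internally.
#' @param set Probe IDs (or a [probe_set()]); must intersect the universe.
#' @param weight Exponent on the statistic (1 = weighted default, 0 =
#'   classical unweighted KS).
#' @return Enrichment score.
#' @export
enrichment_score <- function(stats, set, weight = 1) {
  if (inherits(set, "probe_set")) set <- set$probe_ids
  stats <- stats[order(-stats, names(stats))]
  idx <- which(names(stats) %in% set)
  if (!length(idx)) stop("probe set does not intersect the ranked universe")
  es_from_positions(stats, idx, weight)
}

## core running-sum evaluation from sorted hit positions
es_from_positions <- function(stats, idx, weight) {
  N <- length(stats)
  s <- length(idx)
  if (s == N) return(1)
  w <- abs(stats[idx])^weight
  W <- sum(w)
  if (W <= 0) { w <- rep(1, s); W <- s }
  cw <- cumsum(w) / W
  miss <- 1 / (N - s)
  j <- seq_len(s)
  top <- cw - (idx - j) * miss            # running sum just after each hit
  bot <- c(0, cw[-s]) - (idx - j) * miss  # just before each hit
  hi <- max(top)
  lo <- min(min(bot), 0)
  if (hi >= -lo) hi else lo
}

#' Permutation p-value for stability enrichment
#'
#' The null distribution is generated by drawing random probe sets of the
#' same size from the ranked universe (preranked set-permutation null). The
#' one-sided p-value for enrichment toward high stability is
#' `(1 + #\{ES_null >= ES_obs\}) / (n_perm + 1)`; it can never fall below
#' `1 / (n_perm + 1)`. The normalized score is the observed score divided by
#' the mean null score of the same sign. Sets larger than `max_set_size` are
#' down-sampled reproducibly.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed.
#' @param max_set_size Cap on set size after intersection (default 35000).
#' @param alternative `"greater"` (enrichment toward high stability, the
#'   reported direction) or `"two.sided"`.
#' @return One-row `data.frame`: `set_name`, `es`, `nes`, `p_value`,
#'   `n_perm`, `n_overlap`.
#' @export
permutation_pvalue <- function(stats, set, n_perm = 10000, seed = 1L,
                               weight = 1, max_set_size = 35000,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stop("n_perm must be at least 100")
  set_name <- if (inherits(set, "probe_set")) set$name else NA_character_
  if (inherits(set, "probe_set")) set <- set$probe_ids
  stats <- stats[order(-stats, names(stats))]
  N <- length(stats)
  hits <- which(names(stats) %in% set)
  if (!length(hits)) stop("probe set does not intersect the ranked universe")
  set.seed(as.integer(seed))
  if (length(hits) > max_set_size) hits <- sort(sample(hits, max_set_size))
  s <- length(hits)
  es_obs <- es_from_positions(stats, hits, weight)
  null <- es_null(stats, s, n_perm, weight)
  p <- if (alternative == "greater") {
    (1 + sum(null >= es_obs)) / (n_perm + 1)
  } else {
    (1 + sum(abs(null) >= abs(es_obs))) / (n_perm + 1)
  }
  same_sign <- if (es_obs >= 0) null[null > 0] else null[null < 0]
  nes <- if (length(same_sign)) es_obs / abs(mean(same_sign)) else NA_real_
  data.frame(set_name = set_name, es = es_obs, nes = nes, p_value = p,
             n_perm = as.integer(n_perm), n_overlap = s,
             stringsAsFactors = FALSE)
}

es_null <- function(stats, s, n_perm, weight) {
  N <- length(stats)
  vapply(seq_len(n_perm), function(i) {
    es_from_positions(stats, sort(sample.int(N, s)), weight)
  }, numeric(1))
}

#' Enrichment of many probe sets against a stability ranking
#'
#' @param icc ICC table slice (single scenario) or named statistic vector.
#' @param sets Named list of [probe_set()] objects.
#' @param exclude_below Exclusion threshold for the ranking.
#' @param min_overlap Sets with fewer overlapping probes are skipped
#'   (default 5).
#' @inheritParams permutation_pvalue
#' @return `data.frame` with one row per retained set (plus a `scenario`
#'   column when derivable).
#' @export
run_enrichment <- function(icc, sets, n_perm = 10000, seed = 1L, weight = 1,
                           exclude_below = 0.01, min_overlap = 5,
                           max_set_size = 35000,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  scn <- if (is.data.frame(icc) && length(unique(icc$scenario)) == 1) {
    icc$scenario[1]
  } else NA_character_
  stats <- rank_probes(icc, exclude_below)
  rows <- list()
  for (k in seq_along(sets)) {
    st <- sets[[k]]
    ids <- if (inherits(st, "probe_set")) st$probe_ids else st
    if (sum(names(stats) %in% ids) < min_overlap) next
    row <- permutation_pvalue(stats, st, n_perm = n_perm,
                              seed = as.integer(seed) + k, weight = weight,
                              max_set_size = max_set_size,
                              alternative = alternative)
    if (is.na(row$set_name)) row$set_name <- names(sets)[k]
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$scenario <- scn
  out
}
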