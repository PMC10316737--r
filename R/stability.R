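#' Descriptive statistics of a scenario's stability distribution
#'
#' Mean, SD, median, skewness and excess kurtosis of the included ICC values.
#' Probes with ICC below `exclude_below` (default 0.01; non-converged probes
#' carry ICC 0 and therefore fall in this bin) are excluded from the moments
#' and counted separately. Skewness is the bias-corrected Fisher-Pearson
#' statistic `G1 = g1 * sqrt(n (n-1)) / (n - 2)` and kurtosis is the
#' bias-corrected excess `G2 = ((n + 1) g2 + 6) (n - 1) / ((n - 2)(n - 3))`,
#' where `g1 = m3 / m2^(3/2)` and `g2 = m4 / m2^2 - 3` are the moment ratios.
#' A zero-variance sample has skewness and kurtosis 0 by convention.
#'
#' @param icc Numeric vector of ICC values, or an ICC table `data.frame`
#'   (uses `icc21`; `scenario` is propagated when unique).
#' @param exclude_below Exclusion threshold; strict `<`.
#' @return One-row `data.frame`: `scenario`, `mean`, `sd`, `median`, `skew`,
#'   `kurtosis`, `n_included`, `n_excluded_low`.
#' @export
summarize_stability <- function(icc, exclude_below = 0.01) {
  scn <- NA_character_
  if (is.data.frame(icc)) {
    if (length(unique(icc$scenario)) == 1) scn <- icc$scenario[1]
    icc <- icc$icc21
  }
  if (!length(icc)) stop("empty ICC slice")
  inc <- icc[icc >= exclude_below]
  if (!length(inc)) stop("all probes excluded at threshold ", exclude_below)
  data.frame(
    scenario = scn,
    mean = mean(inc), sd = stats::sd(inc), median = stats::median(inc),
    skew = moment_skewness(inc), kurtosis = moment_kurtosis(inc),
    n_included = length(inc), n_excluded_low = sum(icc < exclude_below),
    stringsAsFactors = FALSE
  )
}

moment_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-14 || n < 3) return(0)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

moment_kurtosis <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-14 || n < 4) return(0)
  g2 <- mean((x - mean(x))^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Stratify probes into standard stability bins
#'
#' Bins: `ICC < 0.01`, `[0.01, 0.50)`, `[0.50, 0.75)`, `[0.75, 0.90)` and
#' `[0.90, 1]`. Boundaries are half-open with exactly 0.01 included in the
#' second bin (the exclusion rule is "less than 0.01").
#'
#' @inheritParams summarize_stability
#' @return `data.frame` with `bin`, `count`, `percent` (summing to 100).
#' @export
bin_stability <- function(icc) {
  if (is.data.frame(icc)) icc <- icc$icc21
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) stop("ICC values must lie in [0, 1]")
  breaks <- c(-Inf, 0.01, 0.50, 0.75, 0.90, Inf)
  labels <- c("<0.01", "0.01-0.50", "0.50-0.75", "0.75-0.90", ">0.90")
  cuts <- cut(icc, breaks = breaks, labels = labels, right = FALSE)
  counts <- as.integer(table(cuts))
  data.frame(bin = labels, count = counts,
             percent = 100 * counts / length(icc),
             stringsAsFactors = FALSE)
}

#' Paired comparison of two matched stability vectors
#'
#' Reports the mean paired difference (the "beta" of scenario contrasts) and
#' the two-sided paired t-test p-value. The inputs must be matched per probe
#' (same probes, same order or named).
#'
#' @param iccA,iccB Matched numeric vectors (optionally named by probe).
#' @return List with `beta` (mean of A - B), `t`, `df`, `p_value`, `n`.
#' @export
compare_paired <- function(iccA, iccB) {
  if (!is.null(names(iccA)) && !is.null(names(iccB))) {
    shared <- intersect(names(iccA), names(iccB))
    iccA <- iccA[shared]; iccB <- iccB[shared]
  }
  if (length(iccA) != length(iccB)) stop("paired vectors must have equal length")
  if (length(iccA) < 2) stop("need at least 2 shared probes")
  d <- iccA - iccB
  if (stats::sd(d) < 1e-14) {
    # degenerate constant difference: t-test undefined
    message("compare_paired: zero-variance paired differences")
    beta <- mean(d)
    return(list(beta = beta, t = if (beta == 0) 0 else Inf * sign(beta),
                df = length(d) - 1,
                p_value = if (beta == 0) 1 else 0, n = length(d)))
  }
  tt <- stats::t.test(iccA, iccB, paired = TRUE)
  list(beta = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, n = length(d))
}

#' Chi-square test on low-stability probe counts
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of probes
#' with ICC below the exclusion threshold versus the rest, across two
#' scenarios or groups.
#'
#' @param countsA,countsB Length-2 integer vectors `(n_low, n_rest)`.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
low_icc_chisq <- function(countsA, countsB) {
  stopifnot(length(countsA) == 2, length(countsB) == 2)
  tab <- rbind(A = countsA, B = countsB)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined with a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}

#' Count probes below the exclusion threshold
#'
#' @inheritParams summarize_stability
#' @return Length-2 integer vector `(n_low, n_rest)` for [low_icc_chisq()].
#' @export
low_icc_counts <- function(icc, exclude_below = 0.01) {
  if (is.data.frame(icc)) icc <- icc$icc21
  c(n_low = sum(icc < exclude_below), n_rest = sum(icc >= exclude_below))
}

#' Pairwise Pearson correlation of scenario stability profiles
#'
#' For each pair of scenarios, the correlation is computed over probes whose
#' ICC passes the exclusion threshold in both members of the pair.
#'
#' @param icc_table Long ICC table from [compute_scenario_icc()].
#' @param value Column to correlate (default `"icc21"`).
#' @param exclude_below Exclusion threshold applied per pair.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
scenario_correlations <- function(icc_table, value = "icc21",
                                  exclude_below = 0.01) {
  wide <- icc_wide(icc_table, value)
  ns <- ncol(wide)
  if (ns < 2) stop("need at least 2 scenarios")
  r <- diag(1, ns)
  dimnames(r) <- list(colnames(wide), colnames(wide))
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      ok <- wide[, a] >= exclude_below & wide[, b] >= exclude_below &
        !is.na(wide[, a]) & !is.na(wide[, b])
      if (sum(ok) < 3) stop("fewer than 3 shared included probes for a pair")
      r[a, b] <- r[b, a] <- stats::cor(wide[ok, a], wide[ok, b])
    }
  }
  r
}

icc_wide <- function(icc_table, value = "icc21") {
  stopifnot(all(c("probe_id", "scenario", value) %in% names(icc_table)))
  scns <- unique(icc_table$scenario)
  probes <- unique(icc_table$probe_id)
  wide <- matrix(NA_real_, length(probes), length(scns),
                 dimnames = list(probes, scns))
  wide[cbind(match(icc_table$probe_id, probes),
             match(icc_table$scenario, scns))] <- icc_table[[value]]
  wide
}

#' Hierarchically cluster test-retest scenarios
#'
#' Scenarios are clustered on their per-probe stability profiles (probes
#' passing the exclusion threshold in every scenario) using Euclidean
#' distance and complete linkage.
#'
#' @inheritParams scenario_correlations
#' @return An `hclust` tree over scenarios.
#' @export
cluster_scenarios <- function(icc_table, value = "icc21",
                              exclude_below = 0.01) {
  wide <- icc_wide(icc_table, value)
  if (ncol(wide) < 2) stop("need at least 2 scenarios")
  keep <- rowSums(is.na(wide)) == 0 & apply(wide >= exclude_below, 1, all)
  wide <- wide[keep, , drop = FALSE]
  if (nrow(wide) < 2) stop("too few probes shared across scenarios")
  stats::hclust(stats::dist(t(wide), method = "euclidean"), method = "complete")
}

#' Newick rendering of a scenario tree
#'
#' @param tree An `hclust` result from [cluster_scenarios()].
#' @return Single-element character vector with the Newick string.
#' @export
scenario_tree_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Stability from subject subsamples
#'
#' Recomputes a scenario's ICC table from `n_sub` randomly drawn subjects.
#' With `per_probe_resample = TRUE` an independent subject subsample is drawn
#' for every probe, so no single draw drives the resulting distribution.
#'
#' @inheritParams compute_scenario_icc
#' @param scenario_name A scenario catalog name or [scenario()] object.
#' @param n_sub Number of subjects to draw (default 14).
#' @param per_probe_resample Draw an independent subsample per probe?
#' @param seed Integer seed; identical seeds give identical tables.
#' @return ICC table `data.frame` as from [compute_scenario_icc()].
#' @export
subsample_icc <- function(beta, sheet, scenario_name, n_sub = 14,
                          per_probe_resample = FALSE, seed = 1L,
                          adjust = TRUE, include_batch = TRUE, probes = NULL) {
  sc <- if (is.character(scenario_name)) {
    scenario_catalog(scenario_name)[[1]]
  } else scenario_name
  design <- scenario_design(sheet, sc, colnames(beta))
  subjects <- unique(design$subject_id)
  if (n_sub > length(subjects)) stop("n_sub exceeds available subjects")
  if (is.null(probes)) probes <- rownames(beta)
  set.seed(as.integer(seed))
  if (!per_probe_resample) {
    take <- sample(subjects, n_sub)
    d <- design[design$subject_id %in% take, , drop = FALSE]
    return(fit_probe_block(beta[probes, d$sample_id, drop = FALSE],
                           d, sc, adjust, include_batch))
  }
  rows <- vector("list", length(probes))
  for (i in seq_along(probes)) {
    take <- sample(subjects, n_sub)
    d <- design[design$subject_id %in% take, , drop = FALSE]
    rows[[i]] <- fit_probe_block(beta[probes[i], d$sample_id, drop = FALSE],
                                 d, sc, adjust, include_batch)
  }
  do.call(rbind, rows)
}

#' Stratified stability by subject group
#'
#' Computes a scenario's ICC tables separately for two subject groups (e.g.,
#' ELA versus control), and compares them with a paired t-test on probes
#' included in both groups plus a chi-square test on low-stability counts.
#'
#' @inheritParams compute_scenario_icc
#' @param scenario_name A scenario catalog name or [scenario()] object.
#' @param group_field Sample-sheet column holding the grouping (default
#'   `"group"`); must have exactly two levels.
#' @param exclude_below Inclusion threshold for the paired comparison.
#' @return List with per-group ICC tables (named by level), `comparison`
#'   ([compare_paired()] on group1 - group2) and `low_icc_test`
#'   ([low_icc_chisq()]).
#' @export
stratify_by_group <- function(beta, sheet, scenario_name,
                              group_field = "group", exclude_below = 0.01,
                              adjust = TRUE, include_batch = TRUE,
                              probes = NULL) {
  levels <- sort(unique(sheet[[group_field]]))
  if (length(levels) != 2) stop("group_field must have exactly two levels")
  tabs <- lapply(levels, function(g) {
    sub <- sheet[sheet[[group_field]] == g, , drop = FALSE]
    if (length(unique(sub$subject_id)) < 2) {
      stop("group '", g, "' has fewer than 2 subjects")
    }
    compute_scenario_icc(beta, sub, scenario_name, adjust = adjust,
                         include_batch = include_batch, probes = probes)
  })
  names(tabs) <- levels
  a <- stats::setNames(tabs[[1]]$icc21, tabs[[1]]$probe_id)
  b <- stats::setNames(tabs[[2]]$icc21, tabs[[2]]$probe_id)
  shared <- intersect(names(a)[a >= exclude_below], names(b)[b >= exclude_below])
  cmp <- compare_paired(a[shared], b[shared])
  chs <- low_icc_chisq(low_icc_counts(tabs[[1]], exclude_below),
                       low_icc_counts(tabs[[2]], exclude_below))
  c(tabs, list(comparison = cmp, low_icc_test = chs))
}
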