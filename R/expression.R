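#' CPM expression filter
#'
#' Counts per million are `count / library_size * 1e6` with library size the
#' column sum. A gene is retained when its CPM exceeds `cpm_cut` in at least
#' `frac` of the samples.
#'
#' @param counts Non-negative integer count matrix (genes x samples).
#' @param cpm_cut CPM threshold (default 1; strict `>`).
#' @param frac Minimum fraction of samples above threshold (default 0.90,
#'   inclusive).
#' @return Character vector of retained gene IDs.
#' @export
cpm_filter <- function(counts, cpm_cut = 1, frac = 0.90) {
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("zero library size in counts matrix")
  cpm <- sweep(counts, 2, libs / 1e6, `/`)
  keep <- rowMeans(cpm > cpm_cut) >= frac
  rownames(counts)[keep]
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values between-sample normalization factors with the
#' published parameters (30% trim on log-ratios, 5% on average intensity,
#' precision weighting; reference column chosen by upper-quartile
#' proximity). Factors multiply to geometric mean 1.
#'
#' @param counts Count matrix (genes x samples), ideally after
#'   [cpm_filter()].
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(counts) <= 0)) stop("all-zero sample in counts matrix")
  dge <- edgeR::calcNormFactors(edgeR::DGEList(counts = counts), method = "TMM")
  stats::setNames(dge$samples$norm.factors, colnames(counts))
}

#' Normalized log2 expression matrix
#'
#' Applies the CPM filter, TMM normalization, and the log2-CPM transform
#' (with a small prior count to keep values finite for occasional zeros).
#'
#' @inheritParams cpm_filter
#' @param prior_count Pseudo-count added before the log (default 0.5).
#' @return Matrix of log2 TMM-normalized CPM (filtered genes x samples).
#' @export
normalize_expression <- function(counts, cpm_cut = 1, frac = 0.90,
                                 prior_count = 0.5) {
  keep <- cpm_filter(counts, cpm_cut, frac)
  if (!length(keep)) stop("no genes pass the CPM filter")
  dge <- edgeR::calcNormFactors(
    edgeR::DGEList(counts = counts[keep, , drop = FALSE]), method = "TMM")
  edgeR::cpm(dge, log = TRUE, prior.count = prior_count)
}

#' Correlate TSS-probe methylation with gene expression
#'
#' Pearson correlation of per-sample paired observations for each probe-gene
#' pair, on the M-value scale by default (the statistical-testing scale);
#' two-sided p-values from the t-distribution with `n - 2` degrees of
#' freedom. Pairs are classified as significantly expression-associated at
#' `alpha` (uncorrected).
#'
#' @param meth Methylation matrix (probes x samples), beta-values.
#' @param expr Expression matrix (genes x samples), e.g.
#'   [normalize_expression()] output.
#' @param map `data.frame` with columns `probe_id`, `gene_id` giving the
#'   TSS probe-to-gene pairs to test.
#' @param scale `"M"` (default) or `"beta"`.
#' @param alpha Significance level for the partition (default 0.05).
#' @return `data.frame`: `probe_id`, `gene_id`, `r`, `p_value`,
#'   `significant`, `n` (paired samples).
#' @export
correlate_probe_expression <- function(meth, expr, map,
                                       scale = c("M", "beta"), alpha = 0.05) {
  scale <- match.arg(scale)
  stopifnot(all(c("probe_id", "gene_id") %in% names(map)))
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(samples) < 3) stop("need at least 3 paired samples")
  map <- map[map$probe_id %in% rownames(meth) & map$gene_id %in% rownames(expr), ,
             drop = FALSE]
  if (!nrow(map)) stop("no probe-gene pairs present in both matrices")
  mm <- meth[map$probe_id, samples, drop = FALSE]
  if (scale == "M") mm <- beta_to_m(mm)
  ee <- expr[map$gene_id, samples, drop = FALSE]
  n <- length(samples)
  vm <- apply(mm, 1, stats::var)
  ve <- apply(ee, 1, stats::var)
  if (any(vm < 1e-14) || any(ve < 1e-14)) {
    stop("zero variance in a methylation or expression vector")
  }
  r <- vapply(seq_len(nrow(map)),
              function(i) stats::cor(mm[i, ], ee[i, ]), numeric(1))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(probe_id = map$probe_id, gene_id = map$gene_id,
             r = r, p_value = p, significant = p < alpha, n = n,
             stringsAsFactors = FALSE)
}

#' Expression-linked probe sets
#'
#' Splits the tested TSS probes into the "expression-correlated" and
#' "expression-uncorrelated" sets (a partition), for use as enrichment
#' inputs.
#'
#' @param corr Result of [correlate_probe_expression()].
#' @return Named list of two [probe_set()] objects.
#' @export
expression_probe_sets <- function(corr) {
  list(
    expression_correlated = probe_set(
      "expression_correlated", corr$probe_id[corr$significant],
      source_tag = "expression_linked"),
    expression_uncorrelated = probe_set(
      "expression_uncorrelated", corr$probe_id[!corr$significant],
      source_tag = "expression_linked")
  )
}
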