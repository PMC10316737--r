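#' Sample-level detection p-value filter
#'
#' A sample is retained when its mean detection p-value over all probes is
#' strictly below `threshold`. This is the first quality filter; probe
#' filtering ([filter_probes()]) is applied afterwards on the retained
#' samples.
#'
#' @param detp Detection p-value matrix (probes x samples).
#' @param threshold Mean detection p cut-off (default 0.05); strict `<`.
#' @return Character vector of retained sample IDs.
#' @export
filter_samples <- function(detp, threshold = 0.05) {
  if (!is.matrix(detp) || nrow(detp) == 0L || ncol(detp) == 0L) {
    stop("detection p-value matrix is empty")
  }
  stopifnot(threshold > 0, threshold < 1)
  keep <- colMeans(detp, na.rm = TRUE) < threshold
  colnames(detp)[keep]
}

#' Probe-level detection and sex-chromosome filter
#'
#' Removes probes whose detection p-value exceeds `p_cut` in strictly more
#' than `frac_cut` of samples, and all probes annotated to chromosomes X or Y.
#' Cross-hybridizing and SNP-overlapping probes are deliberately not masked.
#'
#' @param detp Detection p-value matrix (probes x samples), typically already
#'   restricted to samples passing [filter_samples()].
#' @param ann Probe annotation with `probe_id` and `chromosome` columns
#'   covering every probe in `detp`.
#' @param p_cut Per-observation detection p cut-off (default 0.05); strict `>`
#'   counts as a failure.
#' @param frac_cut Maximum tolerated failure fraction (default 0.10); strict
#'   `>` removes the probe.
#' @return Character vector of retained probe IDs.
#' @export
filter_probes <- function(detp, ann, p_cut = 0.05, frac_cut = 0.10) {
  stopifnot(is.matrix(detp), p_cut > 0, p_cut < 1, frac_cut > 0, frac_cut < 1)
  probes <- rownames(detp)
  miss <- setdiff(probes, ann$probe_id)
  if (length(miss)) {
    stop("annotation missing ", length(miss), " probe(s), e.g. ", miss[1])
  }
  fail_frac <- rowMeans(detp > p_cut, na.rm = TRUE)
  chrom <- ann$chromosome[match(probes, ann$probe_id)]
  keep <- fail_frac <= frac_cut & !chrom %in% c("chrX", "chrY")
  probes[keep]
}

#' Apply the full quality-control filter chain
#'
#' Samples are filtered first on mean detection p-value, then probes are
#' filtered on per-probe failure fraction (computed over the retained samples)
#' and sex-chromosome membership. The order is fixed; the operation is
#' idempotent.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param detp Detection p-value matrix of identical shape.
#' @param sheet Sample sheet; subset to retained samples in the result.
#' @param ann Probe annotation.
#' @inheritParams filter_samples
#' @inheritParams filter_probes
#' @return List with filtered `beta`, `detp`, `sheet` and the retained
#'   `samples` and `probes` ID vectors.
#' @export
apply_qc_filters <- function(beta, detp, sheet, ann,
                             threshold = 0.05, p_cut = 0.05, frac_cut = 0.10) {
  stopifnot(identical(dim(beta), dim(detp)),
            identical(colnames(beta), colnames(detp)),
            identical(rownames(beta), rownames(detp)))
  samples <- filter_samples(detp, threshold)
  probes <- filter_probes(detp[, samples, drop = FALSE], ann, p_cut, frac_cut)
  list(
    beta = beta[probes, samples, drop = FALSE],
    detp = detp[probes, samples, drop = FALSE],
    sheet = sheet[sheet$sample_id %in% samples, , drop = FALSE],
    samples = samples,
    probes = probes
  )
}
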