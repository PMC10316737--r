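#' Convert methylation beta-values to M-values
#'
#' The M-value is the logit2 transform `log2(beta / (1 - beta))`. Beta-values
#' are bounded methylation fractions and are strongly heteroscedastic near 0
#' and 1; M-values are approximately homoscedastic and are the preferred scale
#' for per-probe statistical testing.
#'
#' Values of exactly 0 or 1 would map to infinite M-values, so betas are first
#' clipped into `[eps, 1 - eps]`.
#'
#' @param beta Numeric vector, matrix or array of beta-values in `[0, 1]`.
#' @param eps Clipping bound applied before the transform (default `1e-6`).
#' @return Object of the same shape with M-values.
#' @seealso [m_to_beta()]
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0 and 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (!is.null(dim(beta))) {
    dim(out) <- dim(beta)
    dimnames(out) <- dimnames(beta)
  }
  out
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (2^M + 1)`. Always strictly inside
#' `(0, 1)` for finite M.
#'
#' @param m Numeric vector, matrix or array of M-values.
#' @return Object of the same shape with beta-values.
#' @export
m_to_beta <- function(m) {
  # plogis on the natural scale avoids overflow of 2^M for large |M|
  out <- stats::plogis(m * log(2))
  if (!is.null(dim(m))) {
    dim(out) <- dim(m)
    dimnames(out) <- dimnames(m)
  }
  out
}
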