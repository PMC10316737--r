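#' Select highly stable TSS probes
#'
#' A probe qualifies when its (adjusted) ICC(2,1) is at or above `threshold`
#' in every one of the five NoStress scenarios and CrossSessionT1, with a
#' converged fit in each, and the probe lies in a gene transcription start
#' site.
#'
#' @param icc_table Long ICC table covering all six required scenarios.
#' @param ann Probe annotation with `feature_class`.
#' @param threshold Minimum ICC (default 0.90, inclusive).
#' @param scenarios Names of the required scenarios (default: all NoStress
#'   scenarios plus CrossSessionT1).
#' @return Character vector of selected probe IDs.
#' @export
select_highly_stable <- function(icc_table, ann, threshold = 0.90,
                                 scenarios = c("NoStressT1-2", "NoStressT1-3",
                                               "NoStressT1-4", "NoStressT3-4",
                                               "NoStressT1-2-3-4",
                                               "CrossSessionT1")) {
  have <- unique(icc_table$scenario)
  miss <- setdiff(scenarios, have)
  if (length(miss)) stop("missing scenario table(s): ", paste(miss, collapse = ", "))
  sub <- icc_table[icc_table$scenario %in% scenarios, , drop = FALSE]
  ok <- sub$icc21 >= threshold & sub$converged
  n_ok <- tapply(ok, sub$probe_id, sum)
  n_scn <- tapply(ok, sub$probe_id, length)
  stable <- names(n_ok)[n_ok == length(scenarios) & n_scn == length(scenarios)]
  tss <- ann$probe_id[ann$feature_class == "TSS"]
  sort(intersect(stable, tss))
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (here, number of highly stable probes tested).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Repeated-measures stress-effect model for a block of probes
#'
#' Tests, within the Stress session, whether probe values at T2, T3 and T4
#' differ from the T1 baseline, controlling for monocyte proportion and for
#' batch. Each probe follows a repeated-measures ANOVA: timepoint as a
#' categorical factor (T1 reference), subject as a blocking factor
#' (sum-coded, so the intercept is the average subject's adjusted T1 level),
#' and the centred monocyte proportion as covariate. Batch is constant
#' within subject and is therefore controlled exactly by the subject
#' blocking. All probes share the design matrix, so the whole block is
#' fitted in a single multi-response least-squares pass; `method = "lmer"`
#' fits the equivalent subject-random-intercept model per probe instead
#' (with batch as an explicit fixed effect).
#'
#' @param y Matrix (probes x samples) on the chosen scale, restricted to
#'   Stress-session samples of `sheet`.
#' @param sheet Sample sheet rows matching `colnames(y)` (Stress session).
#' @param method `"anova"` (blocked multi-response least squares, default)
#'   or `"lmer"`.
#' @return `data.frame` with one row per probe x contrast: `probe_id`,
#'   `contrast` (`T2`/`T3`/`T4`), `intercept`, `estimate`, `std_error`,
#'   `p_value`.
#' @export
fit_stress_model <- function(y, sheet, method = c("anova", "lmer")) {
  method <- match.arg(method)
  stopifnot(is.matrix(y))
  sheet <- sheet[match(colnames(y), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sheet does not cover all columns of y")
  tps <- sort(unique(sheet$timepoint))
  if (!"T1" %in% tps || length(tps) < 2) {
    stop("need T1 plus at least one later timepoint")
  }
  n_per <- table(sheet$subject_id)
  if (sum(n_per >= 2) < 2) stop("need at least 2 subjects with repeated measures")
  contrasts <- setdiff(tps, "T1")
  if (method == "anova") {
    fit_stress_anova(y, sheet, contrasts)
  } else {
    fit_stress_lmer(y, sheet, contrasts)
  }
}

fit_stress_anova <- function(y, sheet, contrasts) {
  subj <- factor(sheet$subject_id)
  tp <- factor(sheet$timepoint, levels = sort(unique(sheet$timepoint)))
  mono <- sheet$monocyte_proportion - mean(sheet$monocyte_proportion)
  X <- stats::model.matrix(
    ~ tp + subj + mono,
    contrasts.arg = list(subj = "contr.sum", tp = "contr.treatment"))
  fit <- stats::lm.fit(X, t(y))
  if (fit$rank < ncol(X)) stop("rank-deficient stress design")
  cf <- fit$coefficients
  if (is.null(dim(cf))) {
    cf <- matrix(cf, ncol = 1, dimnames = list(names(cf), rownames(y)))
  }
  df <- nrow(X) - fit$rank
  rss <- colSums(as.matrix(fit$residuals)^2)
  sigma2 <- rss / df
  degenerate <- sigma2 < 1e-20    # numerically constant probes
  xtx_inv_diag <- diag(solve(crossprod(X)))
  names(xtx_inv_diag) <- colnames(X)
  rows <- lapply(contrasts, function(ct) {
    cn <- paste0("tp", ct)
    est <- cf[cn, ]
    se <- sqrt(sigma2 * xtx_inv_diag[cn])
    tstat <- ifelse(degenerate, 0, est / pmax(se, 1e-300))
    data.frame(probe_id = rownames(y), contrast = ct,
               intercept = cf["(Intercept)", ],
               estimate = est, std_error = se,
               p_value = ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

fit_stress_lmer <- function(y, sheet, contrasts) {
  dat <- data.frame(
    subject_id = factor(sheet$subject_id),
    tp = factor(sheet$timepoint, levels = sort(unique(sheet$timepoint))),
    mono = sheet$monocyte_proportion - mean(sheet$monocyte_proportion),
    batch = factor(sheet$batch)
  )
  rhs <- if (nlevels(dat$batch) > 1) "tp + mono + batch" else "tp + mono"
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | subject_id)"))
  rows <- lapply(seq_len(nrow(y)), function(i) {
    dat$.y <- y[i, ]
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    sm <- summary(fit)$coefficients
    lapply(contrasts, function(ct) {
      cn <- paste0("tp", ct)
      est <- sm[cn, "Estimate"]; se <- sm[cn, "Std. Error"]
      data.frame(probe_id = rownames(y)[i], contrast = ct,
                 intercept = sm["(Intercept)", "Estimate"],
                 estimate = est, std_error = se,
                 p_value = 2 * stats::pnorm(-abs(est / max(se, 1e-300))),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

#' Stress-effect analysis of highly stable TSS probes
#'
#' Runs the repeated-measures stress model on the Stress-session samples for
#' the supplied probes, on both scales: the M-value model supplies the
#' p-values (approximately homoscedastic scale) and the beta-value model the
#' parallel effect sizes. Significance is flagged at the Bonferroni
#' threshold `alpha / m` with `m` the number of probes tested.
#'
#' @param beta Beta-value matrix (probes x samples, full cohort).
#' @param sheet Sample sheet.
#' @param probes Probe IDs to test (typically [select_highly_stable()]).
#' @param ann Probe annotation (for gene symbols).
#' @param alpha Family-wise error rate (default 0.05).
#' @inheritParams fit_stress_model
#' @return `data.frame` sorted by p-value with columns `probe_id`,
#'   `gene_symbol`, `contrast`, `beta_intercept`, `beta_estimate`,
#'   `m_intercept`, `m_estimate`, `p_value`, `bonferroni_significant`,
#'   plus attributes `m_tests` and `threshold`.
#' @export
run_stress_analysis <- function(beta, sheet, probes, ann, alpha = 0.05,
                                method = c("anova", "lmer")) {
  method <- match.arg(method)
  if (!length(probes)) stop("no probes to test")
  sub <- sheet[sheet$session == "Stress", , drop = FALSE]
  cols <- intersect(colnames(beta), sub$sample_id)
  b <- beta[probes, cols, drop = FALSE]
  m <- beta_to_m(b)
  res_m <- fit_stress_model(m, sub, method = method)
  res_b <- fit_stress_model(b, sub, method = method)
  key <- paste(res_m$probe_id, res_m$contrast)
  stopifnot(identical(key, paste(res_b$probe_id, res_b$contrast)))
  thr <- bonferroni_threshold(alpha, length(probes))
  out <- data.frame(
    probe_id = res_m$probe_id,
    gene_symbol = ann$gene_symbol[match(res_m$probe_id, ann$probe_id)],
    contrast = res_m$contrast,
    beta_intercept = res_b$intercept,
    beta_estimate = res_b$estimate,
    m_intercept = res_m$intercept,
    m_estimate = res_m$estimate,
    p_value = res_m$p_value,
    bonferroni_significant = res_m$p_value < thr,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "m_tests") <- length(probes)
  attr(out, "threshold") <- thr
  out
}
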