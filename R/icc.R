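#' Fit the per-probe two-way crossed random-effects model
#'
#' Fits, by REML, `y ~ covariates + (1 | subject) + (1 | time)` for a single
#' probe: subject and timepoint are crossed random effects, the monocyte
#' proportion enters as a fixed covariate when `adjust = TRUE`, and batch
#' (array) enters as a categorical fixed effect whenever more than one batch
#' is present (stability calculations control for array throughout;
#' "adjusted" toggles only the cell-proportion covariate).
#'
#' Non-negativity of the variance components is guaranteed by lme4's
#' standard-deviation parameterization. Boundary (singular) fits, such as a
#' timepoint variance estimated at zero, are legitimate REML optima and are
#' reported as converged; `converged = FALSE` marks optimizer failure or a
#' numerically constant response.
#'
#' @param y Numeric response vector, one value per design row (beta-values
#'   for stability calculations).
#' @param design `data.frame` with columns `subject_id`, `time` (factor of
#'   repeated-measurement levels), `monocyte_proportion` and `batch`.
#' @param adjust Include the monocyte covariate?
#' @param include_batch Include batch as fixed effect when >1 level (default
#'   TRUE).
#' @return Object of class `"variance_components"`: `sigma2_omega` (subject),
#'   `sigma2_nu` (time), `sigma2_eps` (residual), `beta0`, `beta1` (monocyte,
#'   NA when unadjusted), `beta2` (named batch coefficients, if any),
#'   `converged`, `n_subjects`, `nt`.
#' @export
fit_probe_model <- function(y, design, adjust = TRUE, include_batch = TRUE) {
  check_icc_design(design)
  if (length(y) != nrow(design)) stop("y must have one value per design row")
  if (!all(is.finite(y)) || stats::var(y) < 1e-12) {
    return(vc_failed(design))
  }
  form <- icc_formula(design, adjust, include_batch)
  fit <- try(suppressMessages(suppressWarnings(
    lme4::lmer(form, data = cbind(design, .y = y), REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  )), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate responses (e.g. zero residual variance) can break the PLS
    # solve; fall back to the closed-form balanced estimator when the model
    # carries no covariates
    has_cov <- adjust || (include_batch && length(unique(design$batch)) > 1)
    fb <- if (has_cov) NULL else anova_fallback(y, design)
    return(if (is.null(fb)) vc_failed(design) else fb)
  }
  vc_from_fit(fit, design, adjust)
}

## balanced-design fallback via the mean-squares estimator (covariate-free)
anova_fallback <- function(y, design) {
  tab <- table(design$subject_id, design$time)
  if (any(tab != 1)) return(NULL)
  Y <- tapply(y, list(design$subject_id, design$time), mean)
  if (anyNA(Y)) return(NULL)
  a <- anova_components(Y)
  structure(
    list(sigma2_omega = a$sigma2_omega, sigma2_nu = a$sigma2_nu,
         sigma2_eps = a$sigma2_eps, beta0 = mean(y), beta1 = NA_real_,
         beta2 = NULL, converged = TRUE,
         n_subjects = nrow(Y), nt = ncol(Y)),
    class = "variance_components"
  )
}

check_icc_design <- function(design) {
  req <- c("subject_id", "time", "monocyte_proportion", "batch")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop("design missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(design$subject_id)) < 2) {
    stop("degenerate design: need at least 2 subjects")
  }
  if (length(unique(design$time)) < 2) {
    stop("degenerate design: need at least 2 repeated-measurement levels")
  }
  invisible(design)
}

icc_formula <- function(design, adjust, include_batch) {
  rhs <- "1"
  if (adjust) rhs <- paste(rhs, "+ monocyte_proportion")
  if (include_batch && length(unique(design$batch)) > 1) {
    rhs <- paste(rhs, "+ batch")
  }
  stats::as.formula(paste(".y ~", rhs, "+ (1 | subject_id) + (1 | time)"))
}

vc_failed <- function(design) {
  structure(
    list(sigma2_omega = 0, sigma2_nu = 0, sigma2_eps = 0,
         beta0 = NA_real_, beta1 = NA_real_, beta2 = NULL,
         converged = FALSE,
         n_subjects = length(unique(design$subject_id)),
         nt = length(unique(design$time))),
    class = "variance_components"
  )
}

vc_from_fit <- function(fit, design, adjust) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  fe <- lme4::fixef(fit)
  opt <- fit@optinfo$conv
  msgs <- opt$lme4$messages
  # optimizer code 0 is clean convergence; -4 (roundoff-limited) arises at
  # degenerate optima such as zero residual variance and is still a usable fit
  converged <- isTRUE(opt$opt %in% c(0, -4)) &&
    (is.null(msgs) || all(grepl("boundary|singular", msgs, ignore.case = TRUE)))
  b2 <- fe[grepl("^batch", names(fe))]
  structure(
    list(sigma2_omega = getv("subject_id"),
         sigma2_nu = getv("time"),
         sigma2_eps = getv("Residual"),
         beta0 = unname(fe["(Intercept)"]),
         beta1 = if (adjust) unname(fe["monocyte_proportion"]) else NA_real_,
         beta2 = if (length(b2)) b2 else NULL,
         converged = converged,
         n_subjects = length(unique(design$subject_id)),
         nt = length(unique(design$time))),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components: omega2=%.4g nu2=%.4g eps2=%.4g converged=%s n=%d nt=%d>\n",
    x$sigma2_omega, x$sigma2_nu, x$sigma2_eps, x$converged, x$n_subjects, x$nt))
  invisible(x)
}

#' ICC from fitted variance components
#'
#' `ICC(2,1) = sigma2_omega / (sigma2_omega + sigma2_nu + sigma2_eps)`;
#' `ICC(2,k) = nt * sigma2_omega / (nt * sigma2_omega + sigma2_nu +
#' sigma2_eps)` with `nt` the number of repeated measurements in the fitted
#' scenario.
#'
#' @param vc A `variance_components` object (or list with the same fields).
#' @param icc_type `"2,1"` or `"2,k"`.
#' @param nt Number of repeated measurements; defaults to `vc$nt`.
#' @return ICC value in `[0, 1]`.
#' @export
icc_from_components <- function(vc, icc_type = c("2,1", "2,k"), nt = vc$nt) {
  icc_type <- match.arg(icc_type)
  true_icc(c(vc$sigma2_omega, vc$sigma2_nu, vc$sigma2_eps), icc_type, nt = nt)
}

#' Balanced two-way ANOVA variance-component estimator
#'
#' Independent closed-form estimator of the crossed-model components from the
#' classical two-way mean squares (subjects x repeated measurements, no
#' replication): `sigma2_eps = MSE`, `sigma2_nu = (MSC - MSE) / n`,
#' `sigma2_omega = (MSR - MSE) / k`. Negative estimates are resolved by
#' hierarchically pooling the offending stratum into the residual, which
#' reproduces the REML optimum at the boundary for balanced data.
#'
#' @param Y Numeric matrix, one row per subject, one column per repeated
#'   measurement (complete and balanced).
#' @return List with `sigma2_omega`, `sigma2_nu`, `sigma2_eps` and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
anova_components <- function(Y) {
  stopifnot(is.matrix(Y), nrow(Y) >= 2, ncol(Y) >= 2, !anyNA(Y))
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ssr <- k * sum((rowMeans(Y) - grand)^2)
  ssc <- n * sum((colMeans(Y) - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  dfr <- n - 1; dfc <- k - 1; dfe <- dfr * dfc
  msr <- ssr / dfr; msc <- ssc / dfc; mse <- sse / dfe

  s_eps <- mse
  s_nu <- (msc - mse) / n
  s_omega <- (msr - mse) / k
  if (s_nu < 0) {
    s_nu <- 0
    s_eps <- (sse + ssc) / (dfe + dfc)
    s_omega <- (msr - s_eps) / k
  }
  if (s_omega < 0) {
    s_omega <- 0
    if (s_nu == 0 && (msc - mse) / n < 0) {
      s_eps <- sst / (n * k - 1)
    } else {
      s_eps <- (sse + ssr) / (dfe + dfr)
      s_nu <- max((msc - s_eps) / n, 0)
    }
  }
  list(sigma2_omega = s_omega, sigma2_nu = s_nu, sigma2_eps = s_eps,
       msr = msr, msc = msc, mse = mse)
}

#' Compute per-probe stability for one or more scenarios
#'
#' For every probe and scenario, fits the crossed random-effects model on
#' beta-values (the stability scale) and reports ICC(2,1) and ICC(2,k).
#' Probes whose model cannot be fitted (constant beta, optimizer failure)
#' are assigned ICC 0 and flagged `converged = FALSE`, which places them in
#' the ICC < 0.01 exclusion bin downstream.
#'
#' A template model is fitted once per scenario and refitted per probe, which
#' makes genome-scale loops feasible; probes fall back to a fresh fit when
#' refitting fails.
#'
#' @param beta Beta-value matrix (probes x samples), already quality-filtered.
#' @param sheet Sample sheet covering the matrix columns.
#' @param scenarios `"all"`, a character vector of catalog names, or a list
#'   of [scenario()] objects.
#' @param adjust Include the monocyte covariate (adjusted stability)?
#' @param include_batch Control for batch/array (default TRUE).
#' @param probes Optional subset of probe IDs.
#' @param verbose Report per-scenario convergence-failure counts?
#' @return `data.frame` with columns `probe_id`, `scenario`, `icc21`,
#'   `icc2k`, `adjusted`, `converged`.
#' @export
compute_scenario_icc <- function(beta, sheet, scenarios = "all", adjust = TRUE,
                                 include_batch = TRUE, probes = NULL,
                                 verbose = FALSE) {
  scn <- resolve_scenarios(scenarios)
  if (is.null(probes)) probes <- rownames(beta)
  out <- vector("list", length(scn))
  for (j in seq_along(scn)) {
    sc <- scn[[j]]
    design <- scenario_design(sheet, sc, colnames(beta))
    ymat <- beta[probes, design$sample_id, drop = FALSE]
    res <- fit_probe_block(ymat, design, sc, adjust, include_batch)
    if (verbose) {
      message(sprintf("%s: %d/%d probes failed to converge",
                      sc$name, sum(!res$converged), nrow(res)))
    }
    out[[j]] <- res
  }
  do.call(rbind, out)
}

resolve_scenarios <- function(scenarios) {
  if (is.character(scenarios)) {
    if (identical(scenarios, "all")) scenario_catalog() else scenario_catalog(scenarios)
  } else if (inherits(scenarios, "scenario")) {
    stats::setNames(list(scenarios), scenarios$name)
  } else {
    stats::setNames(scenarios, vapply(scenarios, `[[`, "", "name"))
  }
}

scenario_design <- function(sheet, sc, sample_ids) {
  sub <- scenario_samples(sheet, sc)
  sub <- sub[sub$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("scenario ", sc$name, " references no available samples")
  }
  ## keep subjects with at least two repeated measurements
  keep_subj <- names(which(table(sub$subject_id) >= 2))
  sub <- sub[sub$subject_id %in% keep_subj, , drop = FALSE]
  if (length(unique(sub$subject_id)) < 2 || length(unique(sub$time)) < 2) {
    stop("scenario ", sc$name, ": degenerate design after sample selection")
  }
  sub
}

fit_probe_block <- function(ymat, design, sc, adjust, include_batch) {
  np <- nrow(ymat)
  icc21 <- numeric(np); icc2k <- numeric(np); conv <- logical(np)
  form <- icc_formula(design, adjust, include_batch)
  dat <- design
  dat$.y <- ymat[1L, ]
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  template <- try(suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE, control = ctrl))), silent = TRUE)
  for (i in seq_len(np)) {
    y <- ymat[i, ]
    if (!all(is.finite(y)) || stats::var(y) < 1e-12) next
    fit <- if (!inherits(template, "try-error")) {
      try(suppressMessages(suppressWarnings(lme4::refit(template, newresp = y))),
          silent = TRUE)
    } else template
    if (inherits(fit, "try-error")) {
      dat$.y <- y
      fit <- try(suppressMessages(suppressWarnings(
        lme4::lmer(form, data = dat, REML = TRUE, control = ctrl))), silent = TRUE)
    }
    has_cov <- adjust || (include_batch && length(unique(design$batch)) > 1)
    vc <- if (inherits(fit, "try-error")) {
      if (has_cov) NULL else anova_fallback(y, design)
    } else {
      vc_from_fit(fit, design, adjust)
    }
    if (is.null(vc)) next
    if (!vc$converged) next
    tot <- vc$sigma2_omega + vc$sigma2_nu + vc$sigma2_eps
    if (tot <= 0) next
    icc21[i] <- icc_from_components(vc, "2,1")
    icc2k[i] <- icc_from_components(vc, "2,k", nt = sc$nt)
    conv[i] <- TRUE
  }
  data.frame(probe_id = rownames(ymat), scenario = sc$name,
             icc21 = icc21, icc2k = icc2k,
             adjusted = adjust, converged = conv,
             row.names = NULL, stringsAsFactors = FALSE)
}
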