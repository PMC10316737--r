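#' Simulation configuration for a synthetic methylation cohort
#'
#' Describes a within-person, between-group cohort: every subject attends a
#' `Stress` and a `NoStress` session one week apart with four blood draws per
#' session, and every probe follows the two-way crossed random-effects model
#' on the M-value scale,
#' `y = mu_j + beta1 * monocyte + beta2 * batch + omega_i + nu_t + eps`,
#' so that the true ICC of every probe is analytic from its variance
#' components. Betas are produced by the inverse logit2 transform.
#'
#' Probe classes set the variance-component triples; the defaults give true
#' ICC(2,1) values of 0.95 ("high"), 0.50 ("medium") and 0.20 ("low"), plus a
#' "circadian" class whose instability comes from the shared timepoint effect
#' rather than residual noise.
#'
#' @param n_subjects_per_group Subjects per group (two groups: ELA, control).
#' @param n_probes Number of probes.
#' @param probe_classes `data.frame` with columns `class`, `prop` (mixing
#'   proportions summing to 1), and M-scale variance components
#'   `sigma2_omega` (subject), `sigma2_nu` (timepoint), `sigma2_eps`
#'   (residual).
#' @param monocyte_beta Fixed effect of monocyte proportion, M-units per unit
#'   proportion, applied to every probe.
#' @param batch_beta Fixed batch (array) effect in M-units; batches are
#'   assigned per subject (all 8 replicates share a slide, slides alternate
#'   between the two arrays).
#' @param n_batches Number of arrays/batches (default 2).
#' @param monocyte_mean Cohort mean monocyte proportion.
#' @param monocyte_sd_subject,monocyte_sd_sample Between-subject and
#'   within-subject SD of the monocyte proportion on the logit scale.
#' @param stress_n_probes Number of stress-responsive probes (drawn from
#'   high-stability TSS probes).
#' @param stress_shift Named numeric: M-unit mean shift at `T2`, `T3`, `T4`
#'   applied only in the Stress session to stress-responsive probes.
#' @param stress_sigma_scale Multiplier on `sigma2_eps` in the Stress session
#'   (default 0.8: acute stress exerts a stabilizing influence).
#' @param ela_sigma_scale Multiplier on `sigma2_eps` for ELA subjects in the
#'   Stress session only (default 1.5: lower stability after acute stress).
#' @param baseline_hypo_mean,baseline_hyper_mean,baseline_sd Parameters of the
#'   two-component baseline M-value mixture (hypo- vs hyper-methylated).
#' @param feature_class_props Named proportions of probe feature classes.
#' @param hypo_prob_by_class Named probability that a probe of each feature
#'   class is baseline-hypomethylated.
#' @param mqtl_frac Fraction of probes flagged as mQTL-associated.
#' @param n_fail_samples Number of samples planted to fail the mean
#'   detection-p filter (default 0).
#' @param n_fail_probes Number of probes planted to fail the probe
#'   detection-p filter (default 0).
#' @param frac_sex_probes Fraction of probes placed on chrX/chrY (default 0;
#'   set above 0 to exercise the sex-chromosome filter).
#' @param expr_n_genes Number of genes in the companion count matrix.
#' @param expr_coupled_frac Fraction of TSS probes coupled to a gene's
#'   expression.
#' @param expr_coupling log2-expression units per M-unit of the coupled probe
#'   (negative: TSS methylation represses).
#' @param expr_noise_sd SD of log2-expression noise.
#' @param expr_libsize_meanlog,expr_libsize_sdlog Log-normal library-size
#'   parameters.
#' @param seed Integer seed making [generate_cohort()] fully deterministic.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects_per_group = 15,
                       n_probes = 2000,
                       probe_classes = default_probe_classes(),
                       monocyte_beta = 1,
                       batch_beta = 0.2,
                       n_batches = 2,
                       monocyte_mean = 0.2,
                       monocyte_sd_subject = 0.3,
                       monocyte_sd_sample = 0.25,
                       stress_n_probes = 10,
                       stress_shift = c(T2 = 0, T3 = 0, T4 = -0.2),
                       stress_sigma_scale = 0.8,
                       ela_sigma_scale = 1.5,
                       baseline_hypo_mean = -4,
                       baseline_hyper_mean = 2.5,
                       baseline_sd = 1,
                       feature_class_props = c(TSS = 0.25, `5UTR` = 0.1,
                                               Body = 0.35, `3UTR` = 0.1,
                                               undefined = 0.2),
                       hypo_prob_by_class = c(TSS = 0.9, `5UTR` = 0.8,
                                              Body = 0.3, `3UTR` = 0.4,
                                              undefined = 0.5),
                       mqtl_frac = 0.1,
                       n_fail_samples = 0,
                       n_fail_probes = 0,
                       frac_sex_probes = 0,
                       expr_n_genes = 300,
                       expr_coupled_frac = 0.5,
                       expr_coupling = -1,
                       expr_noise_sd = 0.5,
                       expr_libsize_meanlog = log(1e6),
                       expr_libsize_sdlog = 0.2,
                       seed = 1L) {
  if (n_subjects_per_group < 1) stop("n_subjects_per_group must be positive")
  if (n_probes < 1) stop("n_probes must be positive")
  req <- c("class", "prop", "sigma2_omega", "sigma2_nu", "sigma2_eps")
  stopifnot(all(req %in% names(probe_classes)))
  vc <- as.matrix(probe_classes[, c("sigma2_omega", "sigma2_nu", "sigma2_eps")])
  if (any(vc < 0)) stop("variance components must be non-negative")
  if (abs(sum(probe_classes$prop) - 1) > 1e-8) {
    stop("probe class proportions must sum to 1")
  }
  if (stress_sigma_scale < 0 || ela_sigma_scale < 0) {
    stop("variance multipliers must be non-negative")
  }
  minutes <- c(T1 = 0, T2 = 75, T3 = 135, T4 = 285)
  if (any(diff(minutes) <= 0)) stop("timepoint minutes must be increasing")
  cfg <- as.list(environment())
  cfg$vc <- NULL
  cfg$req <- NULL
  cfg$timepoints <- names(minutes)
  cfg$timepoint_minutes <- minutes
  cfg$sessions <- c("Stress", "NoStress")
  cfg$groups <- c("ELA", "control")
  structure(cfg, class = "sim_config")
}

#' Default probe stability classes
#'
#' True ICC(2,1) is 0.95, 0.50, 0.20 and 0.20 for the high, medium, low and
#' circadian classes respectively; the circadian class owes its instability
#' to the shared timepoint effect. `total_variance` sets the per-probe total
#' M-scale variance (default 0.25, i.e. an M-value SD of 0.5, typical of a
#' variable array probe); ICCs are invariant to this scale.
#'
#' @param total_variance Per-probe total variance on the M scale.
#' @return `data.frame` of class mixing proportions and M-scale variance
#'   components.
#' @export
default_probe_classes <- function(total_variance = 0.25) {
  data.frame(
    class = c("high", "medium", "low", "circadian"),
    prop = c(0.2, 0.4, 0.3, 0.1),
    sigma2_omega = total_variance * c(0.95, 0.50, 0.20, 0.20),
    sigma2_nu = total_variance * c(0.01, 0.05, 0.05, 0.40),
    sigma2_eps = total_variance * c(0.04, 0.45, 0.75, 0.40)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: %d subjects/group x 2 groups, 2 sessions x 4 timepoints, %d probes, seed=%d>\n",
    x$n_subjects_per_group, x$n_probes, as.integer(x$seed)))
  invisible(x)
}

#' True ICC from variance components
#'
#' `ICC(2,1) = sigma2_omega / (sigma2_omega + sigma2_nu + sigma2_eps)` rates a
#' single measurement; `ICC(2,k) = nt * sigma2_omega / (nt * sigma2_omega +
#' sigma2_nu + sigma2_eps)` rates the mean of `nt` repeated measurements.
#'
#' @param components Numeric length-3 vector `(sigma2_omega, sigma2_nu,
#'   sigma2_eps)`, or a matrix with those three columns.
#' @param icc_type `"2,1"` or `"2,k"`.
#' @param nt Number of timepoints (required for `"2,k"`, must be >= 2).
#' @return ICC value(s) in `[0, 1]`.
#' @export
true_icc <- function(components, icc_type = c("2,1", "2,k"), nt = NULL) {
  icc_type <- match.arg(icc_type)
  cm <- if (is.matrix(components)) components else matrix(components, nrow = 1)
  if (ncol(cm) != 3) stop("components must be (sigma2_omega, sigma2_nu, sigma2_eps)")
  if (any(cm < 0)) stop("variance components must be non-negative")
  if (any(rowSums(cm) == 0)) stop("ICC undefined when all components are zero")
  if (icc_type == "2,1") {
    out <- cm[, 1] / rowSums(cm)
  } else {
    if (is.null(nt) || nt < 2) stop("ICC(2,k) requires nt >= 2")
    out <- nt * cm[, 1] / (nt * cm[, 1] + cm[, 2] + cm[, 3])
  }
  unname(out)
}
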