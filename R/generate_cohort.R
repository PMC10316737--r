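#' Generate a synthetic test-retest methylation cohort
#'
#' Draws a complete cohort under the crossed random-effects model described in
#' [sim_config()]: every subject contributes one sample per session x
#' timepoint (up to 8), each probe has class-specific subject, timepoint and
#' residual variance components on the M scale, fixed monocyte and batch
#' effects are added, stress-responsive probes receive mean shifts at late
#' timepoints of the Stress session, and residual variance is rescaled in the
#' Stress session (globally, and additionally for ELA subjects). M-values are
#' converted to beta-values for output. The companion count matrix couples a
#' configurable fraction of TSS probes to gene expression.
#'
#' Identical configurations (including `seed`) give byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"meth_cohort"` with elements `beta` (probes x
#'   samples), `detp` (same shape), `sheet` (sample sheet), `annotation`
#'   (probe annotation), `counts` (genes x samples), and `truth` (ground
#'   truth: per-probe components and true ICCs, stress-responsive probes,
#'   planted detection failures, probe-to-gene coupling).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  cf <- config

  ## ---- design -------------------------------------------------------------
  n_subj <- 2L * cf$n_subjects_per_group
  subjects <- sprintf("S%03d", seq_len(n_subj))
  group <- rep(cf$groups, each = cf$n_subjects_per_group)
  batch <- sprintf("array%d", ((seq_len(n_subj) - 1L) %% cf$n_batches) + 1L)

  sheet <- expand.grid(
    timepoint = cf$timepoints, session = cf$sessions, subject_id = subjects,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("subject_id", "session", "timepoint")]
  si <- match(sheet$subject_id, subjects)
  sheet$sample_id <- paste(sheet$subject_id, sheet$session, sheet$timepoint, sep = "_")
  sheet$batch <- batch[si]
  sheet$group <- group[si]
  n_samp <- nrow(sheet)

  mono_subj <- stats::rnorm(n_subj, stats::qlogis(cf$monocyte_mean),
                            cf$monocyte_sd_subject)
  sheet$monocyte_proportion <- stats::plogis(
    mono_subj[si] + stats::rnorm(n_samp, 0, cf$monocyte_sd_sample))
  sheet <- sheet[, c("sample_id", "subject_id", "session", "timepoint",
                     "batch", "group", "monocyte_proportion")]

  ## ---- probes -------------------------------------------------------------
  np <- cf$n_probes
  probe_ids <- sprintf("cg%06d", seq_len(np))
  cls_n <- round_counts(cf$probe_classes$prop, np)
  probe_class <- rep(cf$probe_classes$class, cls_n)
  vc_idx <- rep(seq_len(nrow(cf$probe_classes)), cls_n)
  s2_omega <- cf$probe_classes$sigma2_omega[vc_idx]
  s2_nu <- cf$probe_classes$sigma2_nu[vc_idx]
  s2_eps <- cf$probe_classes$sigma2_eps[vc_idx]

  feature_class <- sample(names(cf$feature_class_props), np, replace = TRUE,
                          prob = cf$feature_class_props)
  n_sex <- round(cf$frac_sex_probes * np)
  chrom <- sample(paste0("chr", 1:22), np, replace = TRUE)
  if (n_sex > 0) {
    sex_idx <- sample.int(np, n_sex)
    chrom[sex_idx] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE)
  }
  ann <- data.frame(
    probe_id = probe_ids,
    chromosome = chrom,
    position = sample.int(2.4e8, np, replace = TRUE),
    feature_class = feature_class,
    gene_symbol = sprintf("GENE%04d",
                          sample.int(cf$expr_n_genes, np, replace = TRUE)),
    mQTL = stats::runif(np) < cf$mqtl_frac,
    stringsAsFactors = FALSE
  )
  ann$circadian_TSS <- probe_class == "circadian" & feature_class == "TSS"

  ## expression-coupled TSS probes each get a dedicated gene
  tss_idx <- which(feature_class == "TSS")
  n_coupled <- min(round(cf$expr_coupled_frac * length(tss_idx)), cf$expr_n_genes)
  coupled_idx <- if (n_coupled > 0) sort(sample(tss_idx, n_coupled)) else integer(0)
  coupled_genes <- sprintf("GENE%04d", seq_len(n_coupled))
  ann$gene_symbol[coupled_idx] <- coupled_genes

  ## ---- M-value model ------------------------------------------------------
  hypo <- stats::runif(np) < cf$hypo_prob_by_class[feature_class]
  mu <- stats::rnorm(np,
                     ifelse(hypo, cf$baseline_hypo_mean, cf$baseline_hyper_mean),
                     cf$baseline_sd)

  omega <- matrix(stats::rnorm(np * n_subj), np, n_subj) * sqrt(s2_omega)
  cell_levels <- paste(rep(cf$sessions, each = 4L), cf$timepoints, sep = "_")
  nu <- matrix(stats::rnorm(np * length(cell_levels)), np) * sqrt(s2_nu)
  colnames(nu) <- cell_levels

  is_stress <- sheet$session == "Stress"
  eps_scale <- ifelse(is_stress, cf$stress_sigma_scale, 1) *
    ifelse(is_stress & sheet$group == "ELA", cf$ela_sigma_scale, 1)
  eps <- matrix(stats::rnorm(np * n_samp), np, n_samp) *
    sqrt(outer(s2_eps, eps_scale))

  cell_of_sample <- match(paste(sheet$session, sheet$timepoint, sep = "_"),
                          cell_levels)
  M <- mu +
    cf$monocyte_beta * rep(sheet$monocyte_proportion, each = np) +
    cf$batch_beta * rep(match(sheet$batch, unique(batch)) - 1L, each = np) +
    omega[, si, drop = FALSE] + nu[, cell_of_sample, drop = FALSE] + eps
  dim(M) <- c(np, n_samp)

  ## stress-responsive probes: mean shifts in the Stress session only,
  ## drawn from TSS probes of the most stable class (they must survive the
  ## highly-stable selection downstream)
  class_icc <- cf$probe_classes$sigma2_omega /
    (cf$probe_classes$sigma2_omega + cf$probe_classes$sigma2_nu +
       cf$probe_classes$sigma2_eps)
  stable_class <- cf$probe_classes$class[which.max(class_icc)]
  high_tss <- which(probe_class == stable_class & feature_class == "TSS")
  n_sp <- min(cf$stress_n_probes, length(high_tss))
  stress_probes <- if (n_sp > 0) sort(sample(high_tss, n_sp)) else integer(0)
  for (tp in names(cf$stress_shift)) {
    sh <- cf$stress_shift[[tp]]
    if (sh != 0 && length(stress_probes)) {
      cols <- which(is_stress & sheet$timepoint == tp)
      M[stress_probes, cols] <- M[stress_probes, cols] + sh
    }
  }

  beta <- m_to_beta(M)
  dimnames(beta) <- list(probe_ids, sheet$sample_id)

  ## ---- detection p-values -------------------------------------------------
  detp <- matrix(stats::runif(np * n_samp, 0, 0.01), np, n_samp,
                 dimnames = dimnames(beta))
  fail_samples <- character(0)
  if (cf$n_fail_samples > 0) {
    fs <- sample.int(n_samp, min(cf$n_fail_samples, n_samp))
    detp[, fs] <- stats::runif(np * length(fs), 0.2, 1)
    fail_samples <- sheet$sample_id[fs]
  }
  fail_probes <- character(0)
  if (cf$n_fail_probes > 0) {
    fp <- sample.int(np, min(cf$n_fail_probes, np))
    for (p in fp) {
      bad <- sample.int(n_samp, max(2L, ceiling(0.2 * n_samp)))
      detp[p, bad] <- stats::runif(length(bad), 0.06, 1)
    }
    fail_probes <- probe_ids[fp]
  }

  ## ---- expression counts --------------------------------------------------
  genes <- sprintf("GENE%04d", seq_len(cf$expr_n_genes))
  base_l2 <- stats::rnorm(cf$expr_n_genes, 5, 1.5)
  l2cpm <- matrix(base_l2, cf$expr_n_genes, n_samp) +
    matrix(stats::rnorm(cf$expr_n_genes * n_samp, 0, cf$expr_noise_sd),
           cf$expr_n_genes, n_samp)
  if (n_coupled > 0) {
    Mc <- M[coupled_idx, , drop = FALSE]
    l2cpm[seq_len(n_coupled), ] <- l2cpm[seq_len(n_coupled), ] +
      cf$expr_coupling * (Mc - rowMeans(Mc))
  }
  libsize <- stats::rlnorm(n_samp, cf$expr_libsize_meanlog, cf$expr_libsize_sdlog)
  lambda <- sweep(2^l2cpm, 2, libsize / 1e6, `*`)
  counts <- matrix(stats::rpois(length(lambda), lambda), cf$expr_n_genes, n_samp,
                   dimnames = list(genes, sheet$sample_id))

  ## ---- truth --------------------------------------------------------------
  comps <- cbind(s2_omega, s2_nu, s2_eps)
  truth <- list(
    probes = data.frame(
      probe_id = probe_ids, class = probe_class,
      sigma2_omega = s2_omega, sigma2_nu = s2_nu, sigma2_eps = s2_eps,
      icc21 = true_icc(comps, "2,1"),
      icc2k_nt2 = true_icc(comps, "2,k", nt = 2),
      icc2k_nt4 = true_icc(comps, "2,k", nt = 4),
      stringsAsFactors = FALSE
    ),
    stress_probes = data.frame(
      probe_id = probe_ids[stress_probes],
      matrix(rep(unlist(cf$stress_shift), each = length(stress_probes)),
             nrow = length(stress_probes), ncol = length(cf$stress_shift),
             dimnames = list(NULL, names(cf$stress_shift))),
      stringsAsFactors = FALSE, check.names = FALSE
    ),
    stress_sigma_scale = cf$stress_sigma_scale,
    ela_sigma_scale = cf$ela_sigma_scale,
    fail_samples = fail_samples,
    fail_probes = fail_probes,
    coupled_map = data.frame(probe_id = probe_ids[coupled_idx],
                             gene_id = coupled_genes,
                             stringsAsFactors = FALSE)
  )

  structure(list(beta = beta, detp = detp, sheet = sheet, annotation = ann,
                 counts = counts, truth = truth, config = cf),
            class = "meth_cohort")
}

## largest-remainder apportionment of n into proportions p
round_counts <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1L
  }
  as.integer(k)
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("<meth_cohort: %d probes x %d samples, %d subjects, %d genes>\n",
              nrow(x$beta), ncol(x$beta),
              length(unique(x$sheet$subject_id)), nrow(x$counts)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `beta.tsv`, `detp.tsv`, `sample_sheet.csv`, `probe_annotation.csv`,
#' `counts.tsv` and `truth.json` under `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(cohort$detp, file.path(dir, "detp.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.csv"))
  write_probe_annotation(cohort$annotation, file.path(dir, "probe_annotation.csv"))
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"), id_col = "gene_id")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
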