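#' Run the full stability pipeline on a synthetic cohort
#'
#' Chains every stage: cohort simulation, quality filtering, per-probe
#' stability for the requested scenarios, descriptive summaries and bins,
#' probe-set enrichment (reference-sized synthetic sets plus the
#' expression-linked sets), and the stress-effect test on highly stable TSS
#' probes (threshold relaxed to the supplied value so small cohorts retain
#' a testable set). All randomness derives from `seed`; when `outdir` is
#' given, every table is written as TSV/JSON and two runs with the same
#' inputs are byte-identical.
#'
#' @param config A [sim_config()]; its own `seed` is overridden by `seed`.
#' @param seed Integer master seed.
#' @param outdir Optional output directory.
#' @param scenarios Scenario names to fit (default: all ten).
#' @param n_perm Permutations for enrichment (default 1000 for pipeline
#'   runs).
#' @param stable_threshold Highly-stable selection threshold (default 0.90).
#' @return List with `cohort`, `qc`, `icc` (long table), `summary`, `bins`,
#'   `enrichment`, `stress`, `expression` components.
#' @export
run_stability_pipeline <- function(config = sim_config(), seed = 1L,
                                   outdir = NULL, scenarios = "all",
                                   n_perm = 1000, stable_threshold = 0.90) {
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  qc <- apply_qc_filters(cohort$beta, cohort$detp, cohort$sheet,
                         cohort$annotation)

  icc <- compute_scenario_icc(qc$beta, qc$sheet, scenarios, adjust = TRUE)
  scn_names <- unique(icc$scenario)
  summary <- do.call(rbind, lapply(scn_names, function(s) {
    summarize_stability(icc[icc$scenario == s, ])
  }))
  bins <- do.call(rbind, lapply(scn_names, function(s) {
    cbind(scenario = s, bin_stability(icc[icc$scenario == s, ]))
  }))

  ## enrichment against fabricated reference sets + expression-linked sets
  expr <- normalize_expression(cohort$counts[, qc$samples, drop = FALSE])
  map <- cohort$truth$coupled_map
  corr <- correlate_probe_expression(qc$beta, expr, map)
  sets <- c(make_reference_probe_sets(rownames(qc$beta),
                                      seed = as.integer(seed) + 1000L),
            expression_probe_sets(corr))
  enr_scn <- scn_names[1]
  enrichment <- run_enrichment(icc[icc$scenario == enr_scn, ], sets,
                               n_perm = n_perm, seed = as.integer(seed) + 2000L)

  ## stress effects on highly stable TSS probes
  need <- intersect(c("NoStressT1-2", "NoStressT1-3", "NoStressT1-4",
                      "NoStressT3-4", "NoStressT1-2-3-4", "CrossSessionT1"),
                    scn_names)
  stress <- NULL
  if (length(need) >= 1) {
    stable <- select_highly_stable(icc, cohort$annotation,
                                   threshold = stable_threshold,
                                   scenarios = need)
    if (length(stable)) {
      stress <- run_stress_analysis(qc$beta, qc$sheet, stable,
                                    cohort$annotation)
    }
  }

  out <- list(cohort = cohort, qc = qc, icc = icc, summary = summary,
              bins = bins, enrichment = enrichment, stress = stress,
              expression = corr)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    data.table::fwrite(df, file.path(outdir, f), sep = "\t", quote = FALSE)
  }
  wr(res$icc, "icc_table.tsv")
  wr(res$summary, "stability_summary.tsv")
  wr(res$bins, "stability_bins.tsv")
  if (!is.null(res$enrichment)) wr(res$enrichment, "enrichment.tsv")
  if (!is.null(res$stress)) wr(res$stress, "stress_effects.tsv")
  wr(res$expression, "expression_correlation.tsv")
  write_cohort(res$cohort, file.path(outdir, "cohort"))
  invisible(outdir)
}
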