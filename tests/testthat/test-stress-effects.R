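## single-class cohort with planted T4 hypomethylation on TSS probes
stress_cohort <- function() {
  cached("stress", {
    cls <- data.frame(class = "high", prop = 1, sigma2_omega = 0.2375,
                      sigma2_nu = 0, sigma2_eps = 0.0125)
    cfg <- sim_config(n_subjects_per_group = 15, n_probes = 300,
                      probe_classes = cls, stress_n_probes = 25,
                      stress_shift = c(T2 = 0, T3 = 0, T4 = -0.2),
                      stress_sigma_scale = 1, ela_sigma_scale = 1,
                      feature_class_props = c(TSS = 1),
                      hypo_prob_by_class = c(TSS = 0.9), seed = 201)
    generate_cohort(cfg)
  })
}

test_that("highly stable TSS selection enforces every scenario and the feature class", {
  scns <- c("NoStressT1-2", "NoStressT1-3", "NoStressT1-4", "NoStressT3-4",
            "NoStressT1-2-3-4", "CrossSessionT1")
  tab <- expand.grid(probe_id = c("p1", "p2", "p3"), scenario = scns,
                     stringsAsFactors = FALSE)
  tab$icc21 <- 0.95
  tab$converged <- TRUE
  tab$icc21[tab$probe_id == "p2" & tab$scenario == "NoStressT1-4"] <- 0.89
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    feature_class = c("TSS", "TSS", "Body"))
  expect_identical(select_highly_stable(tab, ann), "p1")
  # inclusive threshold: exactly 0.90 qualifies
  tab$icc21[tab$probe_id == "p2" & tab$scenario == "NoStressT1-4"] <- 0.90
  expect_identical(select_highly_stable(tab, ann), c("p1", "p2"))
  # a non-converged fit disqualifies
  tab$converged[tab$probe_id == "p1" & tab$scenario == "CrossSessionT1"] <- FALSE
  expect_identical(select_highly_stable(tab, ann), "p2")
  expect_error(select_highly_stable(tab[tab$scenario != "CrossSessionT1", ], ann),
               "missing scenario")
})

test_that("planted high-stability probes are selected from a synthetic cohort", {
  # class well above the 0.90 threshold (true ICC 0.98) so recall reflects
  # the selection logic rather than estimator spread at the boundary
  cls <- data.frame(class = "vhigh", prop = 1, sigma2_omega = 0.245,
                    sigma2_nu = 0.0005, sigma2_eps = 0.0045)
  cfg <- sim_config(n_subjects_per_group = 15, n_probes = 60,
                    probe_classes = cls, stress_n_probes = 0,
                    feature_class_props = c(TSS = 1),
                    hypo_prob_by_class = c(TSS = 0.9), seed = 203)
  ch <- generate_cohort(cfg)
  qc <- apply_qc_filters(ch$beta, ch$detp, ch$sheet, ch$annotation)
  probes <- rownames(qc$beta)
  scns <- c("NoStressT1-2", "NoStressT1-3", "NoStressT1-4", "NoStressT3-4",
            "NoStressT1-2-3-4", "CrossSessionT1")
  tab <- compute_scenario_icc(qc$beta, qc$sheet, scns, probes = probes)
  sel <- select_highly_stable(tab, ch$annotation, scenarios = scns)
  # all probes are true ICC 0.95 TSS probes; most should be recovered
  expect_gte(length(sel) / length(probes), 0.9)
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("constant probes give zero estimates and p = 1", {
  ch <- stress_cohort()
  sub <- ch$sheet[ch$sheet$session == "Stress", ]
  y <- matrix(0.42, 2, nrow(sub),
              dimnames = list(c("k1", "k2"), sub$sample_id))
  res <- fit_stress_model(y, sub)
  expect_equal(res$estimate, rep(0, 6), tolerance = 1e-12)
  expect_equal(res$p_value, rep(1, 6))
})

test_that("planted T4 shifts are recovered with the right sign and size", {
  ch <- stress_cohort()
  planted <- ch$truth$stress_probes$probe_id
  res <- run_stress_analysis(ch$beta, ch$sheet, rownames(ch$beta),
                             ch$annotation)
  t4 <- res[res$contrast == "T4", ]
  est <- t4$m_estimate[match(planted, t4$probe_id)]
  expect_gte(mean(est < 0), 0.95)                 # sign recovery
  expect_lt(abs(median(est) + 0.2), 0.05)         # size recovery
  # planted probes dominate the Bonferroni-significant list
  sig <- t4$probe_id[t4$bonferroni_significant]
  expect_gte(length(intersect(sig, planted)) / max(length(sig), 1), 0.9)
  expect_gte(length(intersect(sig, planted)) / length(planted), 0.9)
  # no significant shifts at T2/T3 beyond rare false positives
  expect_lte(sum(res$bonferroni_significant[res$contrast != "T4"]), 2)
})

test_that("beta-scale and M-scale estimates agree in sign", {
  ch <- stress_cohort()
  res <- run_stress_analysis(ch$beta, ch$sheet, rownames(ch$beta)[1:80],
                             ch$annotation)
  # sign agreement is a monotone-transform property of material effects;
  # near-zero estimates can flip sign between scales through noise
  material <- abs(res$m_estimate) > 0.05
  expect_true(any(material))
  expect_true(all(sign(res$beta_estimate[material]) ==
                  sign(res$m_estimate[material])))
  # flags are internally consistent with the threshold
  thr <- attr(res, "threshold")
  expect_equal(res$bonferroni_significant, res$p_value < thr)
  expect_equal(thr, 0.05 / 80)
})

test_that("blocked ANOVA and random-intercept fits agree on timepoint contrasts", {
  ch <- stress_cohort()
  sub <- ch$sheet[ch$sheet$session == "Stress", ]
  m <- beta_to_m(ch$beta[1:15, sub$sample_id])
  ra <- fit_stress_model(m, sub, method = "anova")
  rl <- fit_stress_model(m, sub, method = "lmer")
  key <- paste(ra$probe_id, ra$contrast)
  rl <- rl[match(key, paste(rl$probe_id, rl$contrast)), ]
  expect_equal(ra$estimate, rl$estimate, tolerance = 0.01)
  expect_equal(cor(ra$p_value, rl$p_value), 1, tolerance = 0.01)
})

test_that("type-I error is calibrated on null probes", {
  ch <- stress_cohort()
  null_probes <- setdiff(rownames(ch$beta), ch$truth$stress_probes$probe_id)
  res <- run_stress_analysis(ch$beta, ch$sheet, null_probes, ch$annotation)
  t4 <- res[res$contrast == "T4", ]
  expect_lt(abs(mean(t4$p_value < 0.05) - 0.05), 0.035)
  expect_gt(min(t4$p_value), bonferroni_threshold(0.05, nrow(t4)) / 100)
})

test_that("rank-deficient and malformed stress designs error", {
  ch <- stress_cohort()
  sub <- ch$sheet[ch$sheet$session == "Stress", ]
  only_t1 <- sub[sub$timepoint == "T1", ]
  y <- ch$beta[1:2, only_t1$sample_id]
  expect_error(fit_stress_model(y, only_t1), "T1 plus at least one")
  expect_error(run_stress_analysis(ch$beta, ch$sheet, character(0),
                                   ch$annotation), "no probes")
})
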