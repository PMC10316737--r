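test_that("summary moments and exclusion counts are correct", {
  s <- summarize_stability(rep(0.5, 100))
  expect_equal(s$mean, 0.5)
  expect_equal(s$median, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(s$skew, 0)
  expect_equal(s$n_included, 100)

  s2 <- summarize_stability(c(0.005, 0.5, 0.7))
  expect_equal(s2$n_included, 2)
  expect_equal(s2$n_excluded_low, 1)
  expect_equal(s2$mean, 0.6)
  expect_error(summarize_stability(c(0.001, 0.002)), "excluded")
  expect_error(summarize_stability(numeric(0)), "empty")
})

test_that("skewness and kurtosis match the bias-corrected estimators", {
  set.seed(61)
  x <- rbeta(20, 2, 5)
  s <- summarize_stability(x)
  expect_equal(s$skew, e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(s$kurtosis, e1071::kurtosis(x, type = 2), tolerance = 1e-12)
  expect_equal(s$sd, sd(x))
  expect_equal(s$median, median(x))
})

test_that("stability bins follow the printed boundaries", {
  b <- bin_stability(c(0.0, 0.3, 0.6, 0.8, 0.95))
  expect_equal(b$count, rep(1L, 5))
  expect_equal(sum(b$percent), 100)
  b0 <- bin_stability(rep(0, 10))
  expect_equal(b0$percent, c(100, 0, 0, 0, 0))
  # boundary rules: 0.01 is included in the second bin, 0.90 in the top bin
  bb <- bin_stability(c(0.01, 0.5, 0.75, 0.9))
  expect_equal(bb$count, c(0L, 1L, 1L, 1L, 1L))
  expect_error(bin_stability(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binned synthetic cohorts recover the class mix", {
  cls <- data.frame(class = c("low", "mid", "high"), prop = c(0.2, 0.6, 0.2),
                    sigma2_omega = 0.25 * c(0.10, 0.60, 0.95),
                    sigma2_nu = 0.25 * c(0.02, 0.02, 0.01),
                    sigma2_eps = 0.25 * c(0.88, 0.38, 0.04))
  cfg <- plain_config(n_per_group = 50, n_probes = 150, seed = 67,
                      probe_classes = cls)
  ch <- generate_cohort(cfg)
  tab <- compute_scenario_icc(ch$beta, ch$sheet, "NoStressT1-2",
                              adjust = FALSE, include_batch = FALSE)
  b <- bin_stability(tab)
  # high class (ICC .95) should land in the top bin, mid (0.6) in 0.50-0.75
  expect_lt(abs(b$percent[b$bin == ">0.90"] - 20), 8)
  expect_lt(abs(b$percent[b$bin == "0.50-0.75"] - 60), 12)
})

test_that("paired comparison matches the t-test algebra and is antisymmetric", {
  a <- c(0.2, 0.4, 0.5, 0.6, 0.3, 0.7, 0.45, 0.55, 0.35, 0.65)
  b <- c(0.25, 0.38, 0.55, 0.52, 0.33, 0.74, 0.40, 0.60, 0.30, 0.70)
  cmp <- compare_paired(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$beta, mean(d))
  expect_equal(cmp$t, tstat, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(tstat), length(d) - 1), tolerance = 1e-12)
  rev <- compare_paired(b, a)
  expect_equal(rev$beta, -cmp$beta)
  expect_equal(rev$p_value, cmp$p_value)
})

test_that("degenerate paired comparisons are handled by convention", {
  a <- c(0.1, 0.2, 0.3)
  expect_message(cmp <- compare_paired(a, a), "zero-variance")
  expect_equal(cmp$beta, 0)
  expect_equal(cmp$p_value, 1)
  expect_message(cmp2 <- compare_paired(a, a + 0.1), "zero-variance")
  expect_equal(cmp2$beta, -0.1)
  expect_equal(cmp2$p_value, 0)
  expect_error(compare_paired(0.5, 0.5), "at least 2")
  # named vectors are matched on shared probes
  cmp3 <- compare_paired(c(p1 = 0.5, p2 = 0.6, p3 = 0.4),
                         c(p2 = 0.5, p1 = 0.6, p4 = 0.2))
  expect_equal(cmp3$n, 2)
})

test_that("chi-square on low-stability counts matches the hand formula", {
  res <- low_icc_chisq(c(100, 900), c(200, 800))
  O <- rbind(c(100, 900), c(200, 800))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_identical(low_icc_chisq(c(50, 950), c(50, 950))$p_value, 1)
  expect_lt(low_icc_chisq(c(500, 500), c(0, 1000))$p_value, 1e-10)
  expect_error(low_icc_chisq(c(0, 0), c(1, 1)), "zero margin")
  icc <- c(0.005, 0.5, 0.002, 0.9)
  expect_equal(unname(low_icc_counts(icc)), c(2, 2))
})

test_that("scenario correlations use pairwise-included probes", {
  tab <- data.frame(
    probe_id = rep(paste0("p", 1:5), 2),
    scenario = rep(c("A", "B"), each = 5),
    icc21 = c(0.2, 0.4, 0.6, 0.8, 0.9, 0.25, 0.35, 0.65, 0.75, 0.95),
    converged = TRUE
  )
  r <- scenario_correlations(tab)
  expect_equal(r["A", "B"], cor(tab$icc21[1:5], tab$icc21[6:10]), tolerance = 1e-12)
  expect_equal(diag(r), c(A = 1, B = 1))
  # identical scenarios correlate exactly 1
  tab2 <- tab
  tab2$icc21[6:10] <- tab2$icc21[1:5]
  expect_equal(scenario_correlations(tab2)["A", "B"], 1)
  # excluded probe (<0.01 in one member) drops from that pair
  tab3 <- tab
  tab3$icc21[1] <- 0.001
  expect_equal(scenario_correlations(tab3)["A", "B"],
               cor(tab3$icc21[2:5], tab3$icc21[7:10]), tolerance = 1e-12)
})

test_that("independent stability tables are uncorrelated", {
  set.seed(71)
  n <- 10000
  tab <- data.frame(
    probe_id = rep(sprintf("p%05d", 1:n), 2),
    scenario = rep(c("A", "B"), each = n),
    icc21 = runif(2 * n, 0.05, 0.95),
    converged = TRUE
  )
  expect_lt(abs(scenario_correlations(tab)["A", "B"]), 0.05)
})

test_that("scenario clustering follows a manual complete-linkage trace", {
  # two identical probes per scenario: d(i,j) = sqrt(2) |a_i - a_j|
  a <- c(A = 0.2, B = 0.3, C = 0.5)
  tab <- data.frame(
    probe_id = rep(c("p1", "p2"), each = 3),
    scenario = rep(names(a), 2),
    icc21 = rep(unname(a), 2),
    converged = TRUE
  )
  hc <- cluster_scenarios(tab)
  expect_equal(hc$height, sqrt(2) * c(0.1, 0.3), tolerance = 1e-12)
  first_pair <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first_pair, c("A", "B"))
  # identical scenario vectors merge at height 0
  tab0 <- tab
  tab0$icc21[tab0$scenario == "B"] <- tab0$icc21[tab0$scenario == "A"]
  expect_equal(cluster_scenarios(tab0)$height[1], 0)
  # newick export has all scenario labels
  nwk <- scenario_tree_newick(hc)
  expect_true(all(vapply(names(a), grepl, TRUE, x = nwk, fixed = TRUE)))
})

test_that("clustering is invariant to scenario input order", {
  ch <- tiny_cohort()
  tab <- compute_scenario_icc(ch$beta, ch$sheet,
                              c("NoStressT1-2", "StressT1-2", "StressT3-4"),
                              adjust = FALSE)
  hc1 <- cluster_scenarios(tab)
  tab_rev <- tab[rev(seq_len(nrow(tab))), ]
  hc2 <- cluster_scenarios(tab_rev)
  co1 <- as.matrix(cophenetic(hc1))
  co2 <- as.matrix(cophenetic(hc2))
  expect_equal(co1, co2[rownames(co1), colnames(co1)], tolerance = 1e-12)
})

test_that("subsampling with all subjects reproduces the full table and seeds reproduce", {
  ch <- tiny_cohort()
  probes <- rownames(ch$beta)[1:8]
  full <- compute_scenario_icc(ch$beta, ch$sheet, "StressT1-2", probes = probes)
  all_n <- length(unique(ch$sheet$subject_id))
  sub_all <- subsample_icc(ch$beta, ch$sheet, "StressT1-2", n_sub = all_n,
                           seed = 3, probes = probes)
  expect_equal(sub_all$icc21, full$icc21, tolerance = 1e-9)
  s1 <- subsample_icc(ch$beta, ch$sheet, "StressT1-2", n_sub = 6,
                      per_probe_resample = TRUE, seed = 11, probes = probes)
  s2 <- subsample_icc(ch$beta, ch$sheet, "StressT1-2", n_sub = 6,
                      per_probe_resample = TRUE, seed = 11, probes = probes)
  expect_identical(s1, s2)
  expect_error(subsample_icc(ch$beta, ch$sheet, "StressT1-2", n_sub = 100),
               "exceeds")
})

test_that("stratification by identical groups gives a null comparison", {
  cfg <- plain_config(n_per_group = 6, n_probes = 15, seed = 73)
  ch <- generate_cohort(cfg)
  # clone group ELA data into the control subjects: groups become identical
  sheet <- ch$sheet
  ela_subj <- unique(sheet$subject_id[sheet$group == "ELA"])
  ctl_subj <- unique(sheet$subject_id[sheet$group == "control"])
  beta <- ch$beta
  for (i in seq_along(ctl_subj)) {
    from <- sheet$sample_id[sheet$subject_id == ela_subj[i]]
    to <- sheet$sample_id[sheet$subject_id == ctl_subj[i]]
    beta[, to] <- beta[, from]
  }
  res <- suppressMessages(
    stratify_by_group(beta, sheet, "StressT1-2", adjust = FALSE))
  expect_equal(res$comparison$beta, 0, tolerance = 1e-9)
  expect_equal(res$ELA$icc21, res$control$icc21, tolerance = 1e-9)

  # single-subject group errors
  sheet_bad <- sheet[sheet$subject_id %in% c(ela_subj, ctl_subj[1]), ]
  expect_error(stratify_by_group(beta, sheet_bad, "StressT1-2"), "fewer than 2")
})
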