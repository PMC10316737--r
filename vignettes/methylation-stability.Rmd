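---
title: "Quantifying the biological stability of repeated DNA methylation measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the biological stability of repeated DNA methylation measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methstab)
```

## The problem

Methylation arrays report, for every CpG probe, a beta-value: the fraction of
methylated signal at that site, in $[0,1]$. When the same person is measured
repeatedly — minutes, hours or a week apart — probe values drift for
biological reasons (cell-composition changes, circadian programs, responses
to stressors) on top of technical noise. The *stability* of a probe is the
fraction of its total variance attributable to stable between-person
differences, and it determines how trustworthy a single measurement is for
any downstream application (epigenetic clocks, cell-proportion estimators,
EWAS).

`methstab` quantifies stability with the intraclass correlation derived from
a two-way crossed random-effects model fitted per probe:

$$y_{it} = \beta_0 + \beta_1 x_{1it} + \beta_2 x_{2it} + \omega_i + \nu_t
+ \varepsilon_{it},$$

where $y_{it}$ is the probe value of person $i$ at repeated measurement $t$,
$x_{1it}$ the monocyte proportion of that sample, $x_{2it}$ the array
(batch), $\omega_i \sim N(0, \sigma_\omega^2)$ the person effect, $\nu_t
\sim N(0, \sigma_\nu^2)$ a timepoint effect shared by everyone measured at
occasion $t$, and $\varepsilon_{it} \sim N(0, \sigma_\varepsilon^2)$ the
residual. Two stability indices follow:

$$\mathrm{ICC}(2,1) = \frac{\sigma_\omega^2}
{\sigma_\omega^2 + \sigma_\nu^2 + \sigma_\varepsilon^2},
\qquad
\mathrm{ICC}(2,k) = \frac{n_t\,\sigma_\omega^2}
{n_t\,\sigma_\omega^2 + \sigma_\nu^2 + \sigma_\varepsilon^2},$$

the first rating a single measurement, the second the mean of $n_t$ repeated
measurements. $\mathrm{ICC}(2,k) \ge \mathrm{ICC}(2,1)$ always, with
equality only when $\sigma_\nu^2 + \sigma_\varepsilon^2 = 0$; the package
reports both and uses the conservative single-rater index downstream.

Stability is computed per *test-retest scenario*: a named pair (or
quadruple) of blood draws. The standard catalog
(`scenario_catalog()`) covers both sessions of a within-person design — a
session containing an acute laboratory stressor and a no-stress control
session one week apart, four draws each at nominal minutes 0, 75, 135 and
285 — plus `CrossSessionT1`, which pairs the two session baselines.

## Model fitting and numerical choices

Per-probe models are fitted by REML with `lme4`; the standard-deviation
parameterization guarantees non-negative variance components. Choices that
matter:

* **Scale.** Stability is computed on beta-values. M-values
  ($\log_2 \beta/(1-\beta)$, the approximately homoscedastic scale) are used
  for individual statistical testing (the stress-effect stage) and are
  available everywhere via `beta_to_m()`. Betas of exactly 0 or 1 are
  clipped to $[10^{-6}, 1-10^{-6}]$ before the transform.
* **Covariates.** Batch (array) is included as a categorical fixed effect in
  *both* adjusted and unadjusted fits whenever more than one batch is
  present; "adjusted" toggles only the monocyte-proportion covariate. This
  mirrors a design in which all stability calculations control for array
  while cell-proportion adjustment is the analysis variable of interest. A
  flag (`include_batch`) exposes the alternative.
* **Convergence.** Boundary (singular) fits — e.g. $\hat\sigma_\nu^2 = 0$,
  which is routine when a scenario has only two repeated measurements — are
  legitimate REML optima and are treated as converged. `converged = FALSE`
  is reserved for optimizer failure and numerically constant probes; such
  probes are assigned ICC 0, which places them in the `< 0.01` exclusion bin
  that all descriptive stages apply. Degenerate responses that break the
  penalized least-squares solve (zero residual variance) fall back to the
  closed-form balanced estimator when the model carries no covariates.
* **Oracle.** `anova_components()` ships an independent closed-form
  estimator from the classical two-way mean squares, with hierarchical
  pooling of negative estimates into the residual stratum — which reproduces
  the REML optimum at the boundary for balanced data. The test suite holds
  the two routes to within $10^{-3}$ on cohorts of several hundred probes.

## Descriptive stages

`summarize_stability()` reports mean, SD, median, skewness and excess
kurtosis of a scenario's included probes (ICC $\ge 0.01$). Skewness is the
bias-corrected Fisher–Pearson statistic $G_1 = g_1\sqrt{n(n-1)}/(n-2)$ and
kurtosis the bias-corrected excess $G_2 = ((n+1)g_2 + 6)(n-1)/((n-2)(n-3))$.
`bin_stability()` uses the half-open bins $[0, 0.01)$, $[0.01, 0.50)$,
$[0.50, 0.75)$, $[0.75, 0.90)$, $[0.90, 1]$ — exactly 0.01 is included
because the exclusion rule is "less than 0.01".

Scenario contrasts (`compare_paired()`) are paired t-tests over matched
probes; counts of very unstable probes are compared by Pearson chi-square
without continuity correction (`low_icc_chisq()`; the correction is
negligible at array-scale counts). Scenario profiles are correlated
pairwise over probes included in *both* members of each pair, and clustered
with Euclidean distance and complete linkage — the defaults of the classical
agglomerative routine; both conventions are recorded here because the
procedures they mirror do not pin them down. `subsample_icc()` re-estimates
a scenario from random subject subsets (optionally an independent draw per
probe, so no single subsample drives the distribution), and
`stratify_by_group()` splits a scenario by a between-person factor such as
early-life adversity.

## Enrichment

`run_enrichment()` asks whether a probe set (epigenetic-clock probes,
cell-estimator libraries, mQTLs, feature classes, expression-linked probes)
sits higher in a scenario's stability ranking than chance. The statistic is
the weighted running-sum (Kolmogorov–Smirnov-style) preranked score with
weight exponent 1 by default (0 gives the classical unweighted form), and
the null is generated by drawing random probe sets of the same size — the
set-permutation null of standard preranked enrichment tools, with a fixed
permutation count rather than an adaptive estimator. One-sided p-values
toward high stability are reported as $(1 + \#\{ES_\mathrm{null} \ge
ES_\mathrm{obs}\})/(B+1)$, so $p \ge 1/(B+1)$; 10,000 permutations and a
35,000-probe cap on set size are the defaults. Published set cardinalities
(353, 89, 513, 78,464, 173, 450, 1,200) are bundled as
`reference_set_sizes()`; `make_reference_probe_sets()` fabricates synthetic
membership at those sizes for simulated universes, since real manifests are
out of scope.

## Stress effects on highly stable probes

`select_highly_stable()` takes probes whose adjusted ICC(2,1) is at least
0.90 in every no-stress scenario *and* the cross-session baseline (the
threshold is inclusive), restricted to transcription-start-site probes.
`run_stress_analysis()` then tests, within the stressor session, whether
T2/T3/T4 differ from the T1 baseline. The model is a repeated-measures
ANOVA: timepoint as a categorical factor with T1 reference, subject as a
sum-coded blocking factor (so the intercept is the average person's adjusted
baseline), and centred monocyte proportion as covariate; batch is constant
within subject and therefore controlled exactly by the blocking. Because
every probe shares the design matrix, all probes are fitted in a single
multi-response least-squares pass, which keeps replicate-level calibration
experiments tractable; an equivalent subject-random-intercept `lme4` fit is
available (`method = "lmer"`) and agrees with the blocked fit on timepoint
contrasts under the balanced design. Estimates are reported on both scales
(M-scale p-values, beta-scale effect sizes) and flagged at the Bonferroni
threshold $\alpha/m$ with $m$ the number of probes tested — $m$ is always
computed from the selected list, never hard-coded.

One modelling consequence worth stating: the crossed model's timepoint
effect $\nu_t$ *is* a cohort-level mean shift at occasion $t$. A cohort
simulated with $\sigma_\nu^2 > 0$ therefore genuinely violates the stress
model's null hypothesis, and family-wise-error calibration experiments must
(and here do) use $\sigma_\nu^2 = 0$ for the tested probes.

## Expression linkage

RNA counts pass the standard pipeline: counts-per-million filter (CPM
strictly greater than 1 in at least 90% of samples), TMM between-sample
normalization at the published defaults (30% trim on log-ratios, 5% on
average intensity, precision weights), then $\log_2$ CPM with a 0.5 prior
count to keep occasional zeros finite. `correlate_probe_expression()`
computes per-pair Pearson correlations between TSS-probe methylation
(M-scale by default) and gene expression over paired samples, splitting the
tested probes into expression-correlated and uncorrelated sets at a
two-sided $p < 0.05$ (uncorrected — the choice is configurable because the
mirrored analysis does not state one). The two sets partition the tested
probes and feed directly into the enrichment stage.

## The synthetic-cohort generator

`generate_cohort()` draws complete cohorts under exactly the model the
engine fits, so every stage has analytic ground truth (`truth` element).
Defaults describe a realistic small stress-study cohort and were fixed once:

* 15 subjects per group (exposed / control), 2 sessions $\times$ 4 draws at
  minutes 0/75/135/285 — 8 samples per person, matching a design whose
  stressor-session scenarios have ~30 subjects.
* Four probe classes (high/medium/low stability plus a circadian-unstable
  class whose instability comes from $\sigma_\nu^2$) with true ICC(2,1)
  0.95/0.50/0.20/0.20 and per-probe total M-scale variance 0.25 (M-SD 0.5,
  typical of a variable array probe; ICCs are scale-invariant, and a
  moderate total keeps the beta-scale ICC essentially equal to the M-scale
  truth under the logistic transform).
* Monocyte effect 1 M-unit per unit proportion, batch effect 0.2 M; batch is
  assigned per subject (each person's 8 replicates share a slide, slides
  alternate between two arrays).
* Acute stress: a 0.8 multiplier on residual variance in the stressor
  session (the stabilizing direction observed over long intervals), mean
  shifts of $-0.2$ M at T4 for 10 stress-responsive TSS probes of the most
  stable class (the magnitude of reported stressor-induced hypomethylation),
  and a 1.5 residual-variance multiplier for adversity-exposed subjects in
  the stressor session only — a direction-only choice, since no magnitude is
  reported for that effect.
* Expression: half of the TSS probes couple to a dedicated gene at $-1$
  log2-unit per M-unit (methylation represses), Poisson counts at log-normal
  library sizes around $10^6$.
* Planted quality failures default to zero; configs can plant failing
  samples and probes to exercise the detection-p filters, and a fraction of
  sex-chromosome probes to exercise chromosome filtering.

What the generator does *not* emulate: raw array intensities and
normalization artefacts, realistic genome-wide baseline distributions,
spatial/probe-type effects, linkage structure among mQTLs, or non-Gaussian
heavy-tailed noise. Passing recovery tests therefore validate the
estimation machinery under the stated model, not the behaviour of any
particular normalization pipeline on real arrays.

## Problem sizes and what the checks show

The bundled verification suite runs, among others: formula identities over
a 1,000-point component grid; REML-versus-mean-squares agreement on 500
probes at 50 subjects $\times$ 2 timepoints (tolerance $10^{-3}$); median
recovery of true ICC 0.2/0.5/0.8 within $\pm 0.05$ at 200 subjects and 900
probes; direction checks for single-rater versus multi-rater indices,
cell-proportion adjustment, and subject subsampling (n = 14 versus the full
sample, drawn independently per probe); permutation-enrichment exactness
against exhaustive enumeration on a 5-probe universe, uniformity of null
p-values over 10,000 draws, and detection of a planted high-stability class;
stress-test family-wise error over 200 replicate null cohorts of 1,000
highly stable probes at 30 subjects with planted $-0.2$ M shifts recovered
in sign at $\ge 95\%$; and byte-identical reruns of the full simulate →
filter → ICC → summarize → enrich → stress chain at a fixed seed. These
sizes were chosen so the whole suite completes in minutes on a single core
while leaving each check adequately powered.

## Known limitations

* Only the monocyte proportion is adjusted for; lymphocyte subtypes are
  deliberately out of scope, so residual cell-composition variance remains
  in $\sigma_\varepsilon^2$.
* No confidence intervals for ICC values are provided.
* The enrichment p-value uses the fixed-permutation estimator; very small
  p-values saturate at $1/(B+1)$.
* Scenario fitting with two repeated measurements estimates $\sigma_\nu^2$
  from a single degree of freedom; per-probe component estimates are noisy
  at realistic sample sizes, which is precisely the phenomenon the
  subsampling analysis quantifies.

## A short worked example

```{r example, eval = FALSE}
library(methstab)

cohort <- generate_cohort(sim_config(n_subjects_per_group = 15,
                                     n_probes = 400, seed = 1))
qc <- apply_qc_filters(cohort$beta, cohort$detp, cohort$sheet,
                       cohort$annotation)
icc <- compute_scenario_icc(qc$beta, qc$sheet,
                            c("NoStressT1-2", "StressT1-2"))
summarize_stability(icc[icc$scenario == "NoStressT1-2", ])
bin_stability(icc[icc$scenario == "NoStressT1-2", ])
```
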