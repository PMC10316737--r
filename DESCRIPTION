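Package: methstab
Title: Biological Stability of Repeated DNA Methylation Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the test-retest stability of CpG probes on
    methylation arrays from repeated within-person measurements. Fits a per-probe
    two-way crossed random-effects model (subject and timepoint) with optional
    immune-cell and batch covariates and derives ICC(2,1) and ICC(2,k) stability
    values for named test-retest scenarios; summarizes, bins, correlates and
    clusters stability across scenarios; tests probe sets for enrichment of high
    stability with a preranked permutation statistic; extracts highly stable
    transcription-start-site probes and tests acute-stress effects on them under
    a repeated-measures framework with Bonferroni control; links methylation to
    gene expression after CPM filtering and TMM normalization; and simulates
    cohorts with known variance components so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    edgeR,
    ape,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    e1071
Config/testthat/edition: 3
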