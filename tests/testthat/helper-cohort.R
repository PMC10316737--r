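## shared fixtures, built in code and cached across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## small default cohort used by several files
tiny_cohort <- function() {
  cached("tiny", generate_cohort(sim_config(
    n_subjects_per_group = 8, n_probes = 40, seed = 101)))
}

## balanced covariate-free cohort for oracle comparisons
plain_config <- function(n_per_group = 10, n_probes = 30, seed = 7, ...) {
  sim_config(n_subjects_per_group = n_per_group, n_probes = n_probes,
             monocyte_beta = 0, batch_beta = 0, stress_n_probes = 0,
             stress_sigma_scale = 1, ela_sigma_scale = 1, seed = seed, ...)
}

## single-class config with a known variance triple
one_class_config <- function(s2o, s2n, s2e, n_per_group = 10, n_probes = 20,
                             seed = 7, ...) {
  cls <- data.frame(class = "only", prop = 1, sigma2_omega = s2o,
                    sigma2_nu = s2n, sigma2_eps = s2e)
  plain_config(n_per_group, n_probes, seed, probe_classes = cls, ...)
}

## reshape one probe's scenario values to a subjects x time matrix
probe_matrix <- function(y, design) {
  tapply(y, list(design$subject_id, design$time), mean)
}

## hand-built detection-p fixture: 10 probes x 6 samples, 2 sex-chromosome
## probes and 1 autosomal probe failing in 1/6 (> 10%) of samples
filter_fixture <- function() {
  probes <- sprintf("cg%02d", 1:10)
  samples <- sprintf("S%d", 1:6)
  detp <- matrix(0.001, 10, 6, dimnames = list(probes, samples))
  detp["cg03", "S2"] <- 0.2        # fails in 1/6 = 16.7% of samples
  ann <- data.frame(
    probe_id = probes,
    chromosome = c("chr1", "chr2", "chr3", "chrX", "chr5",
                   "chrY", "chr7", "chr8", "chr9", "chr10"),
    position = 1000L * (1:10),
    feature_class = "Body",
    gene_symbol = "GENE0001",
    stringsAsFactors = FALSE
  )
  list(detp = detp, ann = ann,
       survivors = setdiff(probes, c("cg03", "cg04", "cg06")))
}
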