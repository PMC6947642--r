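# Shared fixtures: tiny datasets built in code.

# Plain dataset with explicit values.
make_tiny_ds <- function() {
  beta <- matrix(c(0.1, 0.2,
                   0.3, 0.4,
                   0.5, 0.6), nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), c("cgA", "cgB")))
  methyl_dataset(beta, age = c(1, 5, 9))
}

# Small synthetic cohort with clean planted signal (no missing, no outliers).
make_clean_cohort <- function(n = 150, p = 40, k = 5, seed = 42,
                              noise = c(0.01, 0.01, 0.01)) {
  generate_cohort(synth_config(
    n_samples = n, n_sites = p, n_informative = k,
    noise_sd_per_regime = noise,
    slope_sd_per_regime = c(0.004, 0.003, 0.002),
    missing_rate = 0, n_outlier_samples = 0, seed = seed))
}

# Cohort whose three regimes are recoverable by the Stage-1 classifier:
# strong multivariate drift, modest noise.
make_regime_cohort <- function(n = 400, seed = 7) {
  generate_cohort(synth_config(
    n_samples = n, n_sites = 120, n_informative = 30,
    noise_sd_per_regime = c(0.01, 0.015, 0.02),
    slope_sd_per_regime = c(0.006, 0.003, 0.0015),
    missing_rate = 0, n_outlier_samples = 0, seed = seed))
}

# Delimited matrix file used by reader tests; returns its path.
write_tiny_matrix_file <- function(path = tempfile(fileext = ".csv"),
                                   missing_cell = FALSE, dup_site = FALSE) {
  header <- c("sample_id", "age", "cgA", if (dup_site) "cgA" else "cgB")
  rows <- list(c("s1", "1", "0.10", "0.20"),
               c("s2", "5", if (missing_cell) "" else "0.30", "0.40"),
               c("s3", "9", "0.50", "0.60"))
  writeLines(c(paste(header, collapse = ","),
               vapply(rows, paste, "", collapse = ",")), path)
  path
}

geo_fixture_path <- function() {
  system.file("extdata", "synthetic_series_matrix.txt", package = "cpgselect")
}
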