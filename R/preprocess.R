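#' Drop fully-missing samples and sites
#'
#' First cleaning step: removes every sample (row) and CpG site (column) whose
#' beta values are all missing, preserving the order of what remains.
#'
#' @param ds a [methyl_dataset].
#' @return the cleaned [methyl_dataset].
#' @export
drop_all_null <- function(ds) {
  keep_row <- rowSums(!is.na(ds$beta)) > 0L
  keep_col <- colSums(!is.na(ds$beta)) > 0L
  if (!any(keep_row) || !any(keep_col)) stop("all beta values are missing")
  if (all(keep_row) && all(keep_col)) return(ds)
  subset_dataset(ds, samples = keep_row, sites = keep_col)
}

#' Mean-impute missing beta values
#'
#' Replaces every missing cell by the mean of its column's non-missing values.
#' Columns with no observed value cannot be imputed; run [drop_all_null()]
#' first.
#'
#' @param ds a [methyl_dataset].
#' @return a [methyl_dataset] without missing values.
#' @export
impute_mean <- function(ds) {
  b <- ds$beta
  if (!anyNA(b)) return(ds)
  cm <- colMeans(b, na.rm = TRUE)
  if (anyNA(cm))
    stop("fully-missing column(s) present; run drop_all_null() first")
  idx <- which(is.na(b), arr.ind = TRUE)
  b[idx] <- cm[idx[, 2L]]
  ds$beta <- b
  validate_methyl_dataset(ds)
  ds
}

#' Min-max normalize beta values per site
#'
#' Rescales every column linearly onto \[0,1\] (constant columns map to 0),
#' preserving the beta-fraction semantics of the data.
#'
#' @param ds a [methyl_dataset] without missing values.
#' @return the normalized [methyl_dataset].
#' @export
normalize_minmax <- function(ds) {
  b <- ds$beta
  if (anyNA(b)) stop("missing values present; impute before normalizing")
  lo <- apply(b, 2L, min)
  hi <- apply(b, 2L, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  b <- sweep(sweep(b, 2L, lo, "-"), 2L, span, "/")
  b[, const] <- 0
  ds$beta <- b
  validate_methyl_dataset(ds)
  ds
}

#' Remove outlier samples by mean-beta z-score
#'
#' A sample whose mean beta deviates from the cohort's mean-of-means by more
#' than `z_threshold` standard deviations is removed. The rule is applied in a
#' single pass (no refitting after removal) and is a no-op for fewer than
#' three samples.
#'
#' @param ds a [methyl_dataset] without missing values.
#' @param z_threshold z-score cutoff (default 3).
#' @return the filtered [methyl_dataset].
#' @export
remove_outliers <- function(ds, z_threshold = 3) {
  if (anyNA(ds$beta)) stop("missing values present; impute before outlier removal")
  if (nrow(ds$beta) < 3L) return(ds)
  sm <- rowMeans(ds$beta)
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) return(ds)
  z <- abs(sm - mean(sm)) / s
  keep <- z <= z_threshold
  if (all(keep)) return(ds)
  subset_dataset(ds, samples = keep)
}

#' Random train/test split
#'
#' Uniform split without replacement: `round(ratio * n)` samples go to the
#' train set, the rest to the test set. Deterministic for a fixed seed.
#'
#' @param ds a [methyl_dataset].
#' @param ratio train fraction in (0,1); the conventional default is
#'   two-thirds.
#' @param seed integer seed.
#' @return an object of class `split_result`: list with `train`, `test`
#'   (both [methyl_dataset]), `seed` and `ratio`.
#' @export
split_train_test <- function(ds, ratio = 2 / 3, seed = 1L) {
  n <- n_samples(ds)
  if (n < 2L) stop("need at least 2 samples to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0,1)")
  n_train <- round(ratio * n)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  structure(list(train = subset_dataset(ds, samples = sort(idx)),
                 test = subset_dataset(ds, samples = sort(setdiff(seq_len(n), idx))),
                 seed = as.integer(seed), ratio = ratio),
            class = "split_result")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying [drop_all_null()], [impute_mean()],
#' [normalize_minmax()] and [remove_outliers()] in order. Idempotent on
#' already-clean data up to the min-max rescaling of each column.
#'
#' @param ds a [methyl_dataset].
#' @param z_threshold outlier z-score cutoff.
#' @param normalize apply min-max normalization (default TRUE).
#' @return the preprocessed [methyl_dataset].
#' @export
preprocess_dataset <- function(ds, z_threshold = 3, normalize = TRUE) {
  ds <- drop_all_null(ds)
  ds <- impute_mean(ds)
  if (normalize) ds <- normalize_minmax(ds)
  remove_outliers(ds, z_threshold = z_threshold)
}
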