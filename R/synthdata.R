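#' Configuration for the synthetic methylation-aging cohort generator
#'
#' Describes a cohort in which a subset of CpG sites drifts with age at
#' regime-specific rates — fast and clean at young ages, slower and noisier at
#' old ages — which is the structure that motivates splitting the age axis into
#' groups before selecting sites. Defaults mirror a merged blood-cohort world:
#' ages uniform on 0-103 years, regime boundaries at 20 and 50 years, noise
#' increasing and drift slowing with age, light missingness and a handful of
#' shifted outlier samples.
#'
#' @param n_samples,n_sites cohort dimensions.
#' @param n_informative number of planted age-informative sites
#'   (`<= n_sites`).
#' @param age_min,age_max age range in years.
#' @param regime_boundaries strictly increasing age cutpoints inside
#'   `(age_min, age_max)`; the default `c(20, 50)` yields the three regimes
#'   0-20, 20-50, 50-103.
#' @param noise_sd_per_regime per-regime beta noise SD (one per regime).
#' @param slope_sd_per_regime per-regime SD of the per-year drift of an
#'   informative site (one per regime); slopes are drawn once per site and
#'   regime, with a random overall sign per site.
#' @param missing_rate fraction of beta cells set missing, in \[0,1).
#' @param n_outlier_samples samples whose betas receive a constant +0.4 shift
#'   before clipping (detectable by [remove_outliers()]).
#' @param outlier_shift size of that shift.
#' @param seed integer seed; the whole cohort is a pure function of the config.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 2079L, n_sites = 25000L,
                         n_informative = 300L, age_min = 0, age_max = 103,
                         regime_boundaries = c(20, 50),
                         noise_sd_per_regime = c(0.01, 0.02, 0.04),
                         slope_sd_per_regime = c(0.004, 0.002, 0.001),
                         missing_rate = 0.005, n_outlier_samples = 10L,
                         outlier_shift = 0.4, seed = 1L) {
  cfg <- structure(list(n_samples = as.integer(n_samples),
                        n_sites = as.integer(n_sites),
                        n_informative = as.integer(n_informative),
                        age_min = age_min, age_max = age_max,
                        regime_boundaries = as.numeric(regime_boundaries),
                        noise_sd_per_regime = as.numeric(noise_sd_per_regime),
                        slope_sd_per_regime = as.numeric(slope_sd_per_regime),
                        missing_rate = missing_rate,
                        n_outlier_samples = as.integer(n_outlier_samples),
                        outlier_shift = outlier_shift,
                        seed = as.integer(seed)),
                   class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with(cfg, {
    if (n_samples < 1 || n_sites < 1) stop("n_samples and n_sites must be >= 1")
    if (n_informative < 0 || n_informative > n_sites)
      stop("n_informative must lie in [0, n_sites]")
    if (age_max <= age_min) stop("age_max must exceed age_min")
    if (length(regime_boundaries)) {
      if (is.unsorted(regime_boundaries, strictly = TRUE))
        stop("regime_boundaries must be strictly increasing")
      if (min(regime_boundaries) <= age_min || max(regime_boundaries) >= age_max)
        stop("regime_boundaries must lie strictly inside (age_min, age_max)")
    }
    n_regimes <- length(regime_boundaries) + 1L
    if (length(noise_sd_per_regime) != n_regimes)
      stop("noise_sd_per_regime must have one entry per regime (", n_regimes, ")")
    if (length(slope_sd_per_regime) != n_regimes)
      stop("slope_sd_per_regime must have one entry per regime (", n_regimes, ")")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must lie in [0,1)")
    if (n_outlier_samples < 0 || n_outlier_samples > n_samples)
      stop("n_outlier_samples must lie in [0, n_samples]")
  })
  invisible(cfg)
}

#' Generate a synthetic methylation-aging cohort
#'
#' Ages are sampled uniformly on `[age_min, age_max]`. Each planted
#' informative site follows a continuous piecewise-linear function of age —
#' one slope per regime, drawn from `slope_sd_per_regime`, anchored at a
#' site-specific baseline — plus zero-mean Gaussian noise whose SD is that of
#' the sample's own age regime; values are clipped to \[0,1\]. Uninformative
#' sites are drawn independently of age from a Beta distribution around a
#' site-specific mean, reproducing the bimodal-ish marginals of real
#' methylation without any age signal. Missing cells are then injected
#' uniformly at random and `n_outlier_samples` samples receive a constant
#' upward shift of all their betas (pre-clipping).
#'
#' @param config a [synth_config].
#' @return a list with elements `dataset` (a [methyl_dataset]) and `truth`
#'   (class `synth_truth`: `informative_site_ids` and the
#'   `per_site_regime_slopes` matrix, sites x regimes), plus
#'   `outlier_sample_ids`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    p <- cfg$n_sites
    ages <- stats::runif(n, cfg$age_min, cfg$age_max)
    cuts <- c(cfg$age_min, cfg$regime_boundaries, cfg$age_max)
    n_regimes <- length(cuts) - 1L
    regime <- findInterval(ages, cuts, rightmost.closed = TRUE)

    site_id <- sprintf("cg%08d", seq_len(p))
    info_idx <- seq_len(cfg$n_informative)
    beta <- matrix(NA_real_, n, p,
                   dimnames = list(sprintf("syn%05d", seq_len(n)), site_id))

    slopes <- matrix(0, cfg$n_informative, n_regimes,
                     dimnames = list(site_id[info_idx], NULL))
    if (cfg$n_informative > 0L) {
      sign_site <- sample(c(-1, 1), cfg$n_informative, replace = TRUE)
      for (r in seq_len(n_regimes)) {
        mag <- abs(stats::rnorm(cfg$n_informative, 0, cfg$slope_sd_per_regime[r]))
        slopes[, r] <- sign_site * mag
      }
      base <- stats::runif(cfg$n_informative, 0.25, 0.75)
      # continuous piecewise-linear response: integrate slopes regime by regime
      seg_len <- diff(cuts)
      for (s in seq_len(cfg$n_informative)) {
        offsets <- c(0, cumsum(slopes[s, ] * seg_len))  # value at each cut
        mu <- base[s] + offsets[regime] +
          slopes[s, regime] * (ages - cuts[regime])
        eps <- stats::rnorm(n, 0, cfg$noise_sd_per_regime[regime])
        beta[, s] <- mu + eps
      }
    }
    if (p > cfg$n_informative) {
      noise_idx <- seq.int(cfg$n_informative + 1L, p)
      m <- stats::runif(length(noise_idx), 0.1, 0.9)
      conc <- 30  # Beta concentration: marginals spread but inside [0,1]
      for (k in seq_along(noise_idx)) {
        beta[, noise_idx[k]] <- stats::rbeta(n, m[k] * conc, (1 - m[k]) * conc)
      }
    }

    outlier_ids <- character(0)
    if (cfg$n_outlier_samples > 0L) {
      out_rows <- sample.int(n, cfg$n_outlier_samples)
      beta[out_rows, ] <- beta[out_rows, , drop = FALSE] + cfg$outlier_shift
      outlier_ids <- rownames(beta)[out_rows]
    }
    beta[beta < 0] <- 0
    beta[beta > 1] <- 1

    if (cfg$missing_rate > 0) {
      n_miss <- round(cfg$missing_rate * length(beta))
      if (n_miss > 0) beta[sample.int(length(beta), n_miss)] <- NA_real_
    }

    truth <- structure(list(informative_site_ids = site_id[info_idx],
                            per_site_regime_slopes = slopes),
                       class = "synth_truth")
    list(dataset = methyl_dataset(beta, age = ages,
                                  source = rep("synthetic", n)),
         truth = truth,
         outlier_sample_ids = outlier_ids)
  })
}

#' Baseline mean absolute deviation of a cohort's ages
#'
#' The MAD obtained by always predicting the mean age — the reference any age
#' model must beat. For ages uniform on \[0,100\] this is 25 years.
#'
#' @param dataset a [methyl_dataset] with ages set.
#' @return the baseline MAD in years.
#' @export
baseline_mad <- function(dataset) {
  if (is.null(dataset$age) || length(dataset$age) == 0L)
    stop("dataset has no ages")
  mean(abs(dataset$age - mean(dataset$age)))
}
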