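#' Rank CpG sites by absolute Pearson correlation with age
#'
#' The pre-selection filter: computes the Pearson correlation between every
#' site's betas and age, and orders sites by decreasing `|r|`. Sites with zero
#' variance get `r = 0`; ties in `|r|` are broken by ascending site id, so the
#' ranking is invariant to sample order.
#'
#' @param ds a [methyl_dataset] with ages set, no missing values, at least 3
#'   samples.
#' @return an object of class `correlation_ranking`: `site_ids` (ordered) and
#'   `r_values` (signed, same order).
#' @export
rank_by_pearson <- function(ds) {
  if (is.null(ds$age)) stop("dataset has no ages")
  if (anyNA(ds$beta)) stop("missing betas; impute first")
  if (n_samples(ds) < 3L) stop("need at least 3 samples for correlations")
  r <- suppressWarnings(as.numeric(stats::cor(ds$beta, ds$age)))
  r[is.na(r)] <- 0  # zero-variance sites
  ids <- site_ids(ds)
  ord <- order(-abs(r), ids)
  structure(list(site_ids = ids[ord], r_values = r[ord]),
            class = "correlation_ranking")
}

#' @export
print.correlation_ranking <- function(x, ...) {
  cat("correlation_ranking: ", length(x$site_ids), " sites, |r| from ",
      round(abs(x$r_values[1]), 3), " down to ",
      round(abs(x$r_values[length(x$r_values)]), 3), "\n", sep = "")
  invisible(x)
}

#' Keep the top-k sites of a correlation ranking
#'
#' @param ranking a `correlation_ranking` from [rank_by_pearson()].
#' @param k panel size; the conventional default keeps the 8000 most
#'   age-correlated sites. When `k` exceeds the number of ranked sites, all
#'   sites are returned with a warning.
#' @return character vector of the selected site ids (highest `|r|` first).
#' @export
take_top_k <- function(ranking, k = 8000L) {
  stopifnot(inherits(ranking, "correlation_ranking"), k >= 1)
  total <- length(ranking$site_ids)
  if (k > total) {
    warning("k (", k, ") exceeds the number of ranked sites (", total,
            "); keeping all")
    k <- total
  }
  ranking$site_ids[seq_len(k)]
}
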