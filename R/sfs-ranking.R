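#' Stepwise-forward-selection configuration
#'
#' @param improvement_epsilon minimum decrease in cross-validated MAD (years)
#'   for an addition to be accepted (default 0.01).
#' @param max_sites optional cap on the number of ranked sites.
#' @param folds cross-validation folds (default 3).
#' @param seed integer seed.
#' @return an object of class `sfs_config`.
#' @export
sfs_config <- function(improvement_epsilon = 0.01, max_sites = NULL,
                       folds = 3L, seed = 1L) {
  stopifnot(improvement_epsilon >= 0, folds >= 2)
  structure(list(improvement_epsilon = improvement_epsilon,
                 max_sites = if (is.null(max_sites)) NULL else as.integer(max_sites),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "sfs_config")
}

# CV MAD of a site subset (addition order irrelevant to the fit).
sfs_cv_mad <- function(ds, sites, gbr_par, folds, seed) {
  m <- cv_regress_partition(ds$beta[, sites, drop = FALSE], ds$age, gbr_par,
                            folds = folds, seed = seed)
  m$mad
}

#' Rank a CpG panel by stepwise forward selection with backward elimination
#'
#' Starting from the mean-age baseline, the candidate site whose inclusion
#' most decreases the cross-validated MAD is added — provided the decrease is
#' at least `improvement_epsilon` — and after each addition a single backward
#' sweep removes any included site whose removal does not increase the CV MAD
#' by more than `improvement_epsilon` (a site made redundant by later
#' additions). The loop stops when no addition qualifies (or `max_sites` is
#' reached). Ties among candidates are broken by ascending site id, and the
#' whole procedure is deterministic for a fixed seed.
#'
#' @param ds the group training [methyl_dataset] restricted to the
#'   GA-selected candidate sites.
#' @param gbr_par a [gbr_params] for the evaluation model.
#' @param sfs_conf an [sfs_config].
#' @param group_label label recorded in the report.
#' @return a [selection_report]: sites in addition order (eliminated sites
#'   dropped) with the CV MAD measured as each one entered.
#' @export
sfs_rank <- function(ds, gbr_par = gbr_params(), sfs_conf = sfs_config(),
                     group_label = "all") {
  if (n_sites(ds) < 1L) stop("no candidate sites")
  if (n_samples(ds) < sfs_conf$folds) stop("fewer samples than folds")
  eps <- sfs_conf$improvement_epsilon
  candidates <- sort(site_ids(ds))  # ascending-id order fixes tie-breaks
  included <- character(0)
  mad_after <- numeric(0)
  current_mad <- baseline_mad(ds)
  step <- 0L

  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, included)
    if (length(remaining) == 0L) break
    if (!is.null(sfs_conf$max_sites) && length(included) >= sfs_conf$max_sites)
      break

    trial <- vapply(remaining, function(s)
      sfs_cv_mad(ds, c(included, s), gbr_par, sfs_conf$folds,
                 seed = derive_seed(sfs_conf$seed, step)), 0)
    best <- which.min(trial)  # remaining is sorted, so ties go to lower id
    if (current_mad - trial[best] < eps) break
    included <- c(included, remaining[best])
    mad_after <- c(mad_after, trial[best])
    current_mad <- trial[best]

    # single backward sweep over previously included sites
    if (length(included) > 1L) {
      for (s in included[-length(included)]) {
        reduced <- setdiff(included, s)
        mad_wo <- sfs_cv_mad(ds, reduced, gbr_par, sfs_conf$folds,
                             seed = derive_seed(sfs_conf$seed, step))
        if (mad_wo <= current_mad + eps) {
          keep <- included != s
          included <- included[keep]
          mad_after <- mad_after[keep]
          current_mad <- min(current_mad, mad_wo)
        }
      }
    }
  }

  final <- if (length(included))
    compute_metrics(ds$age,
                    cv_predictions(ds, included, gbr_par, sfs_conf$folds,
                                   seed = derive_seed(sfs_conf$seed, 0L)))
  else NULL
  selection_report(group_label, included, mad_after, final_metrics = final)
}

# Pooled out-of-fold predictions for a site subset (for final report metrics).
cv_predictions <- function(ds, sites, gbr_par, folds, seed) {
  X <- ds$beta[, sites, drop = FALSE]
  y <- ds$age
  n <- nrow(X)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- fit_gbr(X[tr, , drop = FALSE], y[tr], gbr_par,
                     seed = derive_seed(seed, f))
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  pred
}
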