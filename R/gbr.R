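#' Gradient-boosted regression hyperparameters
#'
#' Bundles the tuning constants of the least-absolute-deviation
#' gradient-boosted regression-tree model used throughout the fitness engine,
#' the stepwise ranking and the final per-group age models. Defaults are the
#' combination found best for blood-methylation age regression: 300 shallow
#' trees (depth 4), strong shrinkage (learning rate 0.03) and 60% row
#' subsampling per stage.
#'
#' `loss` must be `"lad"`; `alpha` and `warm_start` are accepted for interface
#' completeness but are inert for LAD loss (alpha only parameterizes
#' huber/quantile losses; warm_start only matters when refitting a model
#' incrementally, which this package never does).
#'
#' @param n_estimators number of boosting stages (trees).
#' @param max_depth maximum tree depth.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param subsample fraction of samples drawn (without replacement) per stage.
#' @param alpha inert for `loss = "lad"`; kept for contract completeness.
#' @param learning_rate shrinkage applied to every tree's contribution.
#' @param loss only `"lad"` (least absolute deviation) is supported.
#' @param warm_start inert; see Details.
#' @param seed master seed for subsampling streams.
#' @return an object of class `gbr_params`.
#' @export
gbr_params <- function(n_estimators = 300L, max_depth = 4L,
                       min_samples_split = 2L, subsample = 0.6, alpha = 0.6,
                       learning_rate = 0.03, loss = "lad", warm_start = TRUE,
                       seed = 1L) {
  stopifnot(n_estimators >= 1, learning_rate > 0,
            subsample > 0, subsample <= 1, max_depth >= 1,
            min_samples_split >= 2)
  if (!identical(loss, "lad"))
    stop("only loss = 'lad' (least absolute deviation) is supported")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 subsample = subsample, alpha = alpha,
                 learning_rate = learning_rate, loss = loss,
                 warm_start = isTRUE(warm_start), seed = as.integer(seed)),
            class = "gbr_params")
}

#' Fit a gradient-boosted LAD regression model
#'
#' Least-absolute-deviation boosting over depth-limited CART regression trees:
#' the model starts from the median of `y`, each stage fits a tree (squared
#' error splits) to the sign of the current residuals on a random row
#' subsample, re-values each leaf with the median residual of its in-bag
#' samples, and shrinks the update by the learning rate. Fully reproducible
#' from `seed`.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y numeric response (here: age in years).
#' @param params a [gbr_params] bundle.
#' @param seed RNG seed for this fit; defaults to `params$seed`.
#' @return an object of class `gbr_model` with a [predict][predict.gbr_model]
#'   method.
#' @export
fit_gbr <- function(X, y, params = gbr_params(), seed = params$seed) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  if (nrow(X) == 0L) stop("empty training set")
  if (ncol(X) == 0L) stop("no features to fit on")
  fit <- with_seed(seed, .gbr_fit_cpp(X, y, params$n_estimators,
                                      params$learning_rate, params$max_depth,
                                      params$min_samples_split,
                                      params$subsample))
  structure(list(fit = fit, n_features = ncol(X), params = params),
            class = "gbr_model")
}

#' Predict ages from a fitted gradient-boosted model
#'
#' @param object a `gbr_model` from [fit_gbr()].
#' @param newdata numeric matrix with the same feature columns used at fit
#'   time.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features, model expects ",
         object$n_features)
  as.numeric(.gbr_predict_cpp(object$fit, newdata))
}

#' @export
print.gbr_params <- function(x, ...) {
  cat("gbr_params: ", x$n_estimators, " trees, depth ", x$max_depth,
      ", lr ", x$learning_rate, ", subsample ", x$subsample,
      ", loss ", x$loss, "\n", sep = "")
  invisible(x)
}
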