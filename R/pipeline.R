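#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run: preprocessing,
#' Stage-1 grouping, the per-group correlation filter, the GA, the stepwise
#' ranking and the final evaluation. One master seed derives every other seed
#' in the run.
#'
#' @param scheme a [grouping_scheme], or `NULL` to learn one from the decade
#'   confusion matrix with [merge_by_confusion()] (`target_groups` groups).
#' @param target_groups number of groups when `scheme` is `NULL`.
#' @param split_ratio train fraction (default two-thirds; set 0.7 for a 7:3
#'   split).
#' @param filter_k correlation-filter panel size per group.
#' @param n_components Stage-1 PCA dimensionality.
#' @param ga a [ga_config] (`chromosome_length` is adjusted per group to the
#'   actual panel size).
#' @param gbr a [gbr_params].
#' @param sfs an [sfs_config], or `NULL` to skip the stepwise ranking.
#' @param z_threshold outlier cutoff for preprocessing.
#' @param target_size fitness-partition size.
#' @param folds cross-validation folds used throughout.
#' @param parallelism_degree worker processes for population evaluation.
#' @param leakage_free if `TRUE` (default), imputation and normalization
#'   statistics are fitted on the train split and applied to the test split;
#'   if `FALSE`, the whole dataset is preprocessed before splitting
#'   (the classical but leaky order).
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = scheme_three_groups(), target_groups = 3L,
                            split_ratio = 2 / 3, filter_k = 8000L,
                            n_components = 60L, ga = ga_config(),
                            gbr = gbr_params(), sfs = sfs_config(),
                            z_threshold = 3, target_size = 100L, folds = 3L,
                            parallelism_degree = 1L, leakage_free = TRUE,
                            seed = 1L) {
  structure(list(scheme = scheme, target_groups = as.integer(target_groups),
                 split_ratio = split_ratio, filter_k = as.integer(filter_k),
                 n_components = as.integer(n_components), ga = ga, gbr = gbr,
                 sfs = sfs, z_threshold = z_threshold,
                 target_size = as.integer(target_size),
                 folds = as.integer(folds),
                 parallelism_degree = as.integer(parallelism_degree),
                 leakage_free = isTRUE(leakage_free), seed = as.integer(seed)),
            class = "pipeline_config")
}

# Train-fitted preprocessing: imputation means and min-max ranges come from
# the train split only and are then applied to both splits.
fit_preprocessor <- function(train) {
  train <- drop_all_null(train)
  col_mean <- colMeans(train$beta, na.rm = TRUE)
  imputed <- impute_mean(train)
  lo <- apply(imputed$beta, 2L, min)
  hi <- apply(imputed$beta, 2L, max)
  list(sites = site_ids(train), col_mean = col_mean, lo = lo, hi = hi)
}

apply_preprocessor <- function(prep, ds) {
  ds <- subset_dataset(ds, sites = prep$sites)
  b <- ds$beta
  idx <- which(is.na(b), arr.ind = TRUE)
  if (nrow(idx)) b[idx] <- prep$col_mean[idx[, 2L]]
  span <- prep$hi - prep$lo
  const <- span == 0
  span[const] <- 1
  b <- sweep(sweep(b, 2L, prep$lo, "-"), 2L, span, "/")
  b[, const] <- 0
  b[b < 0] <- 0  # test values outside the train range are clipped
  b[b > 1] <- 1
  ds$beta <- b
  ds
}

#' Run the full two-stage selection pipeline
#'
#' Orchestrates preprocess, train/test split, Stage-1 grouping (fixed scheme
#' or confusion-driven merging), per-group correlation filtering, the
#' per-group genetic algorithm, the stepwise forward ranking and the final
#' per-group gradient-boosted age models. Test samples are routed to groups by
#' the Stage-1 classifier's *predicted* label, never by their true age. No
#' test sample influences preprocessing statistics, the filter, the GA or the
#' ranking when `leakage_free` is on (the default).
#'
#' @param dataset a [methyl_dataset] with ages set; alternatively pass
#'   `train` and `test` directly (then `dataset` may be `NULL`).
#' @param config a [pipeline_config].
#' @param train,test optional pre-split datasets overriding the internal
#'   split.
#' @return an object of class `pipeline_result`: the scheme, per-group
#'   selected sites / GA histories / reports, final per-group and pooled
#'   train/test metrics, and reproducibility metadata (`seed`, config).
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), train = NULL,
                         test = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (is.null(train) || is.null(test)) {
    if (config$leakage_free) {
      sp <- split_train_test(dataset, ratio = config$split_ratio,
                             seed = derive_seed(seed, 1L))
      train <- sp$train
      test <- sp$test
    } else {
      pre <- preprocess_dataset(dataset, z_threshold = config$z_threshold)
      sp <- split_train_test(pre, ratio = config$split_ratio,
                             seed = derive_seed(seed, 1L))
      train <- sp$train
      test <- sp$test
    }
  }

  if (config$leakage_free) {
    prep <- fit_preprocessor(train)
    train <- apply_preprocessor(prep, train)
    test <- apply_preprocessor(prep, test)
    train <- remove_outliers(train, z_threshold = config$z_threshold)
  }

  # ---- Stage 1: age grouping -------------------------------------------
  scheme <- config$scheme
  if (is.null(scheme)) {
    confusion <- cv_confusion(train, scheme_identity(), folds = config$folds,
                              seed = derive_seed(seed, 2L),
                              n_components = config$n_components)
    scheme <- merge_by_confusion(confusion, config$target_groups)
  }
  classifier <- fit_group_classifier(train, scheme,
                                     n_components = min(config$n_components,
                                                        min(dim(train$beta))),
                                     seed = derive_seed(seed, 3L))
  train$group <- as.character(apply_scheme(decade_labels(train$age), scheme))
  test <- assign_groups(classifier, test)

  # ---- Stage 2: per-group filter + GA + ranking ------------------------
  groups <- as.character(seq_along(scheme$partition))
  grouped_train <- lapply(groups, function(g)
    subset_dataset(train, samples = train$group == g))
  names(grouped_train) <- groups

  filtered <- lapply(groups, function(g) {
    ranking <- rank_by_pearson(grouped_train[[g]])
    panel <- suppressWarnings(take_top_k(ranking, config$filter_k))
    subset_dataset(grouped_train[[g]], sites = panel)
  })
  names(filtered) <- groups

  ga_conf <- config$ga
  ga_conf$seed <- derive_seed(seed, 4L)
  ga_results <- run_all_groups(filtered, ga_conf, config$gbr,
                               parallelism_degree = config$parallelism_degree,
                               target_size = config$target_size,
                               folds = config$folds)
  failed <- vapply(ga_results, inherits, TRUE, "ga_group_error")
  if (any(failed))
    stop("GA failed for group(s) ",
         paste(groups[failed], collapse = ", "), ": ",
         ga_results[[which(failed)[1]]]$message)

  selected_sites <- lapply(groups, function(g)
    site_ids(filtered[[g]])[ga_results[[g]]$best_chromosome == 1L])
  names(selected_sites) <- groups

  reports <- NULL
  if (!is.null(config$sfs)) {
    reports <- lapply(groups, function(g) {
      conf <- config$sfs
      conf$seed <- derive_seed(seed, 5L, as.integer(g))
      sfs_rank(subset_dataset(grouped_train[[g]], sites = selected_sites[[g]]),
               gbr_par = config$gbr, sfs_conf = conf, group_label = g)
    })
    names(reports) <- groups
  }

  final <- evaluate_final_model(train, test, selected_sites, config$gbr,
                                seed = derive_seed(seed, 6L))

  structure(list(scheme = scheme, classifier = classifier,
                 selected_sites = selected_sites,
                 ga_histories = lapply(ga_results, `[[`, "history"),
                 ga_best_fitness = vapply(ga_results, `[[`, 0, "best_fitness"),
                 reports = reports, final = final,
                 train = train, test = test,
                 seed = seed, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", length(x$selected_sites), " age groups\n", sep = "")
  for (g in names(x$selected_sites)) {
    cat(sprintf("  group %s: %d selected sites, best fitness %.3f\n", g,
                length(x$selected_sites[[g]]), x$ga_best_fitness[[g]]))
  }
  if (!is.null(x$final$pooled_test))
    cat(sprintf("  pooled test:  MAD %.3f years, R2 %s\n",
                x$final$pooled_test$mad,
                ifelse(is.na(x$final$pooled_test$r2), "NA",
                       sprintf("%.4f", x$final$pooled_test$r2))))
  if (!is.null(x$final$pooled_train))
    cat(sprintf("  pooled train: MAD %.3f years, R2 %s\n",
                x$final$pooled_train$mad,
                ifelse(is.na(x$final$pooled_train$r2), "NA",
                       sprintf("%.4f", x$final$pooled_train$r2))))
  invisible(x)
}

#' Fit and evaluate the final per-group age models
#'
#' One gradient-boosted regressor per age group, fitted on the group's
#' training samples restricted to its selected sites. Every test sample is
#' scored by the model of its *predicted* group (the `$group` field written
#' by [assign_groups()]). Metrics are reported per group and pooled over all
#' samples; a group that receives no test samples gets `NULL` test metrics
#' and is simply absent from the pooled test vector.
#'
#' @param train,test [methyl_dataset]s whose `$group` fields hold the group
#'   labels (true ones for train, predicted ones for test).
#' @param selected_sites named list (by group label) of site-id vectors.
#' @param gbr_par a [gbr_params].
#' @param seed seed for the model fits.
#' @return list with `per_group` (each: `train`, `test` metrics),
#'   `pooled_train`, `pooled_test`.
#' @export
evaluate_final_model <- function(train, test, selected_sites,
                                 gbr_par = gbr_params(), seed = 1L) {
  groups <- names(selected_sites)
  stopifnot(!is.null(groups), !is.null(train$group), !is.null(test$group))
  unknown <- setdiff(unique(test$group), groups)
  if (length(unknown))
    stop("test group(s) without a trained model: ",
         paste(unknown, collapse = ", "))

  per_group <- list()
  pred_train <- rep(NA_real_, n_samples(train))
  pred_test <- rep(NA_real_, n_samples(test))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    sites <- selected_sites[[g]]
    tr_idx <- which(train$group == g)
    te_idx <- which(test$group == g)
    if (length(tr_idx) == 0L) stop("group ", g, " has no training samples")
    model <- fit_gbr(train$beta[tr_idx, sites, drop = FALSE],
                     train$age[tr_idx], gbr_par,
                     seed = derive_seed(seed, gi))
    pred_train[tr_idx] <- predict(model, train$beta[tr_idx, sites,
                                                    drop = FALSE])
    m_test <- NULL
    if (length(te_idx)) {
      pred_test[te_idx] <- predict(model, test$beta[te_idx, sites,
                                                    drop = FALSE])
      m_test <- compute_metrics(test$age[te_idx], pred_test[te_idx])
    }
    per_group[[g]] <- list(train = compute_metrics(train$age[tr_idx],
                                                   pred_train[tr_idx]),
                           test = m_test)
  }
  scored <- !is.na(pred_test)
  list(per_group = per_group,
       pooled_train = compute_metrics(train$age, pred_train),
       pooled_test = if (any(scored))
         compute_metrics(test$age[scored], pred_test[scored]) else NULL)
}
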