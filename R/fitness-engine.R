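#' Regression quality metrics
#'
#' The four criteria used everywhere in the package: mean absolute deviation
#' (MAD, years), mean squared error (MSE), its square root (RMSE) and the
#' coefficient of determination R-squared =
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. When `y_true` has zero
#' variance R-squared is undefined and reported as `NA`.
#'
#' @param y_true,y_pred numeric vectors of equal, nonzero length.
#' @return an object of class `regression_metrics`: list with `mad`, `mse`,
#'   `rmse`, `r2`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal nonzero length")
  err <- y_true - y_pred
  mse <- mean(err^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  structure(list(mad = mean(abs(err)), mse = mse, rmse = sqrt(mse),
                 r2 = if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("MAD %.4f  MSE %.4f  RMSE %.4f  R2 %s\n", x$mad, x$mse, x$rmse,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  invisible(x)
}

#' Reduce a dataset to a chromosome's selected sites
#'
#' Drops every CpG column whose gene in the binary chromosome is 0, keeping
#' the selected columns in their original order and all samples.
#'
#' @param ds a [methyl_dataset].
#' @param chromosome integer/logical vector of 0/1 genes, one per site of
#'   `ds`.
#' @return the reduced [methyl_dataset].
#' @export
reduce_dataset <- function(ds, chromosome) {
  chromosome <- as.integer(chromosome)
  if (length(chromosome) != n_sites(ds))
    stop("chromosome length (", length(chromosome),
         ") != site count (", n_sites(ds), ")")
  if (!all(chromosome %in% c(0L, 1L))) stop("genes must be 0 or 1")
  if (sum(chromosome) == 0L) stop("all-zero chromosome selects no sites")
  subset_dataset(ds, sites = chromosome == 1L)
}

#' Plan balanced sample partitions
#'
#' Randomly deals the samples into `max(1, floor(n_samples / target_size))`
#' partitions of near-equal size (differing by at most one), so that
#' chromosome fitness can be computed per partition and averaged — the
#' map/reduce work-unit layout.
#'
#' @param n_samples number of samples.
#' @param target_size nominal partition size (default 100).
#' @param seed integer seed for the shuffle.
#' @return an object of class `partition_plan`: list of disjoint index
#'   vectors covering `1:n_samples`, plus the seed.
#' @export
plan_partitions <- function(n_samples, target_size = 100L, seed = 1L) {
  stopifnot(n_samples >= 1L, target_size >= 1L)
  n_parts <- max(1L, n_samples %/% as.integer(target_size))
  perm <- with_seed(seed, sample.int(n_samples))
  # deal shuffled samples round-robin into n_parts balanced partitions
  parts <- split(perm, rep_len(seq_len(n_parts), n_samples))
  names(parts) <- NULL
  structure(list(partitions = lapply(parts, sort), seed = as.integer(seed)),
            class = "partition_plan")
}

#' Cross-validated regression metrics on one partition
#'
#' Fits the gradient-boosted model per fold, pools the out-of-fold
#' predictions, and applies [compute_metrics()] once to the pooled
#' predictions. With fewer samples than folds, a single fit-and-score on the
#' whole partition is returned with a warning.
#'
#' @param X numeric feature matrix (samples x selected sites).
#' @param y ages.
#' @param params a [gbr_params].
#' @param folds number of folds (default 3).
#' @param seed seed controlling fold assignment and per-fold fits.
#' @return a `regression_metrics` object.
#' @export
cv_regress_partition <- function(X, y, params = gbr_params(), folds = 3L,
                                 seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0L || ncol(X) == 0L) stop("empty partition or no features")
  if (n < folds) {
    warning("partition smaller than fold count; single fit-and-score")
    model <- fit_gbr(X, y, params, seed = derive_seed(seed, 1L))
    return(compute_metrics(y, predict(model, X)))
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- fit_gbr(X[tr, , drop = FALSE], y[tr], params,
                     seed = derive_seed(seed, f))
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  compute_metrics(y, pred)
}

# Average a list of regression_metrics arithmetically (the reduce step).
average_metrics <- function(metric_list) {
  agg <- function(field) mean(vapply(metric_list, `[[`, 0, field))
  structure(list(mad = agg("mad"), mse = agg("mse"), rmse = agg("rmse"),
                 r2 = mean(vapply(metric_list,
                                  function(m) m$r2 %||% NA_real_, 0))),
            class = "regression_metrics")
}

#' The chromosome fitness law
#'
#' `fitness = MAD + n_selected / 50`: one penalty unit per 50 selected CpG
#' sites on top of the partition-averaged cross-validated MAD, so that among
#' equal-MAD chromosomes the sparser panel ranks better. Lower is better.
#'
#' @param mad partition-averaged cross-validated MAD in years.
#' @param n_selected number of 1-genes (selected sites).
#' @return the fitness value.
#' @export
chromosome_fitness <- function(mad, n_selected) mad + n_selected / 50

# Fitness of one (already reduced) chromosome given per-partition metrics.
make_fitness_record <- function(metrics, n_selected) {
  structure(list(metrics = metrics, n_selected = as.integer(n_selected),
                 fitness = chromosome_fitness(metrics$mad, n_selected)),
            class = "fitness_record")
}

worst_fitness_record <- function() {
  structure(list(metrics = structure(list(mad = NA_real_, mse = NA_real_,
                                          rmse = NA_real_, r2 = NA_real_),
                                     class = "regression_metrics"),
                 n_selected = 0L, fitness = Inf),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("fitness %.4f (MAD %s, %d sites selected)\n", x$fitness,
              ifelse(is.na(x$metrics$mad), "NA", sprintf("%.4f", x$metrics$mad)),
              x$n_selected))
  invisible(x)
}

#' Evaluate one chromosome's fitness
#'
#' Reduces the dataset to the chromosome's selected sites, computes
#' cross-validated metrics on every partition of the plan, averages them
#' arithmetically, and scores
#' `fitness = averaged MAD + n_selected / 50` — one penalty unit per 50
#' selected sites, so sparser site panels win among equal-MAD chromosomes.
#' An all-zero chromosome gets `fitness = Inf` (worst possible) without
#' fitting any model, so degenerate offspring never crash a run.
#'
#' @param ds the (filtered) group training [methyl_dataset].
#' @param chromosome 0/1 gene vector over the sites of `ds`.
#' @param plan a [plan_partitions()] plan covering the samples of `ds`.
#' @param params a [gbr_params].
#' @param folds folds inside each partition.
#' @param chrom_index index of the chromosome within its population; it enters
#'   the per-work-unit seed derivation so population evaluation is
#'   reproducible at any parallelism degree.
#' @return an object of class `fitness_record`: `metrics`
#'   (partition-averaged), `n_selected`, `fitness`.
#' @export
evaluate_chromosome <- function(ds, chromosome, plan, params = gbr_params(),
                                folds = 3L, chrom_index = 1L) {
  stopifnot(inherits(plan, "partition_plan"))
  if (sum(chromosome) == 0L) return(worst_fitness_record())
  red <- reduce_dataset(ds, chromosome)
  parts <- plan$partitions
  if (!setequal(unlist(parts), seq_len(n_samples(ds))))
    stop("partition plan does not cover the dataset's samples")
  per_part <- lapply(seq_along(parts), function(j) {
    idx <- parts[[j]]
    cv_regress_partition(red$beta[idx, , drop = FALSE], red$age[idx], params,
                         folds = folds,
                         seed = derive_seed(params$seed, chrom_index, j))
  })
  make_fitness_record(average_metrics(per_part), sum(chromosome))
}

#' Evaluate a population of chromosomes (map/reduce)
#'
#' Semantically a map over independent (chromosome, partition) work units —
#' each computing cross-validated partial metrics — followed by a reduce that
#' averages the partials per chromosome and applies the selected-site-count
#' penalty. Every work unit derives its own seed from
#' `(params$seed, chromosome index, partition index)`, so results are
#' bit-identical at any `parallelism_degree`; degrees above 1 fork the work
#' units across processes.
#'
#' @param ds the (filtered) group training [methyl_dataset].
#' @param chromosomes list of 0/1 gene vectors.
#' @param plan a [plan_partitions()] plan.
#' @param params a [gbr_params].
#' @param parallelism_degree number of worker processes (default 1).
#' @param folds folds inside each partition.
#' @param index_offset added to each chromosome's position when deriving work
#'   unit seeds (used by the GA so offspring keep their absolute population
#'   index).
#' @return list of `fitness_record`s, one per chromosome, in input order.
#' @export
evaluate_population <- function(ds, chromosomes, plan, params = gbr_params(),
                                parallelism_degree = 1L, folds = 3L,
                                index_offset = 0L) {
  stopifnot(parallelism_degree >= 1L, is.list(chromosomes))
  n_chrom <- length(chromosomes)
  parts <- plan$partitions
  active <- which(vapply(chromosomes, function(ch) sum(ch) > 0L, TRUE))

  # map phase: one unit per (active chromosome, partition)
  units <- expand.grid(ci = active, pj = seq_along(parts))
  run_unit <- function(u) {
    ci <- units$ci[u]; pj <- units$pj[u]
    red <- reduce_dataset(ds, chromosomes[[ci]])
    idx <- parts[[pj]]
    tryCatch(
      cv_regress_partition(red$beta[idx, , drop = FALSE], red$age[idx], params,
                           folds = folds,
                           seed = derive_seed(params$seed,
                                              ci + index_offset, pj)),
      error = function(e) stop("work unit (chromosome ", ci + index_offset,
                               ", partition ", pj, ") failed: ",
                               conditionMessage(e)))
  }
  partials <- if (parallelism_degree > 1L && nrow(units) > 1L) {
    res <- parallel::mclapply(seq_len(nrow(units)), run_unit,
                              mc.cores = parallelism_degree,
                              mc.preschedule = TRUE)
    bad <- vapply(res, inherits, TRUE, "try-error")
    if (any(bad)) {
      cond <- attr(res[[which(bad)[1]]], "condition")
      stop(if (!is.null(cond)) conditionMessage(cond)
           else as.character(res[[which(bad)[1]]]))
    }
    res
  } else {
    lapply(seq_len(nrow(units)), run_unit)
  }

  # reduce phase: average partials per chromosome
  out <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    if (!ci %in% active) {
      out[[ci]] <- worst_fitness_record()
      next
    }
    mine <- partials[units$ci == ci]
    out[[ci]] <- make_fitness_record(average_metrics(mine),
                                     sum(chromosomes[[ci]]))
  }
  out
}
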