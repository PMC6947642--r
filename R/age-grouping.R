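#' Decade class labels for chronological ages
#'
#' Maps ages in \[0, 103\] to ten decade classes: class `floor(age/10) + 1`
#' for ages below 90, and class 10 for ages in \[90, 103\].
#'
#' @param ages numeric vector of ages in years.
#' @return integer vector of class labels in 1..10.
#' @export
decade_labels <- function(ages) {
  if (any(is.na(ages))) stop("missing ages")
  if (any(ages < 0 | ages > 103))
    stop("ages must lie in [0, 103]; offending value: ",
         ages[which(ages < 0 | ages > 103)[1]])
  pmin(10L, as.integer(floor(ages / 10)) + 1L)
}

#' Grouping schemes over decade classes
#'
#' A grouping scheme partitions the ten decade classes into ordered runs of
#' consecutive classes; each run induces an age interval (left-closed,
#' right-open, except the last which closes at 103), so the intervals tile
#' \[0, 103\].
#'
#' `scheme_identity()`, `scheme_five_groups()` and `scheme_three_groups()`
#' build the three reference schemes: all ten decades separate; the merged
#' five-group scheme (1), (2,3), (4,5), (6,7), (8,9,10); and the merged
#' three-group scheme (1,2), (3,4,5), (6,...,10) whose intervals are
#' \[0,20), \[20,50), \[50,103\].
#'
#' @param partition list of integer vectors; together they must cover classes
#'   1..10 exactly once, each a run of consecutive classes.
#' @return an object of class `grouping_scheme` with elements `partition` and
#'   `boundaries` (matrix of interval lower/upper bounds).
#' @export
grouping_scheme <- function(partition) {
  partition <- lapply(partition, function(x) sort(as.integer(x)))
  flat <- unlist(partition)
  if (!identical(sort(flat), 1:10))
    stop("partition must cover decade classes 1..10 exactly once")
  ok_runs <- vapply(partition, function(x) all(diff(x) == 1L), TRUE)
  if (!all(ok_runs)) stop("each group must be a run of consecutive classes")
  firsts <- vapply(partition, min, 0L)
  partition <- partition[order(firsts)]
  lower <- vapply(partition, function(x) (min(x) - 1L) * 10, 0)
  upper <- vapply(partition, function(x) if (max(x) == 10L) 103 else max(x) * 10, 0)
  structure(list(partition = partition,
                 boundaries = cbind(lower = lower, upper = upper)),
            class = "grouping_scheme")
}

#' @rdname grouping_scheme
#' @export
scheme_identity <- function() grouping_scheme(as.list(1:10))

#' @rdname grouping_scheme
#' @export
scheme_five_groups <- function()
  grouping_scheme(list(1L, c(2L, 3L), c(4L, 5L), c(6L, 7L), c(8L, 9L, 10L)))

#' @rdname grouping_scheme
#' @export
scheme_three_groups <- function()
  grouping_scheme(list(c(1L, 2L), c(3L, 4L, 5L), 6:10))

#' @export
print.grouping_scheme <- function(x, ...) {
  runs <- vapply(x$partition, function(p) paste(p, collapse = ","), "")
  cat("grouping_scheme: ", length(x$partition), " groups: (",
      paste(runs, collapse = ") ("), ")\n", sep = "")
  iv <- apply(x$boundaries, 1L, function(b)
    paste0("[", b[1], ",", b[2], ifelse(b[2] == 103, "]", ")")))
  cat("  age intervals: ", paste(iv, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Map decade classes to their merged group
#'
#' @param decade_label integer vector of decade classes in 1..10.
#' @param scheme a [grouping_scheme].
#' @return integer vector: index of the partition set containing each label.
#' @export
apply_scheme <- function(decade_label, scheme) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  if (any(!decade_label %in% 1:10)) stop("decade labels must lie in 1..10")
  lut <- integer(10)
  for (g in seq_along(scheme$partition)) lut[scheme$partition[[g]]] <- g
  lut[decade_label]
}

#' Fit the Stage-1 age-group classifier
#'
#' Projects the training betas onto their leading principal components and
#' fits a linear (L2-regularized multinomial logistic) classifier on the
#' projected features against the scheme's group labels — a linear decision
#' function over a 60-dimensional PCA embedding by default.
#'
#' @param train a [methyl_dataset] with ages, no missing values.
#' @param scheme a [grouping_scheme].
#' @param n_components number of principal components (default 60; must not
#'   exceed `min(n_samples, n_sites)`).
#' @param seed integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @param lambda ridge penalty of the linear classifier.
#' @return an object of class `group_classifier` holding the PCA projection
#'   (`center`, `rotation`), the fitted linear model and the scheme.
#' @export
fit_group_classifier <- function(train, scheme, n_components = 60L, seed = 1L,
                                 lambda = 1e-3) {
  stopifnot(inherits(train, "methyl_dataset"), inherits(scheme, "grouping_scheme"))
  if (is.null(train$age)) stop("train has no ages")
  if (anyNA(train$beta)) stop("missing betas; preprocess first")
  if (n_components > min(dim(train$beta)))
    stop("n_components (", n_components, ") exceeds min(samples, sites) = ",
         min(dim(train$beta)))
  y <- apply_scheme(decade_labels(train$age), scheme)
  present <- seq_along(scheme$partition) %in% y
  if (!all(present))
    stop("scheme group(s) with no training sample: ",
         paste(which(!present), collapse = ", "))

  pca <- stats::prcomp(train$beta, center = TRUE, scale. = FALSE,
                       rank. = n_components)
  Z <- pca$x
  n_groups <- length(scheme$partition)
  model <- NULL
  if (n_groups > 1L) {
    # glmnet is unreliable with a length-1 lambda; fit a short decreasing
    # path down to the target and predict at s = lambda later
    lambda_path <- sort(unique(c(10, 1, 0.1, 0.01, lambda)), decreasing = TRUE)
    model <- with_seed(seed,
      glmnet::glmnet(Z, factor(y, levels = seq_len(n_groups)),
                     family = "multinomial", alpha = 0, lambda = lambda_path,
                     standardize = FALSE))
  }
  structure(list(center = pca$center, rotation = pca$rotation, model = model,
                 scheme = scheme, lambda = lambda,
                 site_ids = site_ids(train),
                 n_components = ncol(pca$rotation)),
            class = "group_classifier")
}

#' Predict age-group labels with a fitted Stage-1 classifier
#'
#' @param object a `group_classifier` from [fit_group_classifier()].
#' @param newdata a [methyl_dataset] (or beta matrix) with the same sites, in
#'   the same order, as the training data.
#' @param ... unused.
#' @return integer vector of predicted group indices.
#' @export
predict.group_classifier <- function(object, newdata, ...) {
  b <- if (inherits(newdata, "methyl_dataset")) newdata$beta else as.matrix(newdata)
  if (!identical(colnames(b), object$site_ids))
    stop("site ids of newdata differ from those seen at fit time")
  Z <- sweep(b, 2L, object$center, "-") %*% object$rotation
  if (is.null(object$model)) return(rep(1L, nrow(Z)))
  pr <- stats::predict(object$model, newx = Z, type = "response",
                       s = object$lambda)[, , 1L]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
  as.integer(max.col(pr, ties.method = "first"))
}

#' Assign predicted age groups to a dataset
#'
#' Populates the dataset's `group` field with the classifier's predicted
#' labels — not with the true ages — which is how unseen samples are routed
#' to their per-group regression model.
#'
#' @param classifier a `group_classifier`.
#' @param test a [methyl_dataset] with the classifier's sites.
#' @return `test` with `$group` set to the predicted group index (character).
#' @export
assign_groups <- function(classifier, test) {
  test$group <- as.character(predict(classifier, test))
  validate_methyl_dataset(test)
  test
}

#' Cross-validated confusion matrix of the Stage-1 classifier
#'
#' Stratified k-fold cross-validation: every sample is predicted exactly once
#' by a classifier not trained on it, and the label/prediction pairs are
#' aggregated into a confusion matrix over the scheme's groups.
#'
#' @param train a [methyl_dataset] with ages, no missing values.
#' @param scheme a [grouping_scheme]; use [scheme_identity()] to obtain the
#'   10-decade-class matrix that seeds the class-merging step.
#' @param folds number of folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @param n_components PCA dimensionality passed to [fit_group_classifier()].
#' @return an object of class `confusion_matrix`: `counts` (true x predicted),
#'   `class_order`, and the `scheme`.
#' @export
cv_confusion <- function(train, scheme, folds = 3L, seed = 1L,
                         n_components = 60L) {
  y <- apply_scheme(decade_labels(train$age), scheme)
  n_groups <- length(scheme$partition)
  tab <- tabulate(y, n_groups)
  if (any(tab < folds))
    stop("group(s) with fewer samples than folds: ",
         paste(which(tab < folds), collapse = ", "))

  fold <- integer(length(y))
  with_seed(seed, for (g in seq_len(n_groups)) {
    idx <- which(y == g)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  })

  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    tr <- subset_dataset(train, samples = fold != f)
    cls <- fit_group_classifier(tr, scheme,
                                n_components = min(n_components,
                                                   min(dim(tr$beta))),
                                seed = derive_seed(seed, f))
    pred[fold == f] <- predict(cls, subset_dataset(train, samples = fold == f))
  }
  counts <- matrix(0L, n_groups, n_groups,
                   dimnames = list(true = seq_len(n_groups),
                                   predicted = seq_len(n_groups)))
  for (i in seq_along(y)) counts[y[i], pred[i]] <- counts[y[i], pred[i]] + 1L
  structure(list(counts = counts, class_order = seq_len(n_groups),
                 scheme = scheme),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix over", nrow(x$counts), "classes",
      sprintf("(accuracy %.3f)\n", sum(diag(x$counts)) / sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Merge classes by confusion-matrix similarity
#'
#' Automates the confusion-driven class merging: repeatedly merge the adjacent
#' pair of groups with the highest symmetrized confusion rate — misclassified
#' counts between the pair divided by the pair's total samples — re-aggregate
#' the matrix, and stop when `target_groups` remain. Ties are broken toward
#' the lower class index. Only adjacent (consecutive-age) groups may merge, so
#' the result is always a valid [grouping_scheme] of age intervals.
#'
#' @param confusion a `confusion_matrix` from [cv_confusion()].
#' @param target_groups desired number of groups.
#' @return the merged [grouping_scheme].
#' @export
merge_by_confusion <- function(confusion, target_groups) {
  stopifnot(inherits(confusion, "confusion_matrix"))
  C <- confusion$counts
  parts <- confusion$scheme$partition
  if (target_groups > length(parts))
    stop("target_groups (", target_groups, ") exceeds current class count (",
         length(parts), ")")
  while (length(parts) > target_groups) {
    k <- length(parts)
    rate <- vapply(seq_len(k - 1L), function(i) {
      cross <- C[i, i + 1L] + C[i + 1L, i]
      tot <- sum(C[i, ]) + sum(C[i + 1L, ])
      if (tot == 0) 0 else cross / tot
    }, 0)
    i <- which.max(rate)  # which.max takes the first (lowest-index) maximum
    # aggregate rows/cols i and i+1
    C[i, ] <- C[i, ] + C[i + 1L, ]
    C <- C[-(i + 1L), , drop = FALSE]
    C[, i] <- C[, i] + C[, i + 1L]
    C <- C[, -(i + 1L), drop = FALSE]
    parts[[i]] <- sort(c(parts[[i]], parts[[i + 1L]]))
    parts[[i + 1L]] <- NULL
  }
  grouping_scheme(parts)
}
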