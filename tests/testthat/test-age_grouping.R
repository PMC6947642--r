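test_that("decade labels follow the 10-class convention", {
  expect_equal(decade_labels(c(0, 9.99, 10)), c(1L, 1L, 2L))
  expect_equal(decade_labels(c(89.9, 90, 103)), c(9L, 10L, 10L))
  expect_error(decade_labels(-1), "\\[0, 103\\]")
  expect_error(decade_labels(104), "\\[0, 103\\]")
})

test_that("reference schemes induce the expected age intervals", {
  s3g <- scheme_three_groups()
  expect_equal(s3g$boundaries[, "lower"], c(0, 20, 50))
  expect_equal(s3g$boundaries[, "upper"], c(20, 50, 103))
  expect_equal(apply_scheme(3L, s3g), 2L)  # class 3 (ages 20-30) -> group 2
  expect_equal(apply_scheme(1L, scheme_identity()), 1L)
  # every decade label maps to exactly one group under any scheme
  for (sch in list(scheme_identity(), scheme_five_groups(), s3g)) {
    expect_equal(vapply(1:10, function(l) length(apply_scheme(l, sch)), 0L),
                 rep(1L, 10))
  }
  s5g <- scheme_five_groups()
  expect_equal(lengths(s5g$partition), c(1L, 2L, 2L, 2L, 3L))
})

test_that("grouping_scheme validates partitions", {
  expect_error(grouping_scheme(list(1:5)), "1..10")
  expect_error(grouping_scheme(list(c(1L, 3L), 2L, 4:10)), "consecutive")
  expect_silent(grouping_scheme(list(10:6, 5:1)))  # order normalized
})

test_that("the classifier is perfect on a separable toy and errors sensibly", {
  set.seed(99)
  n <- 30
  ages <- c(runif(n / 3, 0, 15), runif(n / 3, 25, 45), runif(n / 3, 60, 90))
  grp <- apply_scheme(decade_labels(ages), scheme_three_groups())
  beta <- cbind(lo = c(0.1, 0.5, 0.9)[grp] + runif(n, 0, 0.01),
                hi = c(0.8, 0.5, 0.2)[grp] + runif(n, 0, 0.01),
                x3 = runif(n))
  ds <- methyl_dataset(beta, age = ages)
  cls <- fit_group_classifier(ds, scheme_three_groups(), n_components = 3)
  expect_equal(predict(cls, ds),
               apply_scheme(decade_labels(ages), scheme_three_groups()))
  expect_error(fit_group_classifier(ds, scheme_three_groups(),
                                    n_components = 50), "n_components")
  # group 2 (ages 20-50) has no samples under the identity scheme
  expect_error(fit_group_classifier(ds, scheme_identity(), n_components = 3),
               "no training sample")
})

test_that("cv_confusion satisfies counting invariants", {
  coh <- make_regime_cohort(n = 240)
  ds <- coh$dataset
  cm <- cv_confusion(ds, scheme_three_groups(), folds = 3, seed = 5,
                     n_components = 20)
  y <- apply_scheme(decade_labels(ds$age), scheme_three_groups())
  expect_equal(unname(rowSums(cm$counts)), unname(tabulate(y, 3)))
  expect_equal(sum(cm$counts), n_samples(ds))
  expect_error(cv_confusion(subset_dataset(ds, samples = ds$age < 30),
                            scheme_three_groups(), folds = 3),
               "fewer samples")
})

test_that("Stage-1 recovers regimes on a separable synthetic cohort", {
  coh <- make_regime_cohort(n = 420, seed = 12)
  sp <- split_train_test(coh$dataset, seed = 3)
  cm <- cv_confusion(sp$train, scheme_three_groups(), folds = 3, seed = 5,
                     n_components = 30)
  expect_gte(sum(diag(cm$counts)) / sum(cm$counts), 0.9)

  cls <- fit_group_classifier(sp$train, scheme_three_groups(),
                              n_components = 30)
  labeled <- assign_groups(cls, sp$test)
  truth <- apply_scheme(decade_labels(sp$test$age), scheme_three_groups())
  expect_gte(mean(as.integer(labeled$group) == truth), 0.9)
  expect_length(labeled$group, n_samples(sp$test))
  # predicted labels, not true ages, are stored
  expect_type(labeled$group, "character")
})

test_that("merge_by_confusion recovers block structure and honors tie-breaks", {
  fake_confusion <- function(counts, scheme = scheme_identity()) {
    structure(list(counts = counts, class_order = seq_len(nrow(counts)),
                   scheme = scheme), class = "confusion_matrix")
  }
  # block-diagonal: classes 1-2, 3-5, 6-10 confused within blocks only
  C <- matrix(0L, 10, 10)
  blocks <- list(1:2, 3:5, 6:10)
  for (b in blocks) C[b, b] <- 5L
  sch <- merge_by_confusion(fake_confusion(C), 3)
  expect_equal(sch$partition, lapply(blocks, as.integer))

  # identity target: nothing merges
  sch10 <- merge_by_confusion(fake_confusion(C), 10)
  expect_equal(sch10$partition, as.list(1:10))

  # all-diagonal: every merge tied; lowest-index pair merges first
  D <- diag(10L) * 7L
  sch5 <- merge_by_confusion(fake_confusion(D), 5)
  expect_equal(sch5$partition[[1]], 1:6)
  expect_equal(lengths(sch5$partition), c(6L, 1L, 1L, 1L, 1L))

  expect_error(merge_by_confusion(fake_confusion(D), 11), "exceeds")
})

test_that("greedy merging always yields runs of consecutive classes", {
  set.seed(21)
  for (i in 1:20) {
    C <- matrix(rpois(100, 3), 10, 10)
    fake <- structure(list(counts = C, class_order = 1:10,
                           scheme = scheme_identity()),
                      class = "confusion_matrix")
    for (target in c(5, 3)) {
      sch <- merge_by_confusion(fake, target)
      expect_true(all(vapply(sch$partition,
                             function(p) all(diff(p) == 1L), TRUE)))
      expect_equal(sort(unlist(sch$partition)), 1:10)
    }
    # merging to 3 via 5 also yields consecutive runs
    sch5 <- merge_by_confusion(fake, 5)
    agg <- matrix(0L, 5, 5)
    for (a in 1:5) for (b in 1:5) {
      agg[a, b] <- sum(C[sch5$partition[[a]], sch5$partition[[b]]])
    }
    fake5 <- structure(list(counts = agg, class_order = 1:5, scheme = sch5),
                       class = "confusion_matrix")
    sch3 <- merge_by_confusion(fake5, 3)
    expect_true(all(vapply(sch3$partition,
                           function(p) all(diff(p) == 1L), TRUE)))
  }
})

test_that("Stage-1 accuracy does not decrease as groups get coarser", {
  coh <- make_regime_cohort(n = 300, seed = 44)
  ds <- coh$dataset
  acc <- vapply(list(scheme_identity(), scheme_five_groups(),
                     scheme_three_groups()), function(sch) {
    cm <- cv_confusion(ds, sch, folds = 3, seed = 9, n_components = 20)
    sum(diag(cm$counts)) / sum(cm$counts)
  }, 0)
  expect_true(all(diff(acc) >= 0))
})
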