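test_that("compute_metrics matches hand arithmetic and definitions", {
  m <- compute_metrics(c(10, 20), c(12, 18))
  expect_equal(m$mad, 2)
  expect_equal(m$mse, 4)
  expect_equal(m$rmse, 2)

  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mad, 0)
  expect_equal(perfect$r2, 1)

  y <- c(4, 8, 12)
  at_mean <- compute_metrics(y, rep(mean(y), 3))
  expect_equal(at_mean$r2, 0)

  expect_true(is.na(compute_metrics(c(5, 5), c(4, 6))$r2))
  expect_error(compute_metrics(1:3, 1:2), "equal")
})

test_that("compute_metrics agrees with brute-force recomputation to 1e-12", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    y <- runif(n, 0, 100)
    yhat <- y + rnorm(n, 0, 5)
    m <- compute_metrics(y, yhat)
    # independent loop-based recomputation of the four formulas
    s_abs <- 0; s_sq <- 0; s_tot <- 0; ybar <- sum(y) / n
    for (j in seq_len(n)) {
      s_abs <- s_abs + abs(y[j] - yhat[j])
      s_sq <- s_sq + (y[j] - yhat[j])^2
      s_tot <- s_tot + (y[j] - ybar)^2
    }
    expect_equal(m$mad, s_abs / n, tolerance = 1e-12)
    expect_equal(m$mse, s_sq / n, tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(s_sq / n), tolerance = 1e-12)
    expect_equal(m$r2, 1 - s_sq / s_tot, tolerance = 1e-12)
  }
})

test_that("reduce_dataset keeps 1-gene columns in order", {
  ds <- make_tiny_ds()
  ds3 <- methyl_dataset(cbind(a = c(0.1, 0.2), b = c(0.3, 0.4),
                              c = c(0.5, 0.6)), age = c(1, 2))
  expect_equal(site_ids(reduce_dataset(ds3, c(1, 0, 1))), c("a", "c"))
  expect_equal(reduce_dataset(ds3, c(1, 1, 1))$beta, ds3$beta)
  expect_error(reduce_dataset(ds3, c(1, 0)), "length")
  expect_error(reduce_dataset(ds3, c(0, 0, 0)), "all-zero")
})

test_that("plan_partitions deals balanced seeded partitions", {
  p300 <- plan_partitions(300, 100, seed = 1)
  expect_length(p300$partitions, 3L)
  expect_equal(lengths(p300$partitions), rep(100L, 3))

  p250 <- plan_partitions(250, 100, seed = 1)
  expect_equal(sort(lengths(p250$partitions)), c(125L, 125L))

  p80 <- plan_partitions(80, 100, seed = 1)
  expect_length(p80$partitions, 1L)
  expect_equal(p80$partitions[[1]], 1:80)

  expect_setequal(unlist(p300$partitions), 1:300)
  expect_identical(plan_partitions(300, 100, seed = 1), p300)
})

test_that("cv_regress_partition learns easy signal and not shuffled noise", {
  set.seed(6)
  X <- matrix(runif(90), 90, 1)
  y <- 100 * X[, 1]
  easy <- cv_regress_partition(X, y, gbr_params(), folds = 3, seed = 2)
  expect_lt(easy$mad, 2)

  y_shuf <- sample(y)
  null <- cv_regress_partition(X, y_shuf, gbr_params(), folds = 3, seed = 2)
  expect_lte(null$r2, 0.1)

  again <- cv_regress_partition(X, y, gbr_params(), folds = 3, seed = 2)
  expect_identical(easy, again)

  expect_warning(tiny <- cv_regress_partition(X[1:2, , drop = FALSE], y[1:2],
                                              gbr_params(), folds = 3),
                 "single fit")
  expect_s3_class(tiny, "regression_metrics")
})

test_that("evaluate_chromosome applies the fitness law", {
  expect_equal(chromosome_fitness(3.0, 100), 5.0)
  expect_equal(chromosome_fitness(3.0, 50), 4.0)

  coh <- make_clean_cohort(n = 90, p = 20, k = 3)
  ds <- coh$dataset
  plan <- plan_partitions(90, 45, seed = 3)
  ch <- rep(c(1L, 0L), c(5, 15))
  rec <- evaluate_chromosome(ds, ch, plan, gbr_params(seed = 4))
  expect_equal(rec$n_selected, 5L)
  expect_equal(rec$fitness, rec$metrics$mad + 5 / 50)
  expect_gte(rec$metrics$rmse, rec$metrics$mad)
  # rmse = sqrt(mse) holds per partition (the averaged record averages rmses)
  single <- cv_regress_partition(ds$beta[1:45, 1:5], ds$age[1:45],
                                 gbr_params(seed = 4), seed = 9)
  expect_equal(single$rmse, sqrt(single$mse), tolerance = 1e-12)
  expect_gte(single$rmse, single$mad)

  zero <- evaluate_chromosome(ds, rep(0L, 20), plan, gbr_params())
  expect_identical(zero$fitness, Inf)
})

test_that("population evaluation is a pure map/reduce", {
  coh <- make_clean_cohort(n = 100, p = 15, k = 3, seed = 8)
  ds <- coh$dataset
  plan <- plan_partitions(100, 50, seed = 5)
  pop <- init_population(ga_config(population_size = 5, elitism_count = 1,
                                   chromosome_length = 15, init_density = 0.3,
                                   seed = 77))
  par <- gbr_params(n_estimators = 60, seed = 13)

  r1 <- evaluate_population(ds, pop, plan, par, parallelism_degree = 1)
  r4 <- evaluate_population(ds, pop, plan, par, parallelism_degree = 4)
  expect_identical(r1, r4)

  single <- evaluate_population(ds, pop[1], plan, par)
  expect_equal(single[[1]],
               evaluate_chromosome(ds, pop[[1]], plan, par, chrom_index = 1L))

  # reduce is the arithmetic mean of per-partition MADs
  per_part <- lapply(seq_along(plan$partitions), function(j) {
    idx <- plan$partitions[[j]]
    red <- reduce_dataset(ds, pop[[1]])
    cv_regress_partition(red$beta[idx, , drop = FALSE], red$age[idx], par,
                         seed = cpgselect:::derive_seed(par$seed, 1L, j))
  })
  expect_equal(r1[[1]]$metrics$mad,
               mean(vapply(per_part, `[[`, 0, "mad")))

  # an all-zero member degrades to the worst-fitness sentinel
  pop0 <- c(pop[1], list(rep(0L, 15)))
  r0 <- evaluate_population(ds, pop0, plan, par)
  expect_identical(r0[[2]]$fitness, Inf)
  expect_identical(r0[[1]], r1[[1]])
})
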