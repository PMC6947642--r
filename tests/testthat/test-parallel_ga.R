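test_that("init_population matches the binomial law and never emits all-zeros", {
  conf <- ga_config(population_size = 100, chromosome_length = 8000,
                    init_density = 0.0125, seed = 5)
  pop <- init_population(conf)
  ones <- vapply(pop, sum, 0L)
  # per-chromosome 1-count ~ Binomial(8000, 0.0125): mean 100, sd ~ 9.9
  expect_lt(abs(mean(ones) - 100), 15)
  expect_true(all(ones > 0L))
  expect_identical(init_population(conf), pop)

  # density so low that all-zero draws occur: they must be redrawn
  tiny <- ga_config(population_size = 50, elitism_count = 1,
                    chromosome_length = 4, init_density = 0.05, seed = 2)
  expect_true(all(vapply(init_population(tiny), sum, 0L) > 0L))
})

test_that("roulette selection favors low fitness with inverse weights", {
  expect_equal(roulette_select(5, seed = 1), c(1L, 1L))
  draws <- roulette_select(c(1, Inf), seed = 3, n = 500)
  expect_true(all(draws == 1L))
  expect_warning(u <- roulette_select(c(Inf, Inf), seed = 4), "uniform")
  expect_true(all(u %in% 1:2))

  # equal fitnesses: empirical frequencies uniform within 3 sigma
  k <- 4
  draws <- roulette_select(rep(2, k), seed = 9, n = 10000)
  freq <- tabulate(draws, k)
  expect_true(all(abs(freq - 2500) < 3 * sqrt(10000 * (1 / k) * (1 - 1 / k))))

  # weight ratio 2:1 shows through
  draws <- roulette_select(c(1, 2), seed = 11, n = 30000)
  expect_equal(mean(draws == 1L), 2 / 3, tolerance = 0.02)
})

test_that("parent-difference crossover preserves agreements and complements", {
  p1 <- c(1L, 1L, 0L, 0L)
  p2 <- c(1L, 0L, 1L, 0L)
  kids <- crossover_parent_difference(p1, p2, seed = 8)
  expect_equal(kids$c1[c(1, 4)], c(1L, 0L))
  expect_equal(kids$c2[c(1, 4)], c(1L, 0L))
  expect_equal(kids$c2[2:3], 1L - kids$c1[2:3])

  same <- crossover_parent_difference(p1, p1, seed = 1)
  expect_equal(same$c1, p1)
  expect_equal(same$c2, p1)
  expect_error(crossover_parent_difference(p1, p2[1:3]), "lengths")

  set.seed(31)
  for (i in 1:200) {
    a <- sample(0:1, 60, replace = TRUE)
    b <- sample(0:1, 60, replace = TRUE)
    kids <- crossover_parent_difference(a, b)
    agree <- a == b
    expect_true(all(kids$c1[agree] == a[agree]))
    expect_true(all(kids$c2[agree] == a[agree]))
    expect_equal(xor(kids$c1, kids$c2), xor(a, b))
    expect_equal(sum(kids$c1) + sum(kids$c2), sum(a) + sum(b))
  }
})

test_that("balanced mutation flips exactly k genes from balanced pools", {
  ch <- rep(c(1L, 0L), c(30, 30))
  out <- mutate_balanced(ch, 4, seed = 2)
  expect_equal(sum(out != ch), 4L)
  expect_identical(mutate_balanced(ch, 0, seed = 2), ch)

  zeros <- rep(0L, 10)
  out0 <- mutate_balanced(zeros, 2, seed = 5)
  expect_equal(sum(out0), 2L)  # empty 1-pool: both flips are 0 -> 1

  expect_equal(sum(mutate_balanced(ch, 100, seed = 1) != ch), 60L)  # k capped

  # both flip directions near 50% when pools are large
  set.seed(12)
  flips10 <- replicate(400, {
    m <- mutate_balanced(ch, 4)
    sum(ch == 1L & m == 0L)
  })
  expect_equal(mean(flips10) / 4, 0.5, tolerance = 0.05)
})

test_that("next_generation preserves elites and population size", {
  conf <- ga_config(population_size = 10, elitism_count = 3, mutation_k = 2,
                    chromosome_length = 12, init_density = 0.4, seed = 3)
  pop <- init_population(conf)
  fits <- c(5, 1, 7, 2, 2, 9, 4, 8, 6, 3)
  nx <- next_generation(pop, fits, conf, seed = 21)
  expect_length(nx$population, 10L)
  expect_equal(nx$elite_indices, c(2L, 4L, 5L))  # tie at 2 -> lower index
  expect_identical(nx$population[[1]], pop[[2]])
  expect_identical(nx$population[[2]], pop[[4]])
  expect_identical(nx$population[[3]], pop[[5]])
})

test_that("run_ga is monotone, deterministic across degrees, and beats baseline", {
  coh <- make_clean_cohort(n = 120, p = 30, k = 4, seed = 14)
  ds <- coh$dataset
  conf <- ga_config(population_size = 10, generations = 6, elitism_count = 2,
                    mutation_k = 3, chromosome_length = 30,
                    init_density = 0.15, seed = 19)
  par <- gbr_params(n_estimators = 80, seed = 1)
  res <- run_ga(ds, conf, par, target_size = 60, folds = 3)

  expect_equal(nrow(res$history), 6L)
  expect_true(all(diff(res$history$best) <= 0))  # elitism monotonicity
  res4 <- run_ga(ds, conf, par, parallelism_degree = 4, target_size = 60)
  expect_identical(res$best_chromosome, res4$best_chromosome)
  expect_identical(res$history, res4$history)

  penalty <- sum(res$best_chromosome) / 50
  expect_lt(res$best_fitness, baseline_mad(ds) + penalty)
})

test_that("run_all_groups runs one independent GA per group", {
  coh <- make_clean_cohort(n = 180, p = 25, k = 4, seed = 23)
  ds <- coh$dataset
  grp <- apply_scheme(decade_labels(ds$age), scheme_three_groups())
  grouped <- lapply(1:3, function(g) subset_dataset(ds, samples = grp == g))
  names(grouped) <- as.character(1:3)
  conf <- ga_config(population_size = 6, generations = 3, elitism_count = 1,
                    mutation_k = 2, chromosome_length = 25,
                    init_density = 0.2, seed = 4)
  par <- gbr_params(n_estimators = 50, seed = 2)
  res <- run_all_groups(grouped, conf, par, target_size = 50)
  expect_named(res, c("1", "2", "3"))
  expect_true(all(vapply(res, function(r) !inherits(r, "ga_group_error"), TRUE)))

  one <- run_all_groups(grouped[1], conf, par, target_size = 50)
  solo_conf <- conf
  solo_conf$seed <- cpgselect:::derive_seed(conf$seed, 17L, 1L)
  solo <- run_ga(grouped[[1]], solo_conf, par, target_size = 50)
  expect_identical(one[["1"]]$best_chromosome, solo$best_chromosome)

  # a failing group is reported per group, not as a global abort
  broken <- grouped
  broken[["2"]] <- subset_dataset(broken[["2"]], samples = 1:3)
  res2 <- run_all_groups(broken, conf, par, target_size = 50)
  expect_s3_class(res2[["2"]], "ga_group_error")
  expect_false(inherits(res2[["1"]], "ga_group_error"))
})
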