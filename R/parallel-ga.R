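#' Genetic-algorithm configuration
#'
#' The run-time constants of the site-selecting GA. Defaults follow the
#' reference setup: 100 chromosomes over a panel of 8000
#' correlation-prefiltered CpG sites, evolved for 100 generations with
#' roulette-wheel selection, agreement-preserving crossover, balanced k-gene
#' mutation and preservation of the 10 best chromosomes per generation.
#' `init_density` (expected fraction of 1-genes at initialization, default
#' 0.0125, i.e. ~100 selected sites of 8000) and `mutation_k` (default 20
#' flipped genes, roughly a classical 0.25% per-gene rate on 8000 genes) are
#' tuning knobs the reference setup leaves open.
#'
#' @param population_size chromosomes per generation.
#' @param generations number of generations (the termination criterion).
#' @param elitism_count best chromosomes copied unchanged each generation.
#' @param mutation_k genes flipped per mutation.
#' @param chromosome_length panel size (genes per chromosome).
#' @param init_density expected fraction of 1-genes at initialization,
#'   in (0,1).
#' @param seed master seed of the run.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      elitism_count = 10L, mutation_k = 20L,
                      chromosome_length = 8000L, init_density = 0.0125,
                      seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            elitism_count >= 0, elitism_count < population_size,
            mutation_k >= 0, chromosome_length >= 1,
            init_density > 0, init_density < 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elitism_count = as.integer(elitism_count),
                 mutation_k = as.integer(mutation_k),
                 chromosome_length = as.integer(chromosome_length),
                 init_density = init_density, seed = as.integer(seed)),
            class = "ga_config")
}

#' Initialize a random population
#'
#' Each gene is independently 1 with probability `init_density`; any all-zero
#' draw is redrawn, so every emitted chromosome selects at least one site.
#'
#' @param config a [ga_config].
#' @param seed overrides `config$seed` when given.
#' @return list of integer 0/1 vectors of length `chromosome_length`.
#' @export
init_population <- function(config, seed = config$seed) {
  with_seed(seed, lapply(seq_len(config$population_size), function(i) {
    repeat {
      ch <- as.integer(stats::runif(config$chromosome_length) < config$init_density)
      if (sum(ch) > 0L) return(ch)
    }
  }))
}

#' Roulette-wheel parent selection for a minimized fitness
#'
#' Draws two independent parent indices with probability proportional to
#' `w_i = 1 / (fitness_i + 1e-9)`, so lower (better) fitness means a higher
#' chance. Infinite fitnesses get weight 0; if every fitness is infinite the
#' draw is uniform, with a warning.
#'
#' @param fitnesses numeric vector of fitness values (lower is better).
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @param n number of indices to draw (default 2: one parent pair).
#' @return integer vector of `n` selected indices.
#' @export
roulette_select <- function(fitnesses, seed = NULL, n = 2L) {
  if (length(fitnesses) == 0L) stop("empty fitness vector")
  w <- 1 / (fitnesses + 1e-9)
  w[!is.finite(fitnesses)] <- 0
  if (all(w == 0)) {
    warning("all fitnesses infinite; selecting uniformly")
    w <- rep(1, length(fitnesses))
  }
  if (length(fitnesses) == 1L) return(rep(1L, n))
  with_seed(seed, sample.int(length(fitnesses), n, replace = TRUE, prob = w))
}

#' Agreement-preserving ("parent difference") crossover
#'
#' Where the two parents agree, both children copy the shared gene. Where
#' they differ, the first child's gene is a fair coin flip and the second
#' child's gene is its complement — so `c1 XOR c2 = p1 XOR p2` and the total
#' number of 1-genes in the offspring equals that of the parents.
#'
#' @param p1,p2 parent gene vectors of equal length.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return list with elements `c1` and `c2`.
#' @export
crossover_parent_difference <- function(p1, p2, seed = NULL) {
  if (length(p1) != length(p2)) stop("parent lengths differ")
  c1 <- as.integer(p1)
  diff <- which(p1 != p2)
  if (length(diff)) {
    coin <- with_seed(seed, as.integer(stats::runif(length(diff)) < 0.5))
    c1[diff] <- coin
  }
  c2 <- as.integer(p2)
  c2[diff] <- 1L - c1[diff]
  list(c1 = c1, c2 = c2)
}

#' Balanced k-gene mutation
#'
#' Flips exactly `min(k, length)` genes in `k` steps: each step a fair coin
#' chooses between the pool of not-yet-flipped 1-genes and the pool of
#' not-yet-flipped 0-genes, then flips a uniformly chosen position from that
#' pool (falling back to the other pool when the chosen one is empty). Unlike
#' uniform per-gene mutation, 0-to-1 and 1-to-0 flips are equally likely even
#' on the very sparse chromosomes this problem produces.
#'
#' @param chromosome 0/1 gene vector.
#' @param k number of genes to flip.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return the mutated chromosome.
#' @export
mutate_balanced <- function(chromosome, k, seed = NULL) {
  ch <- as.integer(chromosome)
  k <- min(as.integer(k), length(ch))
  if (k <= 0L) return(ch)
  with_seed(seed, {
    pool1 <- which(ch == 1L)
    pool0 <- which(ch == 0L)
    for (step in seq_len(k)) {
      pick1 <- stats::runif(1) < 0.5
      if (pick1 && length(pool1) == 0L) pick1 <- FALSE
      if (!pick1 && length(pool0) == 0L) pick1 <- TRUE
      if (pick1) {
        j <- if (length(pool1) == 1L) 1L else sample.int(length(pool1), 1L)
        pos <- pool1[j]
        pool1 <- pool1[-j]
      } else {
        j <- if (length(pool0) == 1L) 1L else sample.int(length(pool0), 1L)
        pos <- pool0[j]
        pool0 <- pool0[-j]
      }
      ch[pos] <- 1L - ch[pos]
    }
  })
  ch
}

#' Produce the next generation
#'
#' Generational replacement with elitism: the `elitism_count` chromosomes of
#' lowest fitness (ties broken toward the lower population index) are copied
#' unchanged; the remaining slots are filled by roulette-selected parent
#' pairs passed through crossover and mutation of both children. If an odd
#' number of slots remains, the second child of the final pair is discarded.
#'
#' @param population list of chromosomes.
#' @param fitnesses numeric vector of their fitness values.
#' @param config a [ga_config].
#' @param seed optional seed for this generation's operator randomness;
#'   `NULL` draws from the current RNG stream.
#' @return list with `population` (the new generation) and `elite_indices`
#'   (positions in the old population of the preserved elites, in rank
#'   order).
#' @export
next_generation <- function(population, fitnesses, config, seed = NULL) {
  stopifnot(length(population) == length(fitnesses))
  n <- length(population)
  elite_idx <- order(fitnesses)[seq_len(config$elitism_count)]
  offspring <- vector("list", n - config$elitism_count)
  with_seed(seed, {
    slot <- 1L
    while (slot <= length(offspring)) {
      parents <- roulette_select(fitnesses)
      kids <- crossover_parent_difference(population[[parents[1]]],
                                          population[[parents[2]]])
      offspring[[slot]] <- mutate_balanced(kids$c1, config$mutation_k)
      slot <- slot + 1L
      if (slot <= length(offspring)) {
        offspring[[slot]] <- mutate_balanced(kids$c2, config$mutation_k)
        slot <- slot + 1L
      }
    }
  })
  list(population = c(population[elite_idx], offspring),
       elite_indices = elite_idx)
}

#' Run the genetic algorithm on one age group
#'
#' The outer loop: evaluate the population (map/reduce over chromosome x
#' partition work units), log per-generation best/average/worst fitness, and
#' breed the next generation, for a fixed number of generations. Elite
#' chromosomes carried unchanged keep their cached fitness records, so the
#' best fitness per generation is non-increasing by construction. Fully
#' deterministic for a fixed `ga_conf$seed` at any parallelism degree.
#'
#' @param ds the correlation-filtered group training [methyl_dataset]; its
#'   site count must equal `ga_conf$chromosome_length`.
#' @param ga_conf a [ga_config].
#' @param gbr_par a [gbr_params]; its seed is re-derived from the GA seed so
#'   one master seed controls the whole run.
#' @param parallelism_degree worker processes for population evaluation.
#' @param target_size nominal fitness-partition size (default 100 samples).
#' @param folds cross-validation folds inside each partition.
#' @return list with `best_chromosome`, `best_fitness`, `best_record`, and
#'   `history` (data.frame: generation, best, avg, worst) plus
#'   `best_per_generation` (list of chromosomes).
#' @export
run_ga <- function(ds, ga_conf, gbr_par = gbr_params(),
                   parallelism_degree = 1L, target_size = 100L, folds = 3L) {
  stopifnot(inherits(ga_conf, "ga_config"), inherits(gbr_par, "gbr_params"))
  if (n_sites(ds) != ga_conf$chromosome_length)
    stop("chromosome_length (", ga_conf$chromosome_length,
         ") != dataset site count (", n_sites(ds), ")")
  if (n_samples(ds) < 2L * folds)
    stop("need at least ", 2L * folds, " samples")

  gbr_par$seed <- derive_seed(ga_conf$seed, 7L)
  plan <- plan_partitions(n_samples(ds), target_size,
                          seed = derive_seed(ga_conf$seed, 11L))
  population <- init_population(ga_conf)
  records <- NULL

  hist_best <- hist_avg <- hist_worst <- numeric(ga_conf$generations)
  best_per_gen <- vector("list", ga_conf$generations)
  overall_best <- NULL

  for (gen in seq_len(ga_conf$generations)) {
    if (is.null(records)) {
      records <- evaluate_population(ds, population, plan, gbr_par,
                                     parallelism_degree, folds)
    } else {
      # elites (slots 1..E) keep their cached records; offspring are new
      new_idx <- seq.int(ga_conf$elitism_count + 1L, ga_conf$population_size)
      new_recs <- evaluate_population(ds, population[new_idx], plan, gbr_par,
                                      parallelism_degree, folds,
                                      index_offset = derive_seed(ga_conf$seed,
                                                                 13L, gen) %%
                                        1000000L)
      records[new_idx] <- new_recs
    }
    fitnesses <- vapply(records, `[[`, 0, "fitness")
    b <- which.min(fitnesses)
    hist_best[gen] <- fitnesses[b]
    finite <- is.finite(fitnesses)
    hist_avg[gen] <- if (any(finite)) mean(fitnesses[finite]) else Inf
    hist_worst[gen] <- if (all(finite)) max(fitnesses) else Inf
    best_per_gen[[gen]] <- population[[b]]
    if (is.null(overall_best) || fitnesses[b] < overall_best$fitness) {
      overall_best <- list(chromosome = population[[b]],
                           fitness = fitnesses[b], record = records[[b]])
    }
    if (gen < ga_conf$generations) {
      nx <- next_generation(population, fitnesses, ga_conf,
                            seed = derive_seed(ga_conf$seed, 3L, gen))
      population <- nx$population
      records <- c(records[nx$elite_indices],
                   vector("list", ga_conf$population_size -
                            ga_conf$elitism_count))
    }
  }

  list(best_chromosome = overall_best$chromosome,
       best_fitness = overall_best$fitness,
       best_record = overall_best$record,
       history = data.frame(generation = seq_len(ga_conf$generations),
                            best = hist_best, avg = hist_avg,
                            worst = hist_worst),
       best_per_generation = best_per_gen)
}

#' Run the GA independently on every age group
#'
#' Executes [run_ga()] once per group training set with group-specific seeds
#' derived from the master seed. Groups are independent and may be evaluated
#' concurrently; results are keyed by group label and identical to sequential
#' execution.
#'
#' @param grouped_train named list of filtered group training
#'   [methyl_dataset]s.
#' @param ga_conf a [ga_config] (its `chromosome_length` must match each
#'   group's site count; a per-group copy is adjusted automatically).
#' @param gbr_par a [gbr_params].
#' @param parallelism_degree worker processes inside each group's evaluation.
#' @param target_size,folds passed to [run_ga()].
#' @return named list of [run_ga()] results; a failing group yields an
#'   element of class `ga_group_error` carrying the message instead.
#' @export
run_all_groups <- function(grouped_train, ga_conf, gbr_par = gbr_params(),
                           parallelism_degree = 1L, target_size = 100L,
                           folds = 3L) {
  stopifnot(length(grouped_train) >= 1L)
  labels <- names(grouped_train) %||% as.character(seq_along(grouped_train))
  out <- lapply(seq_along(grouped_train), function(g) {
    conf <- ga_conf
    conf$chromosome_length <- n_sites(grouped_train[[g]])
    conf$seed <- derive_seed(ga_conf$seed, 17L, g)
    tryCatch(run_ga(grouped_train[[g]], conf, gbr_par, parallelism_degree,
                    target_size, folds),
             error = function(e) structure(list(group = labels[g],
                                                message = conditionMessage(e)),
                                           class = "ga_group_error"))
  })
  names(out) <- labels
  out
}
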