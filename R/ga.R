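# Simple genetic algorithm over the categorical search space: seeded
# population, AUC fitness, ranked survival with stochastic retention of
# losers, feature-wise breeding with occasional single-axis mutation.
#
# Purity contract: each individual's evaluation seed is derived from the
# master seed and the genome's serialized content, never from execution
# order, so serial and parallel schedules produce identical results and
# fitness can be cached by genome key.

#' Genetic algorithm configuration
#'
#' Defaults follow the search protocol: 10 generations of 100 individuals, a
#' generational retention rate of 40%, a negative rejection probability of
#' 10% (chance that an individual below the retention cut survives anyway),
#' and a mutation frequency of 20% per bred child.
#'
#' @param generations number of generations (>= 1).
#' @param population_size individuals per generation (>= 2).
#' @param retention_rate fraction of the ranked population retained (0, 1].
#' @param rejection_keep_prob probability of keeping a below-cut individual.
#' @param mutation_prob probability a bred child has one axis resampled.
#' @param master_seed seed from which all run randomness derives.
#' @param rejection_mode "keep_losers" (default: the stated probability
#'   retains sub-cut individuals) or "drop_elites" (alternative reading:
#'   the probability drops above-cut individuals).
#' @return a `ga_config` object.
#' @export
ga_config <- function(generations = 10L, population_size = 100L,
                      retention_rate = 0.40, rejection_keep_prob = 0.10,
                      mutation_prob = 0.20, master_seed = 1L,
                      rejection_mode = c("keep_losers", "drop_elites")) {
  rejection_mode <- match.arg(rejection_mode)
  stopifnot(generations >= 1, population_size >= 2,
            retention_rate > 0, retention_rate <= 1,
            rejection_keep_prob >= 0, rejection_keep_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(generations = as.integer(generations),
                 population_size = as.integer(population_size),
                 retention_rate = retention_rate,
                 rejection_keep_prob = rejection_keep_prob,
                 mutation_prob = mutation_prob,
                 master_seed = as.integer(master_seed),
                 rejection_mode = rejection_mode),
            class = "ga_config")
}

#' Evaluate one individual
#'
#' A pure function of (genome, fitness function, eval seed): the fitness
#' function is called under a seeded RNG scope. A fitness function may
#' return either a bare AUC number or a list with `auc` and optional
#' `accuracy`. Errors during evaluation are converted to fitness 0 with the
#' condition message recorded, so one pathological configuration cannot kill
#' a whole run.
#'
#' @param g a `genome`.
#' @param fitness_fn function(genome) -> AUC in [0, 1] (or list).
#' @param eval_seed integer seed for this evaluation.
#' @return an `individual`: list with `genome`, `key`, `fitness`,
#'   `accuracy`, `eval_seed`, `error` (NA when clean).
#' @export
evaluate_individual <- function(g, fitness_fn, eval_seed) {
  res <- tryCatch(
    with_seed(eval_seed, fitness_fn(g)),
    error = function(e) e)
  if (inherits(res, "error")) {
    fit <- 0; acc <- NA_real_; err <- conditionMessage(res)
  } else {
    if (is.list(res)) {
      fit <- res$auc
      acc <- res$accuracy %||% NA_real_
    } else {
      fit <- res
      acc <- NA_real_
    }
    err <- NA_character_
    stopifnot(is.numeric(fit), fit >= 0, fit <= 1)
  }
  structure(list(genome = g, key = genome_key(g), fitness = fit,
                 accuracy = acc, eval_seed = eval_seed, error = err),
            class = "individual")
}

# Deterministic ranking: fitness desc, then accuracy desc (NA last), then
# genome-key hash for full determinism.
rank_population <- function(population) {
  fit <- vapply(population, `[[`, numeric(1), "fitness")
  acc <- vapply(population, function(i) i$accuracy %||% NA_real_, numeric(1))
  acc[is.na(acc)] <- -Inf
  h <- vapply(population, function(i) fnv1a32(i$key), numeric(1))
  population[order(-fit, -acc, -h)]
}

#' Select survivors from a ranked generation
#'
#' The top `ceiling(retention_rate * N)` individuals by fitness survive;
#' each remaining individual is then independently retained with probability
#' `rejection_keep_prob` ("negative rejection"). Ties are broken by
#' accuracy, then genome hash, for determinism. The alternative
#' `drop_elites` reading instead drops each elite with that probability.
#'
#' @param population list of evaluated `individual`s.
#' @param retention_rate fraction retained.
#' @param rejection_keep_prob stochastic retention probability.
#' @param rejection_mode see [ga_config()].
#' @return list of surviving individuals, ranked.
#' @export
select_survivors <- function(population, retention_rate,
                             rejection_keep_prob,
                             rejection_mode = "keep_losers") {
  ranked <- rank_population(population)
  n_keep <- ceiling(retention_rate * length(ranked))
  elites <- ranked[seq_len(n_keep)]
  losers <- ranked[setdiff(seq_along(ranked), seq_len(n_keep))]
  if (rejection_mode == "keep_losers") {
    lucky <- losers[stats::runif(length(losers)) < rejection_keep_prob]
    c(elites, lucky)
  } else {
    kept <- elites[stats::runif(length(elites)) >= rejection_keep_prob]
    if (length(kept) == 0L) kept <- elites[1L]  # never lose everyone
    c(kept, losers[stats::runif(length(losers)) < rejection_keep_prob])
  }
}

#' Breed a child genome from two parents
#'
#' Each axis choice is copied from the mother or the father with equal
#' probability; then, with probability `mutation_prob`, exactly one
#' uniformly chosen axis is reassigned a uniform random variant drawn from
#' the full axis (the "population pool").
#'
#' @param mother,father parent `genome`s from `space`.
#' @param space the `search_space`.
#' @param mutation_prob per-child mutation probability.
#' @return a `genome`.
#' @export
breed <- function(mother, father, space, mutation_prob) {
  axes <- names(space$axes)
  from_mother <- stats::runif(length(axes)) < 0.5
  choices <- stats::setNames(vector("list", length(axes)), axes)
  for (i in seq_along(axes)) {
    choices[[i]] <- if (from_mother[i]) mother$choices[[axes[i]]]
                    else father$choices[[axes[i]]]
  }
  if (stats::runif(1) < mutation_prob) {
    ax <- axes[sample.int(length(axes), 1L)]
    labs <- names(space$axes[[ax]]$variants)
    choices[[ax]] <- labs[sample.int(length(labs), 1L)]
  }
  genome(space, choices)
}

#' Run the genetic algorithm
#'
#' Generation 0 is sampled uniformly from the space; each later generation
#' consists of the survivors plus bred children until the population size is
#' reached. Fitness is cached by genome key, so duplicate genomes cost one
#' evaluation, and each genome's evaluation seed is derived from the master
#' seed plus the genome content (order-independent purity).
#'
#' @param space a `search_space`.
#' @param config a [ga_config()].
#' @param fitness_fn function(genome) -> AUC (or list with auc/accuracy).
#' @param verbose print per-generation progress.
#' @return a `ga_history`: list of generation records (each with
#'   `generation`, `individuals` ranked, `best_fitness`, `mean_fitness`)
#'   plus attributes `evaluations` (total fitness calls) and `config`.
#' @export
evolve <- function(space, config, fitness_fn, verbose = FALSE) {
  stopifnot(inherits(space, "search_space"), inherits(config, "ga_config"))
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  eval_cached <- function(g) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ind <- evaluate_individual(
      g, fitness_fn, derive_seed(config$master_seed, key))
    n_evals <<- n_evals + 1L
    cache[[key]] <- ind
    ind
  }
  history <- vector("list", config$generations)
  with_seed(derive_seed(config$master_seed, "ga-driver"), {
    population <- replicate(config$population_size,
                            random_genome(space), simplify = FALSE)
    for (gen in seq_len(config$generations)) {
      evaluated <- lapply(population, eval_cached)
      evaluated <- rank_population(evaluated)
      fits <- vapply(evaluated, `[[`, numeric(1), "fitness")
      history[[gen]] <- list(generation = gen, individuals = evaluated,
                             best_fitness = max(fits),
                             mean_fitness = mean(fits))
      if (verbose)
        message(sprintf("generation %d: best %.4f mean %.4f (evals %d)",
                        gen, max(fits), mean(fits), n_evals))
      if (gen == config$generations) break
      survivors <- select_survivors(evaluated, config$retention_rate,
                                    config$rejection_keep_prob,
                                    config$rejection_mode)
      n_children <- config$population_size - length(survivors)
      children <- vector("list", max(n_children, 0L))
      for (i in seq_len(max(n_children, 0L))) {
        if (length(survivors) >= 2L) {
          pick <- sample.int(length(survivors), 2L)  # no self-pairing
        } else {
          pick <- c(1L, 1L)
        }
        children[[i]] <- breed(survivors[[pick[1]]]$genome,
                               survivors[[pick[2]]]$genome,
                               space, config$mutation_prob)
      }
      population <- c(lapply(survivors, `[[`, "genome"), children)
      population <- population[seq_len(config$population_size)]
    }
  })
  structure(history, class = "ga_history",
            evaluations = n_evals, config = config)
}

#' Best-fitness trajectory of a run
#' @param history a `ga_history`.
#' @return numeric vector of per-generation best fitness.
#' @export
best_fitness_trace <- function(history) {
  vapply(history, `[[`, numeric(1), "best_fitness")
}

#' Top-k distinct genomes of the final generation
#'
#' @param history a `ga_history`.
#' @param k how many to return (>= 1).
#' @return list of up to k `individual`s, ranked by (fitness, accuracy,
#'   hash) descending, distinct by genome; warns when fewer than k distinct
#'   genomes exist.
#' @export
top_k <- function(history, k = 5L) {
  stopifnot(k >= 1)
  final <- history[[length(history)]]$individuals
  ranked <- rank_population(final)
  keys <- vapply(ranked, `[[`, character(1), "key")
  distinct <- ranked[!duplicated(keys)]
  if (length(distinct) < k) {
    warning("only ", length(distinct), " distinct genomes in the final ",
            "generation; returning all")
    k <- length(distinct)
  }
  distinct[seq_len(k)]
}

#' Fraction of the search space explored by a run
#'
#' Evaluations divided by space cardinality. For the phase-1 space and a
#' full 10 x 100 run this bookkeeping gives 0.005% (1000 / 19,051,200,
#' rounded to three decimals as a percentage).
#'
#' @param history a `ga_history` (or a number of evaluations).
#' @param space the searched `search_space`.
#' @param as_percent return a percentage instead of a fraction.
#' @return explored fraction (or percentage).
#' @export
explored_fraction <- function(history, space, as_percent = FALSE) {
  n <- if (inherits(history, "ga_history"))
    attr(history, "evaluations") else as.numeric(history)
  frac <- n / cardinality(space)
  if (as_percent) frac * 100 else frac
}

#' Flatten a GA history into a generation log
#'
#' One row per individual per generation: generation, rank, every axis
#' choice as its own column, fitness (AUC), accuracy, eval_seed.
#'
#' @param history a `ga_history`.
#' @return data.frame suitable for writing as the run's CSV log.
#' @export
ga_log <- function(history) {
  rows <- list()
  for (rec in history) {
    for (r in seq_along(rec$individuals)) {
      ind <- rec$individuals[[r]]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(generation = rec$generation, rank = r,
                   stringsAsFactors = FALSE),
        as.data.frame(ind$genome$choices, stringsAsFactors = FALSE),
        data.frame(fitness = ind$fitness,
                   accuracy = ind$accuracy %||% NA_real_,
                   eval_seed = ind$eval_seed, stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, rows)
}
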