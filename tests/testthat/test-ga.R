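# Genetic-algorithm mechanics: selection, breeding, evolution, purity,
# caching, explored-fraction bookkeeping.

test_that("survivor selection keeps the right counts deterministically", {
  sp <- toy_space()
  set.seed(40)
  pop <- lapply(1:100, function(i)
    evaluate_individual(random_genome(sp), function(g) runif(1), i))
  set.seed(41)
  surv0 <- select_survivors(pop, 0.4, 0)
  expect_length(surv0, 40L)
  fits <- vapply(pop, `[[`, numeric(1), "fitness")
  expect_setequal(vapply(surv0, `[[`, numeric(1), "fitness"),
                  sort(fits, decreasing = TRUE)[1:40])
  expect_length(select_survivors(pop, 1.0, 0), 100L)
  # binomial bounds on stochastic loser retention (60 losers, p = 0.1)
  set.seed(42)
  kept <- replicate(2000, length(select_survivors(pop, 0.4, 0.1)) - 40L)
  expect_lt(abs(mean(kept) - 6), 3 * sqrt(60 * 0.1 * 0.9 / 2000))
})

test_that("breeding respects parental genes and mutation bounds", {
  sp <- toy_space()
  set.seed(43)
  mother <- random_genome(sp)
  father <- random_genome(sp)
  # identical parents, no mutation -> identical child
  child <- breed(mother, mother, sp, 0)
  expect_identical(genome_key(child), genome_key(mother))
  # closure: without mutation every gene comes from a parent
  for (i in 1:50) {
    ch <- breed(mother, father, sp, 0)
    for (ax in names(sp$axes))
      expect_true(ch$choices[[ax]] %in%
                    c(mother$choices[[ax]], father$choices[[ax]]))
  }
  # forced mutation on a 1-axis space is uniform over variants
  one <- search_space(list(feature_axis("a", list(x = 1, y = 2))))
  g <- genome(one, list(a = "x"))
  set.seed(44)
  draws <- replicate(4000, breed(g, g, one, 1.0)$choices$a)
  p <- mean(draws == "y")
  # mutation resamples uniformly from both variants
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("evolution is elitist, bounded in evaluations, and reproducible", {
  sp <- toy_space()
  fn <- hidden_optimum_fitness(sp, seed = 7)
  cfg <- ga_config(generations = 8, population_size = 20, master_seed = 11)
  h1 <- evolve(sp, cfg, fn)
  h2 <- evolve(sp, cfg, fn)
  # bit-reproducible
  expect_identical(ga_log(h1), ga_log(h2))
  # best fitness non-decreasing
  expect_true(all(diff(best_fitness_trace(h1)) >= 0))
  # evaluation budget
  expect_lte(attr(h1, "evaluations"), 8 * 20)
  expect_equal(length(h1), 8L)
  for (rec in h1) expect_length(rec$individuals, 20L)
})

test_that("evaluation is a pure function of genome and seed (parallel-safe)", {
  sp <- toy_space()
  fn <- function(g) {
    # a stochastic fitness: depends on the scoped RNG stream
    runif(1) * 0.1 + mean(unlist(g$choices) == "v1") * 0.9
  }
  set.seed(45)
  genomes <- replicate(30, random_genome(sp), simplify = FALSE)
  master <- 99L
  eval_all <- function(gs) {
    lapply(gs, function(g)
      evaluate_individual(g, fn, derive_seed_for(master, g)))
  }
  derive_seed_for <- function(master, g)
    gaclassify:::derive_seed(master, genome_key(g))
  serial <- eval_all(genomes)
  shuffled_order <- sample(length(genomes))
  parallel_sim <- eval_all(genomes[shuffled_order])
  # identical fitness multiset, and identical per-genome fitness
  f1 <- vapply(serial, `[[`, numeric(1), "fitness")
  f2 <- vapply(parallel_sim, `[[`, numeric(1), "fitness")
  expect_equal(sort(f1), sort(f2))
  expect_equal(f1[shuffled_order], f2)
  # same genome twice -> identical fitness
  again <- eval_all(genomes[1])
  expect_identical(again[[1]]$fitness, serial[[1]]$fitness)
})

test_that("failed evaluations record fitness 0 instead of killing the run", {
  sp <- toy_space(2, 2)
  fn <- function(g) {
    if (g$choices$a1 == "v1") stop("training diverged")
    0.7
  }
  bad <- evaluate_individual(genome(sp, list(a1 = "v1", a2 = "v1")), fn, 1L)
  expect_identical(bad$fitness, 0)
  expect_match(bad$error, "diverged")
  good <- evaluate_individual(genome(sp, list(a1 = "v2", a2 = "v1")), fn, 1L)
  expect_identical(good$fitness, 0.7)
  expect_true(is.na(good$error))
})

test_that("schema contracts: no new variants without mutation or rejection", {
  sp <- toy_space(4, 3)
  fn <- hidden_optimum_fitness(sp, seed = 3)
  cfg <- ga_config(generations = 6, population_size = 16,
                   rejection_keep_prob = 0, mutation_prob = 0,
                   master_seed = 5)
  h <- evolve(sp, cfg, fn)
  pool_of <- function(rec) {
    lapply(names(sp$axes), function(ax)
      unique(vapply(rec$individuals,
                    function(i) i$genome$choices[[ax]], character(1))))
  }
  for (g in 2:length(h)) {
    prev <- pool_of(h[[g - 1]])
    curr <- pool_of(h[[g]])
    for (ax in seq_along(prev))
      expect_true(all(curr[[ax]] %in% prev[[ax]]))
  }
})

test_that("top_k returns ranked distinct genomes", {
  sp <- toy_space()
  fn <- hidden_optimum_fitness(sp, seed = 13)
  h <- evolve(sp, ga_config(generations = 5, population_size = 30,
                            master_seed = 17), fn)
  top5 <- top_k(h, 5)
  expect_length(top5, 5L)
  keys <- vapply(top5, `[[`, character(1), "key")
  expect_false(anyDuplicated(keys) > 0)
  fits <- vapply(top5, `[[`, numeric(1), "fitness")
  expect_true(all(diff(fits) <= 0))
  expect_identical(top_k(h, 1)[[1]]$key, top5[[1]]$key)
  expect_warning(top_k(h, 1000), "distinct")
})

test_that("explored-fraction bookkeeping matches the printed percentage", {
  sp <- build_phase1_space()
  # 10 generations x 100 individuals = 1000 evaluations
  expect_equal(round(explored_fraction(1000, sp, as_percent = TRUE), 3),
               0.005)
})
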