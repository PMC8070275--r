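separable_dataset <- function(n_per_class = 6, seed = 21) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 4, mean = 0), ncol = 4),
             matrix(rnorm(n_per_class * 4, mean = 8), ncol = 4))
  list(features = X,
       labels = data.frame(condition = rep(c("neg", "pos"),
                                           each = n_per_class),
                           volume_ml = 0L))
}

test_that("fitness is the LOOCV triple and rejects invalid genomes", {
  ds <- separable_dataset()
  task <- label_task("pos")
  f <- fitness(detector_genome(1, rep(TRUE, 4)), ds, task)
  expect_equal(unname(f), c(100, 100, 100))
  expect_error(detector_genome(1, rep(FALSE, 4)), "at least one")
  # memoisation returns the stored triple without recomputation
  cache <- new.env()
  g <- detector_genome(3, rep(TRUE, 4))
  f1 <- fitness(g, ds, task, cache)
  cache_val <- cache[[pleurasound:::genome_key(g)]]
  expect_identical(f1, cache_val)
  expect_identical(fitness(g, ds, task, cache), f1)
})

test_that("ga_config validates its bounds", {
  expect_error(ga_config(tournament_size = 50, population_size = 10),
               "tournament_size")
  expect_error(ga_config(elitism_count = 10, population_size = 10),
               "elitism_count")
  expect_error(ga_config(crossover_prob = 1.5), "crossover_prob")
})

test_that("a population of identical genomes with no variation stays constant", {
  ds <- separable_dataset()
  g <- detector_genome(3, c(TRUE, TRUE, FALSE, TRUE))
  res <- evolve(ds, label_task("pos"),
                ga_config(population_size = 6, n_generations = 5,
                          crossover_prob = 0, mutation_prob_per_gene = 0,
                          stopping_patience = 99, seed = 3),
                initial_population = list(g))
  h <- res$history
  for (col in grep("best_|mean_", names(h), value = TRUE))
    expect_equal(h[[col]], rep(h[[col]][1], nrow(h)), info = col)
  expect_equal(res$best_genome$feature_mask, g$feature_mask)
})

test_that("archive best accuracy is non-decreasing (elitism)", {
  ds <- random_dataset(20, 6, c("neg", "pos"), 31)
  res <- evolve(ds, label_task("pos"),
                ga_config(population_size = 10, n_generations = 8,
                          stopping_patience = 99, seed = 9))
  expect_true(all(diff(res$history$best_accuracy) >= 0))
  expect_true(all(diff(res$history$best_sensitivity) >= 0))
})

test_that("evolution is reproducible and its archive is mutually non-dominated", {
  ds <- random_dataset(18, 5, c("neg", "pos"), 41)
  ga <- ga_config(population_size = 8, n_generations = 6, seed = 17)
  r1 <- evolve(ds, label_task("pos"), ga)
  r2 <- evolve(ds, label_task("pos"), ga)
  expect_equal(r1$history, r2$history)
  expect_equal(r1$best_genome, r2$best_genome)
  expect_equal(r1$pareto_fitness, r2$pareto_fitness)
  F <- r1$pareto_fitness
  for (i in seq_len(nrow(F)))
    for (j in seq_len(nrow(F)))
      if (i != j)
        expect_false(all(F[j, ] >= F[i, ]) && any(F[j, ] > F[i, ]))
  # best genome attains the archive's maximal accuracy
  expect_equal(unname(r1$best_fitness["accuracy"]), max(F[, "accuracy"]))
})

test_that("evolution solves a separable problem to 100/100/100", {
  ds <- separable_dataset(8, seed = 55)
  res <- evolve(ds, label_task("pos"),
                ga_config(population_size = 10, n_generations = 6, seed = 2))
  expect_equal(unname(res$best_fitness), c(100, 100, 100))
})

test_that("early stopping triggers once the Pareto front stabilises", {
  ds <- separable_dataset(6, seed = 77)
  res <- evolve(ds, label_task("pos"),
                ga_config(population_size = 8, n_generations = 50,
                          stopping_patience = 3, seed = 4))
  expect_lt(nrow(res$history), 50)
})
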