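test_that("roulette selection frequencies are proportional to weights", {
  set.seed(1)
  draws <- roulette_select(c(3, 1), n = 10000)
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  flat <- roulette_select(rep(2, 4), n = 10000)
  freq <- tabulate(flat, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))

  expect_identical(roulette_select(5, n = 2), c(1L, 1L))
  expect_error(roulette_select(c(1, NA)), "evaluated")
})

test_that("two-point crossover swaps exactly the cut segment", {
  set.seed(2)
  for (i in 1:50) {
    p1 <- rep(0L, 6)
    p2 <- rep(1L, 6)
    off <- two_point_crossover(p1, p2)
    cuts <- attr(off, "cuts")
    seg <- if (cuts[2] > cuts[1]) (cuts[1] + 1):cuts[2] else integer(0)
    expect_equal(which(off[[1]] == 1L), seg)
    expect_equal(which(off[[2]] == 0L), seg)
    # full swap at the (0, n) boundary
    if (identical(cuts, c(0L, 6L))) {
      expect_equal(off[[1]], p2)
      expect_equal(off[[2]], p1)
    }
  }
  same <- two_point_crossover(c(1L, 0L, 1L), c(1L, 0L, 1L))
  expect_equal(same[[1]], c(1L, 0L, 1L))
  expect_equal(same[[2]], c(1L, 0L, 1L))
  expect_error(two_point_crossover(c(1, 0), c(1, 0, 1)), "equal gene length")
})

test_that("uniform mutation flips at the configured rate", {
  g <- rep(0L, 104)
  expect_identical(uniform_mutation(g, 0), g)
  expect_identical(uniform_mutation(g, 1), rep(1L, 104))
  set.seed(3)
  flips <- replicate(10000, sum(uniform_mutation(g, 0.02)))
  expected <- 104 * 0.02
  se <- sqrt(104 * 0.02 * 0.98 / 10000)
  expect_lt(abs(mean(flips) - expected), 3 * se)
  expect_error(uniform_mutation(g, 1.5), "rate")
})

test_that("GA matches the exhaustive-search optimum on a small instance", {
  d <- toy_classes(n_per_class = 20, k = 3, informative = 2, noise = 3,
                   sep = 1.2, seed = 4)
  spec <- svm_spec("linear")
  oracle <- exhaustive_mask_search(d$x, d$y, spec, k = 5, cv_seed = 17)
  run <- run_ga(d$x, d$y, spec,
                ga_config(n_genes = 5, pop_size = 12, mutation_rate = 0.05,
                          max_iterations = 12, seed = 17), k = 5)
  expect_equal(run$best_fitness, oracle$best_fitness)
})

test_that("GA history is structurally sound and reproducible", {
  d <- toy_classes(n_per_class = 12, k = 2, informative = 1, noise = 2,
                   sep = 2, seed = 5)
  spec <- svm_spec("linear")
  one <- run_ga(d$x, d$y, spec,
                ga_config(n_genes = 3, pop_size = 2, max_iterations = 1,
                          seed = 1), k = 3)
  expect_length(one$history, 1)

  cfg <- ga_config(n_genes = 3, pop_size = 8, mutation_rate = 0.1,
                   max_iterations = 10, seed = 2)
  a <- run_ga(d$x, d$y, spec, cfg, k = 3)
  b <- run_ga(d$x, d$y, spec, cfg, k = 3)
  expect_true(all(diff(a$history) <= 0))  # elitism: monotone non-increasing
  expect_identical(a$best_mask, b$best_mask)
  expect_identical(a$history, b$history)
  expect_equal(a$best_fitness, min(a$history))
  expect_named(coef(a), colnames(d$x))
})

test_that("the published GA operating configuration is accepted and echoed", {
  cfg <- ga_config(n_genes = 104, pop_size = 100, mutation_rate = 0.02,
                   max_iterations = 100, seed = 1)
  expect_equal(cfg$n_genes, 104)
  expect_equal(cfg$selection, "roulette")
  expect_equal(cfg$crossover, "two-point")
  expect_equal(cfg$mutation, "uniform")
  expect_error(ga_config(n_genes = 10, pop_size = 1), "pop_size")
  expect_error(ga_config(n_genes = 10, mutation_rate = 2), "mutation_rate")
})

test_that("mismatched gene length and target-error early stop are handled", {
  d <- toy_classes(n_per_class = 12, k = 2, informative = 1, noise = 2,
                   sep = 6, seed = 6)
  spec <- svm_spec("linear")
  expect_error(run_ga(d$x, d$y, spec, ga_config(n_genes = 7, pop_size = 4,
                                                max_iterations = 2)),
               "n_genes")
  run <- run_ga(d$x, d$y, spec,
                ga_config(n_genes = 3, pop_size = 8, max_iterations = 50,
                          target_error = 0, seed = 3), k = 3)
  expect_lt(length(run$history), 50)  # separable: stops at the target
  expect_equal(run$best_fitness, 0)
})
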