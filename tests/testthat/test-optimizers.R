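test_that("initial populations respect bounds and are reproducible", {
  b <- model_gene_bounds()

  # degenerate bounds collapse to the single admissible point
  deg <- gene_bounds(lower = rep(0.4, 3), upper = rep(0.4, 3))
  expect_equal(init_population(5, deg, seed = 1),
               matrix(0.4, 5, 3))

  p1 <- init_population(20, b, seed = 123)
  p2 <- init_population(20, b, seed = 123)
  expect_identical(p1, p2)

  big <- init_population(10000, b, seed = 5)
  expect_true(all(big[, 1:7] >= 0 & big[, 1:7] <= 1))
  expect_true(all(big[, 8:14] %in% 0:5))
  # uniform moments: coefficient mean ~ 0.5, exponents ~ uniform on 6 levels
  expect_equal(mean(big[, 1:7]), 0.5, tolerance = 0.01)
  freq <- table(factor(big[, 8:14], levels = 0:5)) / (10000 * 7)
  expect_true(all(abs(freq - 1 / 6) < 0.01))
})

test_that("rank selection prefers better ranks linearly", {
  set.seed(21)
  # two eligible individuals with fitnesses (1, 2): linear rank weights 2:1
  picks <- rank_select(c(1, 2), pressure = 1, n_pairs = 6000)
  frac_best <- mean(picks == 1)
  expect_equal(frac_best, 2 / 3, tolerance = 0.02)

  # pressure covering a single individual: only the best is ever selected
  f <- c(5, 1, 3, 4, 2)
  picks <- rank_select(f, pressure = 1 / 5, n_pairs = 50)
  expect_true(all(picks == 2))

  # equal fitnesses: uniform within sampling error, ties kept in order
  picks <- rank_select(rep(1, 4), pressure = 1, n_pairs = 8000)
  freq <- table(factor(picks, levels = 1:4)) / length(picks)
  # linear rank weights 4:3:2:1 applied to insertion order
  expect_equal(as.numeric(freq), c(4, 3, 2, 1) / 10, tolerance = 0.02)

  expect_error(rank_select(numeric(0), 0.5, 1), "empty")
  expect_error(rank_select(c(1, 2), 0, 1), "pressure")
})

test_that("single-point crossover splices genomes index by index", {
  p1 <- c(1:7 / 10, 0:5, 3)
  p2 <- rev(p1)
  expect_equal(crossover_single_point(p1, p1, 5), list(p1, p1))

  # point 7 swaps the whole exponent block
  ch <- crossover_single_point(p1, p2, 7)
  expect_equal(ch[[1]], c(p1[1:7], p2[8:14]))
  expect_equal(ch[[2]], c(p2[1:7], p1[8:14]))

  ch <- crossover_single_point(p1, p2, 3)
  expect_equal(ch[[1]], c(p1[1:3], p2[4:14]))
  expect_equal(ch[[2]], c(p2[1:3], p1[4:14]))

  expect_error(crossover_single_point(p1, p2, 14), "point")
  expect_error(crossover_single_point(p1, p2, 0), "point")
})

test_that("mutation changes one gene with the configured probability", {
  b <- gene_bounds(lower = rep(0, 5), upper = rep(1, 5))
  g <- rep(0.5, 5)
  set.seed(31)
  expect_identical(mutate_genome(g, b, 0), g)

  m1 <- replicate(200, sum(mutate_genome(g, b, 1) != g))
  expect_true(all(m1 == 1))               # prob 1: exactly one gene differs

  changed <- replicate(10000, any(mutate_genome(g, b, 0.3) != g))
  expect_equal(mean(changed), 0.3, tolerance = 0.02)

  # mutated values stay within bounds
  bb <- model_gene_bounds()
  for (i in 1:50) {
    gm <- mutate_genome(init_population(1, bb)[1, ], bb, 1)
    expect_true(all(gm >= bb$lower & gm <= bb$upper))
    expect_true(all(gm[8:14] %in% 0:5))
  }
})

test_that("Levy steps follow the Mantegna construction with heavy tails", {
  # sigma_u oracle computed directly from the Gamma-function formula
  beta <- 1.5
  sigma_oracle <- (gamma(1 + beta) * sin(pi * beta / 2) /
                     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  expect_equal(levy_sigma(1.5), sigma_oracle, tolerance = 1e-12)
  expect_error(levy_sigma(1), "between")
  expect_error(levy_step(3, beta = 2.5), "between")

  set.seed(8)
  s1 <- levy_step(10)
  set.seed(8)
  expect_identical(levy_step(10), s1)

  set.seed(9)
  s <- levy_step(1e5)
  expect_gt(max(abs(s)) / median(abs(s)), 100)      # heavy tail
  g <- rnorm(1e5)
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  expect_gt(kurt(s), 10 * kurt(g))
})

test_that("optimizers honor the evaluation budget exactly and stay in bounds", {
  b <- gene_bounds(lower = rep(0, 4), upper = c(1, 1, 5, 5),
                   step = c(NA, NA, 1, 1))
  seen <- list()
  sphere <- function(g) { seen[[length(seen) + 1L]] <<- g; sum((g - 0.3)^2) }

  for (budget in c(730, 1201)) {
    seen <- list()
    counted <- counted_objective(sphere)
    res <- ga_optimize(counted$fn, b, ga_config(population_size = 50,
                                                eval_budget = budget), seed = 2)
    expect_identical(counted$calls(), res$evaluations_used)
    expect_identical(res$evaluations_used, as.integer(budget))
    G <- do.call(rbind, seen)
    expect_true(all(G >= rep(b$lower, each = nrow(G)) &
                      G <= rep(b$upper, each = nrow(G))))
    expect_true(all(G[, 3:4] %in% 0:5))

    seen <- list()
    counted <- counted_objective(sphere)
    res <- csa_optimize(counted$fn, b, csa_config(nests = 50,
                                                  eval_budget = budget), seed = 2)
    expect_identical(counted$calls(), res$evaluations_used)
    expect_identical(res$evaluations_used, as.integer(budget))
    G <- do.call(rbind, seen)
    expect_true(all(G >= rep(b$lower, each = nrow(G)) &
                      G <= rep(b$upper, each = nrow(G))))
    expect_true(all(G[, 3:4] %in% 0:5))
  }
})

test_that("convergence traces are non-increasing", {
  inst <- grid_instance()
  ga <- ga_optimize(inst$objective, inst$bounds,
                    ga_config(population_size = 40, eval_budget = 2000), seed = 4)
  cs <- csa_optimize(inst$objective, inst$bounds,
                     csa_config(nests = 40, eval_budget = 2000), seed = 4)
  expect_true(all(diff(ga$trace[, "best_fitness"]) <= 0))
  expect_true(all(diff(cs$trace[, "best_fitness"]) <= 0))
  expect_true(all(diff(ga$trace[, "evaluations"]) > 0))
})

test_that("identical inputs give bit-identical fit results", {
  rec <- cohort_channel(generate_cohort(cohort_config(n = 20, seed = 2)), "kinect")
  cfg <- ga_config(population_size = 30, eval_budget = 600)
  expect_identical(ga_fit(rec, cfg, seed = 99), ga_fit(rec, cfg, seed = 99))
  ccfg <- csa_config(nests = 30, eval_budget = 600)
  expect_identical(csa_fit(rec, ccfg, seed = 99), csa_fit(rec, ccfg, seed = 99))
})

test_that("a budget below one generation returns the best of the evaluated init", {
  rec <- cohort_channel(generate_cohort(cohort_config(n = 15, seed = 4)), "true")
  expect_warning(cfg <- ga_config(population_size = 50, eval_budget = 30),
                 "budget")
  fit <- ga_fit(rec, cfg, seed = 12)
  expect_identical(fit$evaluations_used, 30L)
  expect_equal(nrow(fit$trace), 1L)
})

test_that("the genome maps bijectively onto the model", {
  rec <- cohort_channel(generate_cohort(cohort_config(n = 10, seed = 6)), "true")
  nm <- cohort_norm_context(rec)
  g <- init_population(1, model_gene_bounds(), seed = 3)[1, ]
  m <- bwestim:::genome_to_model(g, nm)
  expect_equal(unname(m$coefficients), g[1:7])
  expect_equal(unname(as.numeric(m$exponents)), g[8:14])
  # model fitness and the optimizer objective agree
  obj <- bwestim:::cohort_objective(rec, nm)
  expect_equal(obj(g), fitness(m, rec), tolerance = 1e-12)
})
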