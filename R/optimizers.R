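# Metaheuristic fitting of the 14-gene polynomial encoding.
#
# Both optimizers act on a generic objective over a bounded genome: genes
# 1-7 are coefficients (continuous in [0,1]), genes 8-14 integer exponents
# in {0,...,5}.  Bounds carry an optional grid step, which both generalizes
# the integer exponents and allows fully discretized search spaces that an
# exhaustive enumeration can certify.

#' Per-gene search bounds
#'
#' @param lower,upper Numeric vectors of per-gene limits.
#' @param step Optional per-gene grid step (NA = continuous).  A stepped
#'   gene only takes values `lower + k * step` within the limits; integer
#'   exponents are the special case `step = 1`.
#' @return A data frame of class `gene_bounds`.
#' @export
gene_bounds <- function(lower, upper, step = NA_real_) {
  n <- length(lower)
  step <- rep_len(step, n)
  if (length(upper) != n || any(upper < lower))
    stop("inconsistent bounds", call. = FALSE)
  if (any(!is.na(step) & step <= 0))
    stop("grid steps must be positive", call. = FALSE)
  structure(data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
                       step = as.numeric(step)),
            class = c("gene_bounds", "data.frame"))
}

#' Default 14-gene bounds of the weight-model encoding
#'
#' Coefficients a1-a7 continuous in \[0, 1\]; exponents a8-a14 integer in
#' \{0, ..., 5\}.
#'
#' @return A [gene_bounds()] with 14 rows.
#' @export
model_gene_bounds <- function() {
  gene_bounds(lower = rep(0, 14), upper = c(rep(1, 7), rep(5, 7)),
              step = c(rep(NA_real_, 7), rep(1, 7)))
}

# Round half away from zero onto a gene's grid, then clip to the limits.
snap_genome <- function(genome, bounds) {
  g <- pmin(pmax(genome, bounds$lower), bounds$upper)
  on_grid <- !is.na(bounds$step)
  if (any(on_grid)) {
    k <- (g[on_grid] - bounds$lower[on_grid]) / bounds$step[on_grid]
    k <- trunc(abs(k) + 0.5) * sign(k)
    g[on_grid] <- bounds$lower[on_grid] + k * bounds$step[on_grid]
    g[on_grid] <- pmin(pmax(g[on_grid], bounds$lower[on_grid]),
                       bounds$upper[on_grid])
  }
  g
}

# One uniform draw per gene: continuous genes uniform on [lo, hi], stepped
# genes uniform over their admissible levels.
random_genes <- function(n, bounds) {
  m <- matrix(NA_real_, n, nrow(bounds))
  for (j in seq_len(nrow(bounds))) {
    lo <- bounds$lower[j]; hi <- bounds$upper[j]; st <- bounds$step[j]
    if (is.na(st)) {
      m[, j] <- stats::runif(n, lo, hi)
    } else {
      nlev <- floor((hi - lo) / st + 1e-9) + 1L
      m[, j] <- lo + st * (floor(stats::runif(n) * nlev))
    }
  }
  m
}

#' Random initial population
#'
#' Coefficient genes are drawn uniformly on their interval, stepped genes
#' uniformly over their grid levels.  Reproducible under a fixed seed.
#'
#' @param n Number of genomes (>= 1).
#' @param bounds A [gene_bounds()].
#' @param seed Optional integer seed.
#' @return `n` x `n_genes` numeric matrix, one genome per row.
#' @export
init_population <- function(n, bounds, seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  random_genes(n, bounds)
}

#' Linear rank selection of parent pairs
#'
#' Only the best `ceiling(pressure * N)` individuals (the "biological
#' pressure" fraction) are eligible to reproduce.  Within the eligible pool
#' the selection weight is linear in rank, `w = N_el - rank + 1`, so the
#' best-ranked individual is most likely to be drawn; ties in fitness are
#' broken by insertion order.  Parents are drawn with replacement.
#'
#' @param fitnesses Numeric vector of fitness values (lower is better).
#' @param pressure Fraction in (0, 1] of the population eligible to
#'   reproduce.
#' @param n_pairs Number of parent pairs to draw.
#' @return Integer matrix `n_pairs` x 2 of population indices.
#' @export
rank_select <- function(fitnesses, pressure, n_pairs) {
  n <- length(fitnesses)
  if (n == 0L) stop("empty population", call. = FALSE)
  if (pressure <= 0 || pressure > 1)
    stop("`pressure` must lie in (0, 1]", call. = FALSE)
  ord <- order(fitnesses)                     # stable: ties by insertion order
  n_el <- max(1L, ceiling(pressure * n))
  eligible <- ord[seq_len(n_el)]
  w <- n_el - seq_len(n_el) + 1
  idx <- eligible[sample.int(n_el, 2L * n_pairs, replace = TRUE, prob = w)]
  matrix(idx, ncol = 2L)
}

#' Single-point crossover
#'
#' Splices two parent genomes at `point`: the first child takes genes
#' `1..point` from the first parent and the rest from the second; the second
#' child is the mirror.  Because genes are exchanged verbatim, children
#' respect the bounds automatically.
#'
#' @param parent1,parent2 Numeric genomes of equal length `L`.
#' @param point Crossover point in `1..(L-1)`.
#' @return List of two child genomes.
#' @export
crossover_single_point <- function(parent1, parent2, point) {
  L <- length(parent1)
  if (point < 1L || point >= L)
    stop("`point` must lie in 1..", L - 1L, call. = FALSE)
  i <- seq_len(point)
  c1 <- parent1; c1[-i] <- parent2[-i]
  c2 <- parent2; c2[-i] <- parent1[-i]
  list(c1, c2)
}

#' Mutate a genome
#'
#' With probability `prob` (per individual), one uniformly chosen gene is
#' resampled uniformly within its bounds (over its grid levels for a stepped
#' gene); otherwise the genome is returned unchanged.
#'
#' @param genome Numeric genome.
#' @param bounds A [gene_bounds()].
#' @param prob Mutation probability in \[0, 1\].
#' @return The (possibly) mutated genome.
#' @export
mutate_genome <- function(genome, bounds, prob) {
  if (prob < 0 || prob > 1) stop("`prob` must lie in [0, 1]", call. = FALSE)
  if (stats::runif(1) < prob) {
    j <- sample.int(length(genome), 1L)
    genome[j] <- random_genes(1L, bounds[j, , drop = FALSE])[1L]
  }
  genome
}

#' Mantegna sigma for a Levy-stable step
#'
#' @param beta Stability index in (1, 2).
#' @return The scale of the Gaussian numerator in Mantegna's construction.
#' @export
levy_sigma <- function(beta) {
  if (beta <= 1 || beta >= 2)
    stop("`beta` must lie strictly between 1 and 2", call. = FALSE)
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Heavy-tailed Levy-flight step (Mantegna construction)
#'
#' Per dimension, `step = u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and `sigma_u` from [levy_sigma()].  The resulting steps mix
#' many short moves with rare long jumps, the search pattern cuckoo search
#' exploits.
#'
#' @param dimension Number of components.
#' @param beta Stability index in (1, 2); 1.5 is the conventional default.
#' @return Numeric vector of `dimension` steps.
#' @export
levy_step <- function(dimension, beta = 1.5) {
  sigma <- levy_sigma(beta)
  u <- stats::rnorm(dimension, 0, sigma)
  v <- stats::rnorm(dimension)
  u / abs(v)^(1 / beta)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study protocol: 200 individuals, a 40,000
#' fitness-evaluation budget, 85% biological pressure (fraction of the
#' ranked population eligible to reproduce), 10% elitism and 30%
#' per-individual mutation probability.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param eval_budget Maximum fitness evaluations.
#' @param biological_pressure Eligible-to-reproduce fraction in (0, 1].
#' @param elitism Fraction of best individuals copied unchanged, in (0, 1].
#' @param mutation_prob Per-individual mutation probability.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, eval_budget = 40000L,
                      biological_pressure = 0.85, elitism = 0.10,
                      mutation_prob = 0.30) {
  stopifnot(population_size >= 2L,
            biological_pressure > 0, biological_pressure <= 1,
            elitism > 0, elitism <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  if (eval_budget < population_size)
    warning("evaluation budget below one generation; ",
            "only part of the initial population will be evaluated")
  structure(list(population_size = as.integer(population_size),
                 eval_budget = as.integer(eval_budget),
                 biological_pressure = biological_pressure,
                 elitism = elitism, mutation_prob = mutation_prob),
            class = "ga_config")
}

#' Cuckoo-search configuration
#'
#' Defaults follow the study protocol (200 nests, 40,000-evaluation budget,
#' abandonment probability Pa = 0.25) with the conventional Levy-flight
#' settings beta = 1.5 and a step scale of 1% of each gene's range.
#'
#' @param nests Number of host nests (>= 2).
#' @param eval_budget Maximum fitness evaluations.
#' @param pa Probability a foreign egg is discovered, i.e. the fraction of
#'   worst nests abandoned per iteration, in (0, 1).
#' @param levy_beta Levy stability index in (1, 2).
#' @param step_scale Step size as a fraction of each gene's range.
#' @return List of class `csa_config`.
#' @export
csa_config <- function(nests = 200L, eval_budget = 40000L, pa = 0.25,
                       levy_beta = 1.5, step_scale = 0.01) {
  stopifnot(nests >= 2L, pa > 0, pa < 1, levy_beta > 1, levy_beta < 2,
            step_scale > 0)
  if (eval_budget < nests)
    warning("evaluation budget below one nest sweep; ",
            "only part of the initial nests will be evaluated")
  structure(list(nests = as.integer(nests), eval_budget = as.integer(eval_budget),
                 pa = pa, levy_beta = levy_beta, step_scale = step_scale),
            class = "csa_config")
}

# Shared bookkeeping: evaluate genomes one by one against the remaining
# budget; returns fitnesses (NA where the budget ran out first).
eval_rows <- function(objective, genomes, remaining) {
  n <- min(nrow(genomes), remaining)
  f <- rep(NA_real_, nrow(genomes))
  for (i in seq_len(n)) f[i] <- objective(genomes[i, ])
  f
}

new_fit_result <- function(best_genome, best_fitness, trace, evals, seed) {
  structure(list(best_genome = best_genome, best_fitness = best_fitness,
                 trace = trace, evaluations_used = evals, seed = seed),
            class = "bw_fit")
}

#' @export
print.bw_fit <- function(x, ...) {
  cat(sprintf("metaheuristic fit: best fitness %.6g after %d evaluations (seed %d)\n",
              x$best_fitness, x$evaluations_used, x$seed))
  invisible(x)
}

#' Minimize an objective with a genetic algorithm with elitism
#'
#' Generational loop: linear rank selection under biological pressure,
#' single-point crossover, per-individual mutation, and unconditional
#' survival of the elite fraction (whose cached fitness is never
#' re-evaluated).  The evaluation budget is spent exactly: the final
#' offspring batch is truncated to the remaining evaluations, so two
#' optimizers given the same budget consume identical evaluation counts.
#'
#' @param objective Function of a genome returning a scalar to minimize.
#' @param bounds A [gene_bounds()].
#' @param config A [ga_config()].
#' @param seed Integer seed; the whole run draws from one seeded generator.
#' @return A `bw_fit`: best genome and fitness, convergence `trace`
#'   (matrix of evaluations consumed vs best fitness so far),
#'   `evaluations_used`, `seed`.
#' @export
ga_optimize <- function(objective, bounds, config = ga_config(), seed = 1L) {
  set.seed(seed)
  np <- config$population_size
  budget <- config$eval_budget
  n_elite <- max(1L, ceiling(config$elitism * np))

  pop <- random_genes(np, bounds)
  fit <- eval_rows(objective, pop, budget)
  evals <- sum(!is.na(fit))
  keep <- !is.na(fit)
  pop <- pop[keep, , drop = FALSE]; fit <- fit[keep]

  b <- which.min(fit)
  best_genome <- pop[b, ]; best_fitness <- fit[b]
  trace <- list(c(evals, best_fitness))

  repeat {
    n_off <- min(nrow(pop) - n_elite, budget - evals)
    if (n_off <= 0L) break
    pairs <- rank_select(fit, config$biological_pressure, ceiling(n_off / 2))
    kids <- matrix(NA_real_, 2L * nrow(pairs), ncol(pop))
    for (p in seq_len(nrow(pairs))) {
      pt <- sample.int(ncol(pop) - 1L, 1L)
      ch <- crossover_single_point(pop[pairs[p, 1L], ], pop[pairs[p, 2L], ], pt)
      kids[2L * p - 1L, ] <- ch[[1L]]
      kids[2L * p, ] <- ch[[2L]]
    }
    kids <- kids[seq_len(n_off), , drop = FALSE]
    for (k in seq_len(nrow(kids)))
      kids[k, ] <- mutate_genome(kids[k, ], bounds, config$mutation_prob)
    kfit <- vapply(seq_len(nrow(kids)), function(k) objective(kids[k, ]),
                   numeric(1))
    evals <- evals + nrow(kids)

    elite_idx <- order(fit)[seq_len(n_elite)]
    pop <- rbind(pop[elite_idx, , drop = FALSE], kids)
    fit <- c(fit[elite_idx], kfit)

    b <- which.min(fit)
    if (fit[b] < best_fitness) {            # incumbent retained on ties
      best_fitness <- fit[b]; best_genome <- pop[b, ]
    }
    trace[[length(trace) + 1L]] <- c(evals, best_fitness)
  }

  trace <- do.call(rbind, trace)
  colnames(trace) <- c("evaluations", "best_fitness")
  new_fit_result(best_genome, best_fitness, trace, evals, as.integer(seed))
}

#' Minimize an objective with cuckoo search and Levy flights
#'
#' Per iteration a new cuckoo is proposed from a uniformly chosen nest by a
#' scaled Levy step ([levy_step()]), snapped to the gene grid and clipped to
#' the bounds; it replaces a uniformly chosen nest if strictly fitter.  Then
#' the worst `ceiling(pa * nests)` nests are abandoned and rebuilt by Levy
#' steps from surviving nests.  The best nest is tracked across iterations
#' and every fitness call is counted; the final abandonment batch is
#' truncated so the budget is spent exactly.
#'
#' @inheritParams ga_optimize
#' @param config A [csa_config()].
#' @return A `bw_fit` (see [ga_optimize()]).
#' @export
csa_optimize <- function(objective, bounds, config = csa_config(), seed = 1L) {
  set.seed(seed)
  np <- config$nests
  budget <- config$eval_budget
  rng_range <- bounds$upper - bounds$lower

  nests <- random_genes(np, bounds)
  fit <- eval_rows(objective, nests, budget)
  evals <- sum(!is.na(fit))
  keep <- !is.na(fit)
  nests <- nests[keep, , drop = FALSE]; fit <- fit[keep]

  b <- which.min(fit)
  best_genome <- nests[b, ]; best_fitness <- fit[b]
  trace <- list(c(evals, best_fitness))
  n_aband_full <- min(np - 1L, ceiling(config$pa * np))

  while (evals < budget && nrow(nests) >= 2L) {
    # one cuckoo by Levy flight, compared against a random nest j
    i <- sample.int(nrow(nests), 1L)
    cuckoo <- snap_genome(
      nests[i, ] + config$step_scale * rng_range *
        levy_step(ncol(nests), config$levy_beta),
      bounds)
    fc <- objective(cuckoo); evals <- evals + 1L
    j <- sample.int(nrow(nests), 1L)
    if (fc < fit[j]) {                      # fitter-wins; incumbent keeps ties
      nests[j, ] <- cuckoo; fit[j] <- fc
    }
    if (fc < best_fitness) { best_fitness <- fc; best_genome <- cuckoo }

    # abandon the worst nests, rebuild from survivors by Levy steps
    n_aband <- min(n_aband_full, budget - evals)
    if (n_aband > 0L) {
      worst <- order(fit, decreasing = TRUE)[seq_len(n_aband)]
      survivors <- setdiff(seq_len(nrow(nests)), worst)
      for (w in worst) {
        base <- nests[survivors[sample.int(length(survivors), 1L)], ]
        fresh <- snap_genome(
          base + config$step_scale * rng_range *
            levy_step(ncol(nests), config$levy_beta),
          bounds)
        ff <- objective(fresh); evals <- evals + 1L
        nests[w, ] <- fresh; fit[w] <- ff
        if (ff < best_fitness) { best_fitness <- ff; best_genome <- fresh }
      }
    }
    trace[[length(trace) + 1L]] <- c(evals, best_fitness)
  }

  trace <- do.call(rbind, trace)
  colnames(trace) <- c("evaluations", "best_fitness")
  new_fit_result(best_genome, best_fitness, trace, evals, as.integer(seed))
}

# Genome <-> model mapping and the cohort objective shared by ga_fit/csa_fit
genome_to_model <- function(genome, norm) {
  polynomial_model(genome[1:7], genome[8:14], norm)
}

cohort_objective <- function(records, norm) {
  records <- validate_records(records, require_bw = TRUE)
  Xn <- normalized_matrix(records, norm)
  yn <- records$bw / norm$bw_scale
  n <- nrow(Xn)
  function(genome) {
    E <- matrix(genome[8:14], n, 7L, byrow = TRUE)
    sqrt(mean((as.vector((Xn ^ E) %*% genome[1:7]) - yn)^2))
  }
}

fit_cohort <- function(records, config, seed, norm, optimize_fn) {
  records <- validate_records(records, require_bw = TRUE)
  if (is.null(norm)) norm <- cohort_norm_context(records)
  counted <- counted_objective(cohort_objective(records, norm))
  res <- optimize_fn(counted$fn, model_gene_bounds(), config, seed)
  stopifnot(counted$calls() == res$evaluations_used)
  res$best_model <- genome_to_model(res$best_genome, norm)
  res
}

#' Fit the polynomial weight model with the genetic algorithm
#'
#' @param records Data frame of biometric records carrying observed `bw`.
#' @param config A [ga_config()].
#' @param seed Integer seed (whole-run reproducibility).
#' @param norm Optional [norm_context()]; defaults to the cohort's
#'   max-per-variable context ([cohort_norm_context()]).
#' @return A `bw_fit` whose `best_model` is a [polynomial_model()];
#'   `best_fitness` is the normalized RMSE the optimizer minimized.
#' @export
ga_fit <- function(records, config = ga_config(), seed = 1L, norm = NULL) {
  fit_cohort(records, config, seed, norm, ga_optimize)
}

#' Fit the polynomial weight model with cuckoo search
#'
#' @inheritParams ga_fit
#' @param config A [csa_config()].
#' @return A `bw_fit` (see [ga_fit()]).
#' @export
csa_fit <- function(records, config = csa_config(), seed = 1L, norm = NULL) {
  fit_cohort(records, config, seed, norm, csa_optimize)
}
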