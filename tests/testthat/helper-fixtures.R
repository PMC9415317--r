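# Small fixtures shared across test files; everything is built in code.

# n records with unit-scale measurements, optionally with observed weight
toy_records <- function(n = 3, values = NULL, bw = NULL) {
  if (is.null(values)) values <- matrix(1, n, 7)
  df <- as.data.frame(values)
  names(df) <- bw_variables
  df <- cbind(animal_id = as.character(seq_len(n)), channel = "true", df)
  if (!is.null(bw)) df$bw <- bw
  df
}

unit_norm <- function() norm_context(stats::setNames(rep(1, 7), bw_variables), 1)

# a hand-set cohort wrapped as a bw_cohort (for pearson_matrix tests)
manual_cohort <- function(true_vals, kinect_vals, bw) {
  n <- nrow(true_vals)
  mk <- function(M, channel) {
    df <- as.data.frame(M); names(df) <- bw_variables
    cbind(animal_id = sprintf("A%02d", seq_len(n)), channel = channel, df,
          bw = bw)
  }
  structure(list(records = rbind(mk(true_vals, "true"),
                                 mk(kinect_vals, "kinect")),
                 outlier_ids = character(0)),
            class = "bw_cohort")
}

# noise-free recovery cohort: weights generated exactly by a known model
recovery_cohort <- function(n = 56, seed = 7) {
  generate_cohort(cohort_config(n = n, seed = seed, residual_cv = 0,
                                sensor_cv = 0, rescale_bw = FALSE))
}

# discretized 2-variable instance whose optimum brute force can certify:
# genes (c1, c2, e1, e2), coefficients on an 11-point grid, exponents 0..2
grid_instance <- function(seed = 42, n = 8, noise = 0.03) {
  set.seed(seed)
  x1 <- runif(n, 0.3, 1); x2 <- runif(n, 0.3, 1)
  truth <- c(0.6, 0.3, 2, 1)
  y <- truth[1] * x1^truth[3] + truth[2] * x2^truth[4] + noise * rnorm(n)
  objective <- function(g) sqrt(mean((g[1] * x1^g[3] + g[2] * x2^g[4] - y)^2))
  grid <- expand.grid(c1 = seq(0, 1, 0.1), c2 = seq(0, 1, 0.1),
                      e1 = 0:2, e2 = 0:2)
  list(objective = objective,
       bounds = gene_bounds(lower = rep(0, 4), upper = c(1, 1, 2, 2),
                            step = c(0.1, 0.1, 1, 1)),
       brute_optimum = min(apply(grid, 1, objective)))
}
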