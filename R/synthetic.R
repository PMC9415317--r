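# Synthetic cohorts with the statistical structure the analysis assumes:
# correlated allometric biometrics driven by a latent size factor, a known
# ground-truth weight law from the model family itself, a multiplicative
# sensor-noise channel, and rare gross outliers.

#' Default ground-truth weight law of the synthetic generator
#'
#' An arbitrary but fixed member of the polynomial family (documented as
#' synthetic, not a fitted or published model) used so that recovery
#' experiments are well-posed: the generated weights are actually produced
#' by a model the optimizers can represent.
#'
#' @param norm A [norm_context()].
#' @return A [polynomial_model()].
#' @export
default_truth_model <- function(norm) {
  polynomial_model(c(0.20, 0.15, 0.10, 0.05, 0.30, 0.08, 0.12),
                   c(2, 1, 3, 1, 2, 2, 1), norm)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study population: 56 ewes with body weight
#' 30.31 +/- 7.83 kg, sensor measurements correlating ~0.90 with the true
#' values, and rare gross outliers (~2 animals in 56 with one variable off
#' by 50%).  Baseline sizes and allometric exponents are plausible
#' implementer-chosen values for ~30 kg hair sheep, not published data.
#'
#' @param n Number of animals (>= 1).
#' @param bw_mean,bw_sd Target body-weight mean and SD, kg.
#' @param baselines Named per-variable baseline sizes, cm, at latent size 1.
#' @param gammas Named per-variable allometric exponents: a variable scales
#'   as `size^gamma`, so girth-type measures (larger gamma) respond more to
#'   size than skeletal lengths.
#' @param size_sd SD of the latent size factor (mean 1).
#' @param individual_cv Per-variable idiosyncratic CV around the allometric
#'   law.
#' @param sensor_cv Multiplicative sensor-noise CV of the kinect channel;
#'   the default 0.043 is calibrated (closed form) so the average
#'   true-vs-sensor Pearson correlation is about 0.90.
#' @param outlier_prob Per-animal probability of one gross sensor error.
#' @param outlier_magnitude Relative size of a gross error, in (0, 1].
#' @param residual_cv CV of weight noise around the ground-truth law.
#' @param rescale_bw If TRUE (default) the noise-free weights are affinely
#'   matched to `(bw_mean, bw_sd)` before residual noise; if FALSE they are
#'   only scaled (never shifted) to hit `bw_mean`, which keeps the observed
#'   weights exactly representable by the stored ground-truth model — use
#'   this for parameter-recovery experiments.
#' @param ground_truth Optional function `(norm) -> bw_model` overriding
#'   [default_truth_model()].
#' @param seed Integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 56L,
                          bw_mean = 30.31, bw_sd = 7.83,
                          baselines = c(hwk = 62, rhk = 64, blk = 60,
                                        bdlk = 68, btlk = 95, gsck = 38,
                                        asck = 42),
                          gammas = c(hwk = 0.9, rhk = 0.9, blk = 1.0,
                                     bdlk = 1.0, btlk = 1.1, gsck = 1.2,
                                     asck = 1.3),
                          size_sd = 0.08, individual_cv = 0.03,
                          sensor_cv = 0.043,
                          outlier_prob = 2 / 56, outlier_magnitude = 0.5,
                          residual_cv = 0.05,
                          rescale_bw = TRUE,
                          ground_truth = default_truth_model,
                          seed = 1L) {
  stopifnot(n >= 1L, bw_mean > 0, bw_sd > 0,
            all(baselines > 0), size_sd >= 0, individual_cv >= 0,
            sensor_cv >= 0, outlier_prob >= 0, outlier_prob <= 1,
            outlier_magnitude > 0, outlier_magnitude <= 1,
            residual_cv >= 0)
  baselines <- baselines[bw_variables]; gammas <- gammas[bw_variables]
  if (anyNA(baselines) || anyNA(gammas))
    stop("`baselines` and `gammas` must name all seven variables",
         call. = FALSE)
  structure(list(n = as.integer(n), bw_mean = bw_mean, bw_sd = bw_sd,
                 baselines = baselines, gammas = gammas, size_sd = size_sd,
                 individual_cv = individual_cv, sensor_cv = sensor_cv,
                 outlier_prob = outlier_prob,
                 outlier_magnitude = outlier_magnitude,
                 residual_cv = residual_cv, rescale_bw = rescale_bw,
                 ground_truth = ground_truth, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Each animal has a latent size `s ~ N(1, size_sd)`; true variable j is
#' `baseline_j * s^gamma_j * (1 + eps)` with idiosyncratic noise
#' `eps ~ N(0, individual_cv^2)`.  The true weight comes from the
#' ground-truth polynomial on the normalized variables, affinely matched to
#' the target `(bw_mean, bw_sd)` (see `rescale_bw`), plus residual noise.
#' The kinect channel multiplies every true value by `(1 + delta)`,
#' `delta ~ N(0, sensor_cv^2)`.  All values are clipped strictly positive.
#'
#' @param config A [cohort_config()].
#' @return List of class `bw_cohort`: `records` (both channels, aligned by
#'   `animal_id`), `ground_truth_model`, `outlier_ids` (empty until
#'   [inject_outliers()]), the rescale coefficients `alpha`/`beta`
#'   (observed noise-free weight = alpha * model output + beta) and the
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n
  eps <- 1e-6

  s <- pmax(stats::rnorm(n, 1, config$size_sd), 0.2)
  X <- sapply(bw_variables, function(v) {
    pmax(config$baselines[[v]] * s^config$gammas[[v]] *
           (1 + stats::rnorm(n, 0, config$individual_cv)), eps)
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, bw_variables))

  scales <- apply(X, 2L, max)
  norm0 <- norm_context(scales, bw_scale = 1)
  truth0 <- config$ground_truth(norm0)
  f <- predict(truth0, as.data.frame(X), type = "normalized")

  if (config$rescale_bw) {
    if (stats::sd(f) == 0)
      stop("ground-truth outputs have zero variance; cannot rescale",
           call. = FALSE)
    alpha <- config$bw_sd / stats::sd(f)
    beta <- config$bw_mean - alpha * mean(f)
    base <- alpha * f + beta
    bw_scale <- max(base)
  } else {
    if (mean(f) == 0) stop("degenerate ground-truth outputs", call. = FALSE)
    alpha <- config$bw_mean / mean(f)
    beta <- 0
    base <- alpha * f
    bw_scale <- alpha      # bw / bw_scale == model output: truth has fitness 0
  }
  bw <- pmax(base * (1 + stats::rnorm(n, 0, config$residual_cv)), eps)

  K <- pmax(X * (1 + matrix(stats::rnorm(n * 7L, 0, config$sensor_cv), n, 7L)),
            eps)

  ids <- sprintf("A%04d", seq_len(n))
  mk <- function(M, channel) {
    df <- data.frame(animal_id = ids, channel = channel,
                     as.data.frame(M), bw = bw,
                     stringsAsFactors = FALSE)
    names(df) <- c("animal_id", "channel", bw_variables, "bw")
    df
  }
  records <- rbind(mk(X, "true"), mk(K, "kinect"))

  norm <- norm_context(scales, bw_scale)
  truth <- polynomial_model(truth0$coefficients, truth0$exponents, norm)

  structure(list(records = records, ground_truth_model = truth,
                 outlier_ids = character(0), alpha = alpha, beta = beta,
                 config = config),
            class = "bw_cohort")
}

#' @export
print.bw_cohort <- function(x, ...) {
  tr <- cohort_channel(x, "true")
  cat(sprintf("synthetic cohort: %d animals, BW %.2f +/- %.2f kg (%d outliers)\n",
              nrow(tr), mean(tr$bw), stats::sd(tr$bw), length(x$outlier_ids)))
  invisible(x)
}

#' Extract one measurement channel of a cohort
#'
#' @param cohort A `bw_cohort`.
#' @param channel `"true"` or `"kinect"`.
#' @return Data frame of records, ordered by `animal_id`.
#' @export
cohort_channel <- function(cohort, channel = c("true", "kinect")) {
  channel <- match.arg(channel)
  df <- cohort$records[cohort$records$channel == channel, , drop = FALSE]
  df[order(df$animal_id), , drop = FALSE]
}

#' Inject gross sensor outliers into the kinect channel
#'
#' Each animal's kinect record, with probability `prob`, gets one uniformly
#' chosen variable multiplied by `(1 +/- magnitude)` (sign at random),
#' emulating gross measurement errors such as ~50% errors caused by animal
#' movement.  Affected animals are recorded in `outlier_ids`.
#'
#' @param cohort A `bw_cohort`.
#' @param prob Per-animal outlier probability (default from the cohort's
#'   config).
#' @param magnitude Relative error magnitude in (0, 1\].
#' @param seed Optional integer seed.
#' @return The modified cohort.
#' @export
inject_outliers <- function(cohort, prob = cohort$config$outlier_prob,
                            magnitude = cohort$config$outlier_magnitude,
                            seed = NULL) {
  stopifnot(prob >= 0, prob <= 1, magnitude > 0, magnitude <= 1)
  if (!is.null(seed)) set.seed(seed)
  ki <- which(cohort$records$channel == "kinect")
  ids <- cohort$records$animal_id[ki]
  hit <- stats::runif(length(ki)) < prob
  for (r in which(hit)) {
    v <- bw_variables[sample.int(7L, 1L)]
    sgn <- if (stats::runif(1) < 0.5) -1 else 1
    cohort$records[ki[r], v] <- cohort$records[ki[r], v] * (1 + sgn * magnitude)
  }
  cohort$outlier_ids <- sort(union(cohort$outlier_ids, ids[hit]))
  cohort
}

#' Pearson correlation matrix of a cohort
#'
#' Correlations over the seven true-channel variables, the seven
#' kinect-channel variables and the observed body weight (15 columns).
#'
#' @param cohort A `bw_cohort`.
#' @return Symmetric 15 x 15 correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(cohort) {
  tr <- cohort_channel(cohort, "true")
  ki <- cohort_channel(cohort, "kinect")
  stopifnot(identical(tr$animal_id, ki$animal_id))
  if (nrow(tr) < 3L)
    stop("need at least 3 animals for correlations", call. = FALSE)
  M <- cbind(as.matrix(tr[bw_variables]), as.matrix(ki[bw_variables]),
             bw = tr$bw)
  colnames(M) <- c(toupper(bw_variables), paste0(toupper(bw_variables), ".k"),
                   "BW")
  if (any(apply(M, 2L, stats::sd) == 0))
    stop("zero-variance column: correlation undefined", call. = FALSE)
  stats::cor(M)
}

#' Average true-vs-sensor correlation of the seven variables
#'
#' The summary used to characterize sensor fidelity: the Pearson
#' correlation between true and kinect values of each biometric variable,
#' averaged over the seven variables.
#'
#' @param cohort A `bw_cohort`.
#' @return List with `per_variable` (named length-7 vector) and `average`.
#' @export
sensor_agreement <- function(cohort) {
  tr <- cohort_channel(cohort, "true")
  ki <- cohort_channel(cohort, "kinect")
  stopifnot(identical(tr$animal_id, ki$animal_id))
  r <- vapply(bw_variables, function(v) stats::cor(tr[[v]], ki[[v]]),
              numeric(1))
  list(per_variable = r, average = mean(r))
}
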