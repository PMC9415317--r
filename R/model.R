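#' bwestim: body-weight estimation from biometric measurements
#'
#' Fits an adjustable-degree multivariate polynomial that maps seven
#' depth-sensor biometric measurements of an animal to its body weight.
#' Both the coefficient and the integer exponent of every term are free
#' parameters, estimated by a genetic algorithm with elitism or by cuckoo
#' search with Levy flights under a shared fitness-evaluation budget.
#' The package also ships the depth-image measurement chain used to obtain
#' the biometric variables, a synthetic-cohort generator for end-to-end
#' testing, and classical girth-and-length baseline formulas.
#'
#' @keywords internal
#' @aliases bwestim-package
"_PACKAGE"

#' The seven biometric variables, in model term order
#'
#' Height at withers (HWK), rump height (RHK), body length (BLK), diagonal
#' body length (BDLK), total body length (BTLK), girth semi-circumference
#' (GSCK) and abdomen semi-circumference (ASCK), all in cm.  The K suffix
#' marks depth-sensor provenance.
#'
#' @export
bw_variables <- c("hwk", "rhk", "blk", "bdlk", "btlk", "gsck", "asck")

#' Normalization context for a weight model
#'
#' The polynomial acts on dimensionless inputs: each biometric variable is
#' divided by a per-cohort reference scale (by default the cohort maximum of
#' that variable) and the observed weight by `bw_scale`.  Raw centimetre
#' inputs raised to powers up to 5 with coefficients bounded by 1 could not
#' produce kilogram-scale outputs, so the scales are an integral part of a
#' fitted model and travel with it.
#'
#' @param scales Named positive numeric vector, one entry per variable in
#'   [bw_variables] (cm).
#' @param bw_scale Positive scalar; reference weight (kg).
#' @return An object of class `norm_context`.
#' @export
norm_context <- function(scales, bw_scale) {
  scales <- unlist(scales)
  if (is.null(names(scales))) names(scales) <- bw_variables
  if (!setequal(names(scales), bw_variables) || length(scales) != 7L)
    stop("`scales` must carry exactly the seven biometric variables", call. = FALSE)
  scales <- scales[bw_variables]
  if (!all(is.finite(scales)) || any(scales <= 0))
    stop("all scales must be strictly positive and finite", call. = FALSE)
  if (!is.numeric(bw_scale) || length(bw_scale) != 1L || !is.finite(bw_scale) ||
      bw_scale <= 0)
    stop("`bw_scale` must be a strictly positive scalar", call. = FALSE)
  structure(list(scales = scales, bw_scale = as.numeric(bw_scale)),
            class = "norm_context")
}

#' Build a normalization context from a cohort
#'
#' Uses the per-variable maximum (and the maximum observed weight) as the
#' reference scales, so every normalized training value lies in (0, 1].
#'
#' @param records Data frame of biometric records (see [read_cohort()]).
#' @return A [norm_context()].
#' @export
cohort_norm_context <- function(records) {
  records <- validate_records(records, require_bw = TRUE)
  norm_context(vapply(records[bw_variables], max, numeric(1)),
               max(records$bw))
}

#' Adjustable-degree polynomial weight model
#'
#' The model is
#' \deqn{\widehat{BW} = \sum_{i=1}^{7} a_i \, (x_i / s_i)^{e_i},}
#' a sum of one power term per biometric variable, where both the
#' coefficient \eqn{a_i \in [0, 1]} and the integer exponent
#' \eqn{e_i \in \{0, \dots, 5\}} are free parameters and \eqn{s_i} are the
#' reference scales of `norm`.  The output is on the normalized weight scale
#' and is multiplied by `norm$bw_scale` to give kilograms.  The convention
#' \eqn{0^0 = 1} makes an exponent-0 term a pure constant equal to its
#' coefficient.
#'
#' @param coefficients Numeric vector of 7 coefficients in \[0, 1\].
#' @param exponents Integer vector of 7 exponents in \{0, ..., 5\}.
#' @param norm A [norm_context()].
#' @return An object of class `bw_model`.
#' @seealso [predict.bw_model()], [fitness()], [ga_fit()], [csa_fit()]
#' @export
polynomial_model <- function(coefficients, exponents, norm) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 7L || anyNA(coefficients) ||
      any(coefficients < 0 | coefficients > 1))
    stop("`coefficients` must be 7 values in [0, 1]", call. = FALSE)
  exponents <- as.numeric(exponents)
  if (length(exponents) != 7L || anyNA(exponents) ||
      any(exponents != round(exponents)) || any(exponents < 0 | exponents > 5))
    stop("`exponents` must be 7 integers in {0, ..., 5}", call. = FALSE)
  if (!inherits(norm, "norm_context"))
    stop("`norm` must be a norm_context", call. = FALSE)
  structure(list(coefficients = stats::setNames(coefficients, bw_variables),
                 exponents = stats::setNames(as.integer(exponents), bw_variables),
                 norm = norm),
            class = "bw_model")
}

#' @export
print.bw_model <- function(x, ...) {
  cat("Adjustable-degree polynomial weight model\n")
  for (i in seq_along(bw_variables)) {
    cat(sprintf("  %+.4g * (%s/%.4g)^%d\n", x$coefficients[i],
                toupper(bw_variables[i]), x$norm$scales[i], x$exponents[i]))
  }
  cat(sprintf("  weight scale: %.4g kg\n", x$norm$bw_scale))
  invisible(x)
}

# Normalized design matrix (n x 7) from validated records
normalized_matrix <- function(records, norm) {
  X <- as.matrix(records[bw_variables])
  sweep(X, 2L, norm$scales, "/")
}

#' Validate a table of biometric records
#'
#' Checks that all seven measurements are present, finite and strictly
#' positive, and (optionally) that observed body weight is present and
#' strictly positive.  Column names are matched case-insensitively.
#'
#' @param records Data frame.
#' @param require_bw Must an observed `bw` column be present?
#' @return The records with lower-case canonical column names.
#' @export
validate_records <- function(records, require_bw = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame", call. = FALSE)
  names(records) <- tolower(names(records))
  missing <- setdiff(bw_variables, names(records))
  if (length(missing))
    stop("missing biometric variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (v in bw_variables) {
    x <- records[[v]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0))
      stop("variable `", v, "` must be strictly positive and finite",
           call. = FALSE)
  }
  if (require_bw) {
    if (is.null(records$bw) || anyNA(records$bw) || any(records$bw <= 0))
      stop("observed body weight `bw` must be present and strictly positive",
           call. = FALSE)
  }
  records
}

#' Predict body weight for biometric records
#'
#' @param object A [polynomial_model()].
#' @param newdata Data frame with the seven biometric variables in cm
#'   (columns matched case-insensitively).
#' @param type `"kg"` for de-normalized weight in kilograms, `"normalized"`
#'   for the dimensionless model output.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.bw_model <- function(object, newdata, type = c("kg", "normalized"), ...) {
  type <- match.arg(type)
  newdata <- validate_records(newdata)
  Xn <- normalized_matrix(newdata, object$norm)
  E <- matrix(object$exponents, nrow(Xn), 7L, byrow = TRUE)
  pred <- as.vector((Xn ^ E) %*% object$coefficients)
  if (type == "kg") pred * object$norm$bw_scale else pred
}

#' Root-mean-squared error
#'
#' \eqn{\sqrt{\frac{1}{n}\sum_i (\hat y_i - y_i)^2}}, in the units of its
#' inputs.  This is the quantity the optimizers minimize (on the normalized
#' weight scale).
#'
#' @param predicted,observed Equal-length non-empty numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed))
    stop("`predicted` and `observed` must be non-empty and of equal length",
         call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Error metrics for weight predictions
#'
#' Percentage metrics are scale-free: RMSE and MBE are normalized by the mean
#' observed weight, MAPE by the per-animal observed weight, and R-squared is
#' the ordinary coefficient of determination \eqn{1 - SS_{res}/SS_{tot}}
#' (unclipped: it can be negative for models worse than the mean, and NA
#' with a warning when the observations have zero variance).
#'
#' @inheritParams rmse
#' @return A one-row data frame of class `bw_metrics` with columns
#'   `rmse_raw` (input units), `rmse_pct`, `r2_pct`, `mbe_pct`, `mape_pct`
#'   and `n`.
#' @export
weight_metrics <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed))
    stop("`predicted` and `observed` must be non-empty and of equal length",
         call. = FALSE)
  if (any(observed == 0))
    stop("MAPE is undefined for zero observed values", call. = FALSE)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0)
    warning("R-squared is undefined for zero-variance observations; ",
            "reporting NA", call. = FALSE)
  err <- predicted - observed
  out <- data.frame(
    rmse_raw = sqrt(mean(err^2)),
    rmse_pct = 100 * sqrt(mean(err^2)) / mean(observed),
    r2_pct   = if (sstot == 0) NA_real_ else 100 * (1 - sum(err^2) / sstot),
    mbe_pct  = 100 * mean(err) / mean(observed),
    mape_pct = 100 * mean(abs(err) / observed),
    n        = length(observed)
  )
  class(out) <- c("bw_metrics", class(out))
  out
}

#' Fitness of a model on a cohort
#'
#' The single objective both optimizers minimize: the RMSE between the
#' model's normalized predictions and the normalized observed weights
#' (dimensionless).  See [counted_objective()] to audit how many times an
#' optimizer evaluates it.
#'
#' @param model A [polynomial_model()].
#' @param records Data frame of records carrying observed `bw`.
#' @return Non-negative scalar.
#' @export
fitness <- function(model, records) {
  records <- validate_records(records, require_bw = TRUE)
  rmse(predict(model, records, type = "normalized"),
       records$bw / model$norm$bw_scale)
}

#' Wrap an objective with a fitness-call counter
#'
#' Every optimizer run in this package counts fitness evaluations against a
#' budget; this wrapper exposes the same audit to the user, e.g. to verify
#' that a matched-budget comparison gave both algorithms exactly equal
#' evaluation counts.
#'
#' @param objective Function taking a genome (numeric vector) and returning
#'   a scalar fitness.
#' @return List with `fn` (counting objective) and `calls()` (evaluations
#'   so far).
#' @export
counted_objective <- function(objective) {
  count <- 0L
  list(
    fn = function(genome) {
      count <<- count + 1L
      objective(genome)
    },
    calls = function() count
  )
}
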