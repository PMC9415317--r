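#' Schaeffer's girth-and-length weight formula
#'
#' \eqn{W = L G^2 / 300} with the body length `L` (point of shoulder to pin
#' bone) and chest girth `G` both in inches, per the source convention.  No
#' unit conversion is applied.
#'
#' @param length_in Body length, inches (> 0).
#' @param girth_in Chest girth, inches (> 0).
#' @return Weight in the source convention's unit.
#' @export
schaeffer_weight <- function(length_in, girth_in) {
  if (any(length_in <= 0) || any(girth_in <= 0))
    stop("length and girth must be strictly positive", call. = FALSE)
  length_in * girth_in^2 / 300
}

#' Agarwal's girth-and-length weight formula
#'
#' \eqn{W = (G \times L) / Y} with a girth-dependent divisor: Y = 9.0 for
#' girth below 65 inches, 8.5 for girth between 65 and 80 inches, and 8.0
#' above 80 inches.  Inputs in inches per the source convention.
#'
#' @param girth_in Chest girth, inches (> 0).
#' @param length_in Body length, inches (> 0).
#' @return Weight in the source convention's unit.
#' @export
agarwal_weight <- function(girth_in, length_in) {
  if (any(girth_in <= 0) || any(length_in <= 0))
    stop("girth and length must be strictly positive", call. = FALSE)
  y <- ifelse(girth_in < 65, 9.0, ifelse(girth_in <= 80, 8.5, 8.0))
  girth_in * length_in / y
}

#' Classical growth curves for body weight over age
#'
#' Closed forms for the logistic \eqn{Y = A (1 + e^{-Kt})^{-M}}, Gompertz
#' \eqn{Y = A \exp(-B e^{-Kt})} and von Bertalanffy
#' \eqn{Y = A (1 - B e^{-Kt})^3} models, where `A` is the asymptotic weight,
#' `B` the integration-constant scale, `K` the maturation rate and `M` the
#' logistic shape parameter, with `t` in months.
#'
#' @param kind One of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`.
#' @param t Age in months (>= 0).
#' @param A Asymptotic weight (> 0).
#' @param B Scale parameter (Gompertz / von Bertalanffy).
#' @param K Growth rate (> 0).
#' @param M Shape parameter (logistic).
#' @return Weight at age `t`.
#' @export
growth_curve <- function(kind, t, A, B = NULL, K, M = NULL) {
  kind <- as.character(kind)
  if (length(kind) != 1L ||
      !kind %in% c("logistic", "gompertz", "von_bertalanffy"))
    stop("unknown growth-curve kind: ", kind, call. = FALSE)
  if (any(A <= 0) || any(K <= 0) || any(t < 0))
    stop("require A > 0, K > 0 and t >= 0", call. = FALSE)
  switch(kind,
    logistic = {
      if (is.null(M)) stop("logistic curve needs `M`", call. = FALSE)
      A * (1 + exp(-K * t))^(-M)
    },
    gompertz = {
      if (is.null(B)) stop("Gompertz curve needs `B`", call. = FALSE)
      A * exp(-B * exp(-K * t))
    },
    von_bertalanffy = {
      if (is.null(B)) stop("von Bertalanffy curve needs `B`", call. = FALSE)
      A * (1 - B * exp(-K * t))^3
    }
  )
}
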