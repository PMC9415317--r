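# Cohort CSV and model JSON interchange.
# Cohort CSV header: animal_id,channel,HWK,RHK,BLK,BDLK,BTLK,GSCK,ASCK,BW
# (measurements in cm, BW in kg, '.' decimal separator, UTF-8).

#' Read a cohort of biometric records from CSV
#'
#' @param path CSV file with columns
#'   `animal_id,channel,HWK,RHK,BLK,BDLK,BTLK,GSCK,ASCK,BW`.
#' @param require_bw Require observed body weight on every record?
#' @return Data frame with lower-case canonical columns; `bw` may be NA for
#'   prediction-only records when `require_bw = FALSE`.
#' @export
read_cohort <- function(path, require_bw = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  names(df) <- tolower(names(df))
  if (is.null(df$animal_id)) df$animal_id <- as.character(seq_len(nrow(df)))
  if (is.null(df$channel)) df$channel <- "true"
  validate_records(df, require_bw = require_bw)
}

#' Write a cohort of biometric records to CSV
#'
#' @param records Data frame of records (canonical lower-case columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_records(records, require_bw = FALSE)
  out <- records[intersect(c("animal_id", "channel", bw_variables, "bw"),
                           names(records))]
  names(out) <- ifelse(names(out) %in% c(bw_variables, "bw"),
                       toupper(names(out)), names(out))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted weight model to JSON
#'
#' Stores coefficients, exponents, normalization scales and optional
#' provenance (optimizer, seed, evaluation budget) so a fitted model is
#' portable across cohorts.
#'
#' @param model A [polynomial_model()].
#' @param path Output JSON file.
#' @param provenance Optional named list recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "bw_model"))
  obj <- list(
    coefficients = as.list(model$coefficients),
    exponents = as.list(model$exponents),
    norm = list(scales = as.list(model$norm$scales),
                bw_scale = model$norm$bw_scale),
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a weight model from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @return A [polynomial_model()]; any provenance is attached as the
#'   `"provenance"` attribute.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- polynomial_model(unlist(obj$coefficients)[bw_variables],
                        unlist(obj$exponents)[bw_variables],
                        norm_context(unlist(obj$norm$scales)[bw_variables],
                                     obj$norm$bw_scale))
  attr(m, "provenance") <- obj$provenance
  m
}
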