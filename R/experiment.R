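# Experimental protocol: matched-budget GA vs CSA comparison, repeated-run
# validation with averaged metrics, and file reports.

resolve_records <- function(cohort, channel = "kinect") {
  if (inherits(cohort, "bw_cohort")) return(cohort_channel(cohort, channel))
  records <- validate_records(cohort, require_bw = TRUE)
  if (!is.null(records$channel) && channel %in% records$channel)
    records <- records[records$channel == channel, , drop = FALSE]
  records
}

#' Matched-budget comparison of the genetic algorithm and cuckoo search
#'
#' Runs both optimizers on the identical cohort, seed and fitness-evaluation
#' budget (the budget is consumed exactly by both, so the fitness-call
#' counters are equal by construction), and reports per-algorithm error
#' metrics, convergence traces and the per-animal predicted-vs-observed
#' table.
#'
#' @param cohort A `bw_cohort` (its kinect channel is fitted, mirroring the
#'   sensor-based protocol) or a plain records data frame with `bw`.
#' @param budget Shared fitness-evaluation budget.
#' @param seed Integer seed used by both optimizers.
#' @param population_size Individuals / nests for GA / CSA.
#' @param channel Channel to fit when `cohort` is a `bw_cohort`.
#' @return List of class `bw_comparison`: per-algorithm `fit`
#'   ([ga_fit()]/[csa_fit()] results), `metrics` ([weight_metrics()] on the
#'   kg scale), `predictions` (animal, observed and both predictions, kg)
#'   and `fairness` (evaluation counters).
#' @export
run_comparison <- function(cohort, budget = 40000L, seed = 1L,
                           population_size = 200L, channel = "kinect") {
  records <- resolve_records(cohort, channel)
  ga <- ga_fit(records, ga_config(population_size = population_size,
                                  eval_budget = budget), seed = seed)
  csa <- csa_fit(records, csa_config(nests = population_size,
                                     eval_budget = budget), seed = seed)
  if (ga$evaluations_used != csa$evaluations_used)
    stop("internal error: unequal evaluation counts in matched comparison")
  obs <- records$bw
  pred <- list(ga = predict(ga$best_model, records),
               csa = predict(csa$best_model, records))
  metrics <- rbind(cbind(algorithm = "ga", weight_metrics(pred$ga, obs)),
                   cbind(algorithm = "csa", weight_metrics(pred$csa, obs)))
  predictions <- data.frame(animal_id = records$animal_id, observed_kg = obs,
                            ga_kg = pred$ga, csa_kg = pred$csa)
  structure(list(ga = ga, csa = csa, metrics = metrics,
                 predictions = predictions,
                 fairness = c(ga = ga$evaluations_used,
                              csa = csa$evaluations_used),
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "bw_comparison")
}

#' @export
print.bw_comparison <- function(x, ...) {
  cat(sprintf("matched-budget comparison (budget %d, seed %d)\n",
              x$budget, x$seed))
  print(x$metrics, row.names = FALSE)
  cat(sprintf("fitness evaluations: GA %d, CSA %d\n",
              x$fairness[["ga"]], x$fairness[["csa"]]))
  invisible(x)
}

#' Repeated-run validation with averaged metrics
#'
#' Because the optimizers are stochastic, a single fit is validated by
#' repeating it with distinct seeds and averaging the error metrics.  Seeds
#' default to `base_seed + run_index - 1`.
#'
#' @param cohort As in [run_comparison()].
#' @param optimizer `"ga"` or `"csa"`.
#' @param runs Number of independent fits (>= 1).
#' @param base_seed Base seed for derived per-run seeds.
#' @param seeds Optional explicit seed vector (length >= `runs`).
#' @param budget Fitness-evaluation budget per run.
#' @param population_size Individuals / nests.
#' @param channel Channel to fit when `cohort` is a `bw_cohort`.
#' @return List of class `bw_validation`: `per_run` (metrics per run with
#'   its seed), `mean` (arithmetic mean of the per-run metrics) and `fits`.
#' @export
repeated_runs <- function(cohort, optimizer = c("ga", "csa"), runs = 10L,
                          base_seed = 1L, seeds = NULL, budget = 40000L,
                          population_size = 200L, channel = "kinect") {
  optimizer <- match.arg(optimizer)
  stopifnot(runs >= 1L)
  if (is.null(seeds)) seeds <- base_seed + seq_len(runs) - 1L
  if (length(seeds) < runs) stop("need at least `runs` seeds", call. = FALSE)
  seeds <- as.integer(seeds[seq_len(runs)])
  records <- resolve_records(cohort, channel)

  fits <- lapply(seeds, function(s) {
    if (optimizer == "ga")
      ga_fit(records, ga_config(population_size = population_size,
                                eval_budget = budget), seed = s)
    else
      csa_fit(records, csa_config(nests = population_size,
                                  eval_budget = budget), seed = s)
  })
  per_run <- do.call(rbind, lapply(seq_along(fits), function(i) {
    m <- weight_metrics(predict(fits[[i]]$best_model, records), records$bw)
    cbind(run = i, seed = seeds[i], m)
  }))
  mcols <- c("rmse_raw", "rmse_pct", "r2_pct", "mbe_pct", "mape_pct")
  mean_row <- as.data.frame(as.list(colMeans(per_run[mcols])))
  mean_row$n <- per_run$n[1]
  structure(list(optimizer = optimizer, per_run = per_run, mean = mean_row,
                 fits = fits, budget = as.integer(budget), seeds = seeds),
            class = "bw_validation")
}

#' @export
print.bw_validation <- function(x, ...) {
  cat(sprintf("%d-run validation (%s, budget %d)\n",
              nrow(x$per_run), toupper(x$optimizer), x$budget))
  print(x$per_run, row.names = FALSE)
  cat("mean:\n"); print(x$mean, row.names = FALSE)
  invisible(x)
}

atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write experiment reports to a directory
#'
#' Persists a [run_comparison()] or [repeated_runs()] result: fitted model
#' JSON(s), a metrics CSV, convergence-trace CSV, predicted-vs-observed CSV
#' and a plain-text log (including the budget-fairness audit).  Writes are
#' atomic (temp file + rename) and idempotent.
#'
#' @param results A `bw_comparison` or `bw_validation`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
report_outputs <- function(results, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  written <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(dir, name)
    atomic_write(function(p) utils::write.csv(df, p, row.names = FALSE), path)
    written <<- c(written, path)
  }
  log_lines <- c(format(Sys.time(), "report written %Y-%m-%d %H:%M:%S"))

  if (inherits(results, "bw_comparison")) {
    for (alg in c("ga", "csa")) {
      path <- file.path(dir, paste0("model_", alg, ".json"))
      atomic_write(function(p) write_model_json(
        results[[alg]]$best_model, p,
        provenance = list(optimizer = alg, seed = results$seed,
                          budget = results$budget)), path)
      written <- c(written, path)
      tr <- as.data.frame(results[[alg]]$trace)
      tr$algorithm <- alg
      put_csv(tr, paste0("convergence_", alg, ".csv"))
    }
    put_csv(results$metrics, "metrics.csv")
    put_csv(results$predictions, "predictions.csv")
    log_lines <- c(log_lines,
                   sprintf("budget %d seed %d", results$budget, results$seed),
                   sprintf("fairness audit: GA evaluations %d, CSA evaluations %d, equal: %s",
                           results$fairness[["ga"]], results$fairness[["csa"]],
                           results$fairness[["ga"]] == results$fairness[["csa"]]))
  } else if (inherits(results, "bw_validation")) {
    put_csv(results$per_run, "metrics_per_run.csv")
    put_csv(results$mean, "metrics_mean.csv")
    best <- which.min(vapply(results$fits, `[[`, numeric(1), "best_fitness"))
    path <- file.path(dir, "model_best.json")
    atomic_write(function(p) write_model_json(
      results$fits[[best]]$best_model, p,
      provenance = list(optimizer = results$optimizer,
                        seed = results$seeds[best],
                        budget = results$budget)), path)
    written <- c(written, path)
    log_lines <- c(log_lines,
                   sprintf("%s, %d runs, budget %d, seeds %s",
                           results$optimizer, nrow(results$per_run),
                           results$budget,
                           paste(results$seeds, collapse = ",")))
  } else stop("unsupported results object", call. = FALSE)

  log_path <- file.path(dir, "report.log")
  atomic_write(function(p) writeLines(log_lines, p), log_path)
  invisible(c(written, log_path))
}
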