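#' Table-style summary of an event's FIB data
#'
#' Per indicator: sample count, exceedance count, below-LOD count, mean,
#' maximum and standard deviation of concentration (MPN/100 mL, on the
#' substituted scale), coefficient of variation, and the mean and maximum
#' normalized adjacent-sample difference at the event's base interval.
#'
#' @param event A [fib_event()] (raw or processed; censored values are
#'   substituted for the summary).
#' @param indicators Indicators to summarize.
#' @return data.frame, one row per indicator.
#' @export
event_summary <- function(event, indicators = fib_indicators()) {
  indicators <- intersect(indicators, names(event$data))
  rows <- lapply(indicators, function(ind) {
    s <- substitute_censored(event_fib_series(event, ind))
    ds <- delta_series(s)
    data.frame(
      indicator = ind,
      n = length(s$values),
      exceedances = sum(flag_exceedance(s)),
      below_lod = sum(s$below_lod),
      mean = mean(s$values),
      max = max(s$values),
      sd = stats::sd(s$values),
      cv = coefficient_of_variation(s$values),
      mean_delta = ds$mean_delta,
      max_delta = ds$max_delta
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on one event
#'
#' Orchestrates preprocessing ([process_event()]), the Table-style summary,
#' the per-indicator variability analysis ([variability_report()]), the
#' lagged correlation screen ([association_report()]), grouped
#' Kruskal-Wallis comparisons (day/night, tide high/low, cloud category)
#' and the hurdle models ([fit_hurdle()]) into one reproducible report.
#' When `out_dir` is given, writes `processed.csv`, `summary.json`,
#' `variability.json`, `association.json` and `model_<indicator>.json`.
#'
#' @param event A raw or processed [fib_event()].
#' @param indicators Indicators to analyse (default all present).
#' @param seed Integer seed for the model fits.
#' @param intervals Downsampling intervals, minutes.
#' @param max_lag Maximum correlation lag, minutes.
#' @param out_dir Optional output directory.
#' @return A list of class `fib_report` with elements `summary`,
#'   `variability`, `association`, `kruskal`, `models`, `processed`.
#' @export
run_event_analysis <- function(event, indicators = NULL, seed = 0,
                               intervals = c(60, 120, 180, 360, 720, 1440),
                               max_lag = 180, out_dir = NULL) {
  stopifnot(inherits(event, "fib_event"))
  if (is.null(indicators)) {
    indicators <- intersect(fib_indicators(), names(event$data))
  }
  if (!length(indicators)) stop("stage ingest: no FIB columns found")

  processed <- tryCatch(process_event(event),
                        error = function(e) stop("stage preprocess: ",
                                                 conditionMessage(e)))
  summary_tab <- event_summary(processed, indicators)

  variability <- lapply(indicators, function(ind) {
    tryCatch(variability_report(processed, ind, intervals = intervals),
             error = function(e) stop("stage variability (", ind, "): ",
                                      conditionMessage(e)))
  })
  names(variability) <- indicators

  association <- lapply(indicators, function(ind) {
    tryCatch(association_report(processed, ind, max_lag = max_lag),
             error = function(e) stop("stage association (", ind, "): ",
                                      conditionMessage(e)))
  })
  names(association) <- indicators

  d <- processed$data
  kruskal <- lapply(stats::setNames(indicators, indicators), function(ind) {
    vals <- d[[ind]]
    groups <- list(tide = d$tide_high, daytime = d$daytime, cloud = d$cloud)
    lapply(groups[!vapply(groups, is.null, logical(1))],
           function(g) tryCatch(kruskal_wallis(vals, g),
                                error = function(e) NULL))
  })

  models <- lapply(indicators, function(ind) {
    tryCatch({
      design <- build_lagged_design(processed, ind, max_lag = max_lag,
                                    assoc = association[[ind]])
      fit_hurdle(design, seed = seed)
    }, error = function(e) stop("stage model (", ind, "): ",
                                conditionMessage(e)))
  })
  names(models) <- indicators

  report <- structure(
    list(summary = summary_tab, variability = variability,
         association = association, kruskal = kruskal,
         models = models, processed = processed, seed = seed),
    class = "fib_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fib_report <- function(x, ...) {
  cat("<fib_report>\n")
  print(transform(x$summary,
                  mean = round(mean, 1), max = round(max, 1),
                  sd = round(sd, 1), cv = round(cv, 2),
                  mean_delta = round(mean_delta, 2),
                  max_delta = round(max_delta, 2)))
  for (m in x$models) print(m)
  invisible(x)
}

report_json <- function(report) {
  vr <- lapply(report$variability, function(v) {
    list(cv = v$cv, mean = v$mean, sd = v$sd, n = v$n,
         below_lod = v$below_lod, exceedances = v$exceedances,
         mean_delta = v$delta$mean_delta, max_delta = v$delta$max_delta,
         detection_changes = v$detection_changes,
         exceedance_changes = v$exceedance_changes,
         unchanged = v$unchanged,
         downsampled = lapply(v$downsampled, function(dd) {
           list(interval = dd$interval, offsets = dd$offsets,
                mean_of_means = dd$mean_of_means,
                std_of_means = dd$std_of_means)
         }))
  })
  as_assoc <- lapply(report$association, function(a) {
    list(best_lags = a$best_lags,
         rho = lapply(a$correlations, function(cc) {
           list(lags = cc$lags, rho = cc$rho, p = cc$p)
         }))
  })
  models <- lapply(report$models, function(m) {
    list(
      indicator = m$indicator,
      lags = as.list(m$lags),
      binary = if (is.null(m$binary_part)) NULL else list(
        retained = m$binary_part$keep,
        removed = m$binary_part$removed,
        importances = as.list(m$binary_part$importances),
        accuracy = m$binary_part$accuracy
      ),
      concentration = list(
        coefficients = as.list(m$conc_part$coefficients),
        p_values = as.list(m$conc_part$p),
        ar = m$conc_part$ar,
        pruned_by_vif = m$pruned_by_vif,
        vifs = as.list(m$vifs)
      ),
      metrics = m$metrics,
      n_below_lod = m$n_below_lod,
      seed = m$seed
    )
  })
  list(summary = report$summary, variability = vr, association = as_assoc,
       kruskal = report$kruskal, models = models, seed = report$seed)
}

#' Write a report bundle to disk
#'
#' @param report A `fib_report` from [run_event_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_event_csv(report$processed, file.path(out_dir, "processed.csv"))
  j <- report_json(report)
  jsonlite::write_json(j$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(j$variability, file.path(out_dir, "variability.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(j$association, file.path(out_dir, "association.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ind in names(j$models)) {
    jsonlite::write_json(j$models[[ind]],
                         file.path(out_dir, paste0("model_", ind, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
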