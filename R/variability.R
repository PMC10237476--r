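#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' computed on the raw (substituted) concentration scale.
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return Unitless CV.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 3))  # sqrt(2)/2
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least two samples")
  m <- mean(values)
  if (!is.finite(m) || m == 0) stop("mean must be nonzero")
  stats::sd(values) / m
}

#' Normalized adjacent-sample differences (delta_i)
#'
#' The high-frequency variability statistic
#' \deqn{\delta_i(t) = |c(t+i) - c(t)| / \mu}
#' where `i` is the sampling interval, `c` the concentration, and `mu` the
#' mean concentration over the entire series. A mean delta of 1 means
#' consecutive samples differ, on average, by the whole-record mean
#' concentration. Operates on the raw (substituted) concentration scale.
#'
#' @param values Concentration series on a regular grid, or a
#'   [fib_series()] (its `values` are used).
#' @param interval Sampling interval in minutes (metadata only; taken from
#'   the series when a `fib_series` is supplied).
#' @param mu Normalizing mean; defaults to `mean(values)`.
#' @return An object of class `delta_series` with fields `interval`,
#'   `deltas`, `mu`, `mean_delta`, `max_delta`.
#' @export
delta_series <- function(values, interval = NA_real_, mu = NULL) {
  if (inherits(values, "fib_series")) {
    interval <- values$interval
    values <- values$values
  }
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least two samples")
  if (is.null(mu)) mu <- mean(values)
  if (!is.finite(mu) || mu <= 0) stop("series mean must be positive")
  deltas <- abs(diff(values)) / mu
  structure(
    list(interval = interval, deltas = deltas, mu = mu,
         mean_delta = mean(deltas), max_delta = max(deltas)),
    class = "delta_series"
  )
}

#' @export
print.delta_series <- function(x, ...) {
  cat(sprintf("<delta_series> i = %g min: mean %.3g, range 0-%.3g (mu = %.3g)\n",
              x$interval, x$mean_delta, x$max_delta, x$mu))
  invisible(x)
}

#' Variability of downsampled series across start offsets
#'
#' Resamples a base-interval series to a coarser interval. Because a
#' coarser grid admits several choices of first sample (interval / base of
#' them), every start offset is enumerated; for each offset the mean
#' delta_i of the resampled subseries is computed, with the normalizing
#' mean recomputed from that subseries. The spread of mean delta across
#' offsets measures how sensitive an infrequent monitoring program is to
#' when sampling happens to start.
#'
#' @param values Concentration series (or [fib_series()]) at `base` minutes.
#' @param interval Target interval in minutes; must be a multiple of `base`.
#' @param base Base sampling interval in minutes (default 30).
#' @return A `downsample_result`: `interval`, `offsets` (count),
#'   `offset_means` (mean delta per offset), `mean_of_means`, `std_of_means`.
#' @export
downsample_delta <- function(values, interval, base = 30) {
  if (inherits(values, "fib_series")) {
    base <- values$interval
    values <- values$values
  }
  values <- as.numeric(values)
  k <- interval / base
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("interval must be a positive integer multiple of the base interval")
  }
  k <- as.integer(round(k))
  n <- length(values)
  offset_means <- vapply(seq_len(k), function(o) {
    sub <- values[seq(o, n, by = k)]
    if (length(sub) < 2) return(NA_real_)
    delta_series(sub, interval = interval)$mean_delta
  }, numeric(1))
  if (all(is.na(offset_means))) stop("series too short for this interval")
  structure(
    list(interval = interval, offsets = k, offset_means = offset_means,
         mean_of_means = mean(offset_means, na.rm = TRUE),
         std_of_means = stats::sd(offset_means[!is.na(offset_means)])),
    class = "downsample_result"
  )
}

#' Count adjacent-sample status changes
#'
#' Number of positions where a binary status (detection above/below the
#' LOD, or regulatory exceedance) differs from the status of the following
#' sample. The final sample has no successor and contributes no pair.
#'
#' @param flags Logical vector on a regular grid.
#' @return Integer count of changes.
#' @export
status_change_counts <- function(flags) {
  flags <- as.logical(flags)
  if (length(flags) < 2) return(0L)
  sum(flags[-1] != flags[-length(flags)])
}

#' Count adjacent samples with identical concentration
#'
#' MPN concentrations are discrete, so exact repeats occur; their count is
#' a complementary view of short-term variability.
#'
#' @param values Concentration series (or [fib_series()]), substituted.
#' @return Integer count of positions with `c(t+1) == c(t)` exactly.
#' @export
unchanged_concentration_count <- function(values) {
  if (inherits(values, "fib_series")) values <- values$values
  sum(diff(as.numeric(values)) == 0)
}

#' Partial autocorrelation with a large-sample significance band
#'
#' Computes the partial autocorrelation function of a (log10-transformed)
#' concentration series via the Durbin-Levinson recursion on the sample
#' autocorrelations, and flags lags whose coefficient falls outside the
#' two-sided large-sample band +/- 1.96 / sqrt(n).
#'
#' @param values Numeric series (typically log10 concentration).
#' @param max_lag Maximum lag in sampling steps.
#' @return List with `lag`, `pacf`, `band` (half-width), `significant`.
#' @export
partial_autocorrelation <- function(values, max_lag = 20) {
  values <- as.numeric(values)
  n <- length(values)
  if (n <= max_lag + 2) stop("series too short for requested max_lag")
  if (stats::sd(values) == 0) stop("PACF undefined for a constant series")
  pac <- as.numeric(stats::pacf(values, lag.max = max_lag, plot = FALSE)$acf)
  band <- 1.96 / sqrt(n)
  list(lag = seq_len(max_lag), pacf = pac, band = band,
       significant = abs(pac) > band)
}

#' Full variability report for one indicator
#'
#' Bundles the whole-series coefficient of variation, the base-interval
#' delta summary, the downsampling analysis over a set of intervals,
#' detection- and exceedance-status change counts, the unchanged-
#' concentration count and the PACF into one list, mirroring the summary
#' statistics a monitoring study reports.
#'
#' @param event A processed [fib_event()].
#' @param indicator `"tc"`, `"ec"` or `"ent"`.
#' @param intervals Downsampling intervals in minutes (multiples of the
#'   event grid interval; the grid interval itself is reported directly).
#' @param max_lag PACF maximum lag.
#' @return A list of class `variability_report`.
#' @export
variability_report <- function(event, indicator = "ent",
                               intervals = c(60, 120, 180, 360, 720, 1440),
                               max_lag = 20) {
  s <- substitute_censored(event_fib_series(event, indicator))
  exc <- flag_exceedance(s)
  det <- !s$below_lod
  ds <- delta_series(s)
  down <- lapply(intervals, function(iv) downsample_delta(s, iv))
  names(down) <- paste0(intervals, "m")
  structure(
    list(
      indicator = indicator,
      n = length(s$values),
      mean = mean(s$values),
      max = max(s$values),
      sd = stats::sd(s$values),
      cv = coefficient_of_variation(s$values),
      below_lod = sum(s$below_lod),
      exceedances = sum(exc),
      delta = ds,
      downsampled = down,
      detection_changes = status_change_counts(det),
      exceedance_changes = status_change_counts(exc),
      unchanged = unchanged_concentration_count(s),
      pacf = partial_autocorrelation(log10(s$values), max_lag = max_lag)
    ),
    class = "variability_report"
  )
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("<variability_report> %s (n = %d)\n", toupper(x$indicator), x$n))
  cat(sprintf("  mean %.3g  max %.3g  sd %.3g  CV %.3g\n",
              x$mean, x$max, x$sd, x$cv))
  cat(sprintf("  below LOD %d  exceedances %d\n", x$below_lod, x$exceedances))
  cat(sprintf("  mean delta %.3g (0-%.3g); detection changes %d, exceedance changes %d, unchanged %d\n",
              x$delta$mean_delta, x$delta$max_delta,
              x$detection_changes, x$exceedance_changes, x$unchanged))
  invisible(x)
}
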