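# Serially correlated noise helpers. ar1() is parameterized by the
# marginal (stationary) sd; ar2_innov() by the innovation sd, matching how
# the regression error variance is estimated downstream.
ar1 <- function(n, phi, sd, burn = 100) {
  innov <- stats::rnorm(n + burn, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))[(burn + 1):(burn + n)]
}

ar2_innov <- function(n, phi, sd, burn = 200) {
  innov <- stats::rnorm(n + burn, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))[(burn + 1):(burn + n)]
}

#' Ground-truth parameters for the synthetic FIB generator
#'
#' Coefficients are on the log10-MPN-per-z-unit scale applied to z-scored,
#' lag-shifted covariate features; the residual process is AR(2) on the
#' log10 scale with the given innovation standard deviation, and
#' concentrations below `censor_lod` are left-censored. Defaults emulate
#' the magnitudes reported for a 48-hour harbor-beach sampling event:
#' an Enterococcus-like indicator driven by chlorophyll, turbidity,
#' tide state, clear skies and the diel clock with roughly a quarter of
#' samples censored; an E. coli-like indicator (~10-15% censored); and a
#' total-coliform-like indicator far enough above the LOD that censoring
#' is negligible.
#'
#' @param indicator `"ent"`, `"ec"` or `"tc"`.
#' @param intercept,beta,lags,ar,noise_sd,censor_lod Overrides of the
#'   per-indicator defaults. `beta` is a named vector over derived feature
#'   names (see [derive_features()]); `lags` gives minutes per variable.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(indicator = c("ent", "ec", "tc"),
                            intercept = NULL, beta = NULL, lags = NULL,
                            ar = c(0.5, 0.2), noise_sd = NULL,
                            censor_lod = 10) {
  indicator <- match.arg(indicator)
  def <- switch(indicator,
    ent = list(intercept = 1.494,
               beta = c(log_chl = 0.200, log_turb = 0.074, tide_high = -0.095,
                        cloud_clear = 0.226, hours_from_noon = -0.232),
               lags = c(log_chl = 0, log_turb = 0, tide_high = 60,
                        cloud_clear = 180, hours_from_noon = 0),
               noise_sd = 0.50),
    ec = list(intercept = 1.580,
              beta = c(wtemp = 0.234, log_turb = 0.255, dtemp = -0.220,
                       vis = 0.127),
              lags = c(wtemp = 120, log_turb = 0, dtemp = 0, vis = 30),
              noise_sd = 0.30),
    tc = list(intercept = 2.45,
              beta = c(log_turb = 0.354, dtemp = -0.129, daytime = -0.153),
              lags = c(log_turb = 0, dtemp = 0, daytime = 0),
              noise_sd = 0.25)
  )
  if (is.null(intercept)) intercept <- def$intercept
  if (is.null(beta)) beta <- def$beta
  if (is.null(lags)) lags <- def$lags[names(beta)]
  if (is.null(noise_sd)) noise_sd <- def$noise_sd
  lags[is.na(lags)] <- 0
  names(lags) <- names(beta)
  stopifnot(noise_sd > 0)
  # stationarity of the AR(2) residual process
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1)) {
    stop("AR polynomial must have roots outside the unit circle")
  }
  structure(list(indicator = indicator, intercept = intercept, beta = beta,
                 lags = lags, ar = ar, noise_sd = noise_sd,
                 censor_lod = censor_lod),
            class = "synthetic_truth")
}

#' Generate a tide-level series
#'
#' Sum of a semidiurnal (12.42 h) and a diurnal (23.93 h) sinusoid plus an
#' offset, clipped to a configured range — the mixed-tide structure of a
#' US Pacific coast gauge, in meters above mean lower low water.
#'
#' @param times `POSIXct` grid.
#' @param amplitudes Named or positional vector: semidiurnal, diurnal (m).
#' @param offset Mean level (m).
#' @param phase Phases (radians) of the two constituents.
#' @param clip Range to clip to (default 0 to 2 m).
#' @return Numeric tide series (m above MLLW).
#' @export
generate_tide <- function(times, amplitudes = c(0.55, 0.20), offset = 0.85,
                          phase = c(0, 0), clip = c(0, 2)) {
  th <- as.numeric(times) / 3600
  tide <- offset +
    amplitudes[1] * sin(2 * pi * th / 12.42 + phase[1]) +
    amplitudes[2] * sin(2 * pi * th / 23.93 + phase[2])
  pmin(clip[2], pmax(clip[1], tide))
}

#' Generate environmental covariate series
#'
#' Each covariate is a deterministic diel and/or tidal component plus
#' serially correlated AR(1) noise, with ranges emulating a summer
#' harbor-beach deployment (water ~15 C, salinity ~34, chlorophyll with a
#' skewed 0.1-180 ug/L range, turbidity 3-256 NTU, wind ~3 m/s averaging,
#' tide 0.1-1.6 m). Solar irradiance is a non-negative half-sinusoid zeroed
#' at night and damped under cloud; cloud category follows a persistent
#' 3-state Markov chain. Draws come from the current RNG state, so wrap in
#' `set.seed()` (or use [generate_event()]) for reproducibility.
#'
#' @param times `POSIXct` grid.
#' @return data.frame of covariates (`wtemp`, `sal`, `chl`, `turb`, `rad`,
#'   `tide`, `temp`, `dtemp`, `pres`, `wspd`, `wdir`, `vis`, `cloud`).
#' @export
generate_environment <- function(times) {
  n <- length(times)
  lt <- as.POSIXlt(times)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  th <- as.numeric(times) / 3600
  diel <- sin(2 * pi * (h - 9) / 24)          # peaks mid-afternoon
  daylight <- h >= 6.25 & h < 20.25
  sun <- ifelse(daylight, sin(pi * (h - 6.25) / 14), 0)

  # persistent 3-state cloud Markov chain
  states <- c("clear", "overcast", "partly")
  P <- rbind(c(0.92, 0.05, 0.03),
             c(0.05, 0.92, 0.03),
             c(0.10, 0.10, 0.80))
  cloud_i <- integer(n)
  cloud_i[1] <- sample.int(3, 1, prob = c(0.45, 0.45, 0.10))
  if (n > 1) for (t in 2:n) {
    cloud_i[t] <- sample.int(3, 1, prob = P[cloud_i[t - 1], ])
  }
  cloud <- states[cloud_i]
  cloud_damp <- c(clear = 1, overcast = 0.45, partly = 0.75)[cloud]

  data.frame(
    wtemp = 15.1 + 0.3 * diel + ar1(n, 0.90, 0.15),
    sal   = 34.0 + 0.15 * sin(2 * pi * th / 12.42 + 1) + ar1(n, 0.80, 0.08),
    chl   = pmin(180, pmax(0.1, 10^(1.0 + 0.35 * diel + ar1(n, 0.85, 0.35)))),
    turb  = pmin(256, pmax(3, 10^(1.6 + ar1(n, 0.85, 0.30)))),
    rad   = 880 * sun * unname(cloud_damp),
    tide  = generate_tide(times),
    temp  = 15.3 + 1.2 * diel + ar1(n, 0.90, 0.30),
    dtemp = 13.8 + 1.0 * diel + ar1(n, 0.85, 0.35),
    pres  = 1013 + 1.2 * sin(2 * pi * th / 12) + ar1(n, 0.90, 0.50),
    wspd  = pmin(10, pmax(0, 3.2 + 1.8 * diel + ar1(n, 0.80, 0.80))),
    wdir  = (300 + 25 * ar1(n, 0.80, 1.0)) %% 360,
    vis   = pmin(10, pmax(0.5, 8.5 + ar1(n, 0.90, 1.2))),
    cloud = cloud,
    stringsAsFactors = FALSE
  )
}

#' Generate a left-censored FIB series from environmental drivers
#'
#' Implements the lagged log-linear response the analysis assumes:
#' \deqn{\log_{10} c(t) = \alpha + \sum_j \beta_j z_j(t - lag_j) + \epsilon(t)}
#' with `z_j` the z-scored derived covariate features, `epsilon` an AR(2)
#' process on the log10 scale, and concentrations below `censor_lod`
#' marked below-LOD and substituted with 1 MPN/100 mL. Lagged values
#' preceding the series start are padded with the first value. The exact
#' design matrix used (z-scored, lag-shifted) and the uncensored log10
#' series are attached as attributes `"design"` and `"true_log10"` for
#' recovery tests.
#'
#' @param event A [fib_event()] carrying the environmental columns (derived
#'   features are computed if absent).
#' @param truth A [synthetic_truth()].
#' @return A censored [fib_series()].
#' @export
generate_fib <- function(event, truth) {
  stopifnot(inherits(event, "fib_event"), inherits(truth, "synthetic_truth"))
  ev <- if ("hours_from_noon" %in% names(event$data)) event
        else derive_features(event)
  d <- ev$data
  n <- nrow(d)
  step <- ev$interval
  miss <- setdiff(names(truth$beta), names(d))
  if (length(miss)) stop("event lacks feature(s): ", paste(miss, collapse = ", "))

  Z <- vapply(names(truth$beta), function(v) {
    z <- as.numeric(d[[v]])
    # a driver constant over the block is absorbed by the intercept
    if (stats::sd(z) == 0) return(numeric(n))
    z <- (z - mean(z)) / stats::sd(z)
    k <- as.integer(round(truth$lags[[v]] / step))
    if (k >= n) stop("lag exceeds the series span for ", v)
    if (k > 0) z <- c(rep(z[1], k), z[seq_len(n - k)])
    z
  }, numeric(n))

  eps <- ar2_innov(n, truth$ar, truth$noise_sd)
  log10c <- truth$intercept + as.numeric(Z %*% truth$beta) + eps
  conc <- 10^log10c
  below <- conc < truth$censor_lod
  values <- ifelse(below, fib_defaults()$substitute, conc)

  out <- fib_series(values, d$timestamp, indicator = truth$indicator,
                    below_lod = below)
  attr(out, "design") <- Z
  attr(out, "true_log10") <- log10c
  out
}

#' Generate a complete synthetic sampling event
#'
#' Produces a 48-hour, 30-minute-interval event dataset (N = 96 by
#' default): tidal/diel environmental covariates with serially correlated
#' noise, plus one left-censored FIB series per supplied truth, fully
#' reproducible from the seed. Optionally nests a 1-minute 'sprint' block
#' (31 samples spanning 11:00-11:30 on the second day, bracketing
#' on-the-hour samples included) generated by the same mechanism with the
#' innovation sd scaled by `sprint_sd_factor`, reflecting the smaller
#' sample-to-sample variation observed at 1-minute spacing.
#'
#' @param seed Integer seed; identical (arguments, seed) pairs give
#'   identical output.
#' @param n Number of main-event samples (default 96).
#' @param interval Main-event sampling interval, minutes (default 30).
#' @param start Event start time (character or POSIXct).
#' @param truths Named list of [synthetic_truth()]s, one per indicator.
#' @param sprint Generate the nested 1-minute block?
#' @param sprint_sd_factor Innovation-sd multiplier for the sprint block.
#' @return A list with `event` (a processed-schema [fib_event()]), `truth`,
#'   `true_log10` (per indicator), and optionally `sprint` (same structure).
#' @export
generate_event <- function(seed = 0, n = 96, interval = 30,
                           start = "2022-08-01 08:00:00",
                           truths = list(tc = synthetic_truth("tc"),
                                         ec = synthetic_truth("ec"),
                                         ent = synthetic_truth("ent")),
                           sprint = FALSE, sprint_sd_factor = 0.5) {
  set.seed(seed)
  times <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * interval * 60
  build <- function(times, truths) {
    env <- generate_environment(times)
    ev <- fib_event(cbind(data.frame(timestamp = times), env))
    ev <- derive_features(ev)
    truth_log <- list()
    for (ind in names(truths)) {
      fib <- generate_fib(ev, truths[[ind]])
      ev$data[[ind]] <- fib$values
      ev$data[[paste0(ind, "_blod")]] <- fib$below_lod
      ev$data[[paste0("log_", ind)]] <- log10(fib$values)
      truth_log[[ind]] <- attr(fib, "true_log10")
    }
    list(event = ev, truth = truths, true_log10 = truth_log)
  }
  out <- build(times, truths)
  if (sprint) {
    day2 <- as.POSIXct(start, tz = "UTC") + 24 * 3600
    t0 <- trunc(day2, "days") + 11 * 3600
    sprint_times <- t0 + 0:30 * 60
    sprint_truths <- lapply(truths, function(tr) {
      tr$noise_sd <- tr$noise_sd * sprint_sd_factor
      # driver lags exceed the 30-min block span; within it they act at lag 0
      tr$lags[] <- 0
      tr
    })
    out$sprint <- build(sprint_times, sprint_truths)
  }
  out
}
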