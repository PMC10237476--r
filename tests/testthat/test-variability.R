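test_that("coefficient of variation matches hand computation and scales invariantly", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(11)
  x <- runif(40, 1, 100)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
  expect_error(coefficient_of_variation(5), "two samples")
})

test_that("delta series implements |c(t+i) - c(t)| / mu over adjacent pairs", {
  expect_equal(delta_series(c(7, 7, 7, 7))$deltas, c(0, 0, 0))
  d <- delta_series(c(10, 20))
  expect_equal(d$deltas, 10 / 15)
  expect_equal(d$mu, 15)

  # brute-force oracle and rescaling invariance on random series
  set.seed(21)
  for (i in 1:20) {
    x <- runif(sample(5:60, 1), 1, 1000)
    mu <- mean(x)
    bf <- vapply(seq_len(length(x) - 1),
                 function(t) abs(x[t + 1] - x[t]) / mu, numeric(1))
    d <- delta_series(x)
    expect_equal(d$deltas, bf, tolerance = 1e-14)
    expect_equal(d$mean_delta, mean(bf))
    expect_equal(d$max_delta, max(bf))
    expect_equal(delta_series(13 * x)$deltas, d$deltas, tolerance = 1e-12)
  }
  expect_error(delta_series(5), "two samples")
})

test_that("downsampling enumerates every start offset with per-offset means", {
  x <- c(1, 5, 2, 8, 3, 9, 4, 7)
  r <- downsample_delta(x, 60, base = 30)
  expect_equal(r$offsets, 2)
  # offset subseries computed by hand, mu recomputed per subseries
  o1 <- x[c(1, 3, 5, 7)]; o2 <- x[c(2, 4, 6, 8)]
  expect_equal(r$offset_means,
               c(mean(abs(diff(o1)) / mean(o1)),
                 mean(abs(diff(o2)) / mean(o2))))
  expect_equal(r$mean_of_means, mean(r$offset_means))
  expect_equal(r$std_of_means, sd(r$offset_means))

  const <- downsample_delta(rep(4, 96), 120, base = 30)
  expect_equal(const$mean_of_means, 0)
  expect_equal(const$std_of_means, 0)

  # 24-h interval on a 96-sample, 30-min series: 48 offsets of one pair each
  r24 <- downsample_delta(runif(96, 1, 10), 1440, base = 30)
  expect_equal(r24$offsets, 48)
  expect_true(all(is.finite(r24$offset_means)))

  expect_error(downsample_delta(x, 45, base = 30), "multiple")
})

test_that("status changes and unchanged concentrations count adjacent pairs", {
  expect_equal(status_change_counts(c(TRUE, TRUE, TRUE)), 0L)
  expect_equal(status_change_counts(c(TRUE, FALSE, TRUE, FALSE)), 3L)
  expect_equal(status_change_counts(rep(c(TRUE, TRUE, FALSE), 3)),
               sum(diff(rep(c(1, 1, 0), 3)) != 0))

  expect_equal(unchanged_concentration_count(1:10), 0)
  expect_equal(unchanged_concentration_count(rep(7, 6)), 5)
  expect_equal(unchanged_concentration_count(c(10, 10, 20, 20, 31)), 2)
})

test_that("PACF matches AR theory and flags ~5% of white-noise lags", {
  set.seed(31)
  x <- as.numeric(stats::filter(rnorm(2100), 0.8, method = "recursive"))[101:2100]
  p <- partial_autocorrelation(x, max_lag = 10)
  expect_equal(p$pacf[1], 0.8, tolerance = 0.05)
  expect_true(sum(abs(p$pacf[2:10]) > p$band) <= 2)

  # lag-1 PACF is the lag-1 autocorrelation
  a1 <- as.numeric(stats::acf(x, lag.max = 1, plot = FALSE)$acf)[2]
  expect_equal(p$pacf[1], a1, tolerance = 1e-10)

  # white noise: fraction of flagged lags near the nominal 5%
  set.seed(32)
  flagged <- replicate(200, {
    p <- partial_autocorrelation(rnorm(96), max_lag = 15)
    mean(p$significant)
  })
  expect_gt(mean(flagged), 0.02)
  expect_lt(mean(flagged), 0.10)

  expect_error(partial_autocorrelation(rep(1, 50)), "constant")
  expect_error(partial_autocorrelation(rnorm(10), max_lag = 9), "short")
})

test_that("variability report aggregates all statistics consistently", {
  g <- generate_event(seed = 5)
  v <- variability_report(g$event, "ent",
                          intervals = c(60, 120, 360, 1440))
  s <- substitute_censored(event_fib_series(g$event, "ent"))
  expect_equal(v$n, 96)
  expect_equal(v$cv, sd(s$values) / mean(s$values))
  expect_equal(v$below_lod, sum(s$below_lod))
  expect_equal(v$delta$mean_delta, mean(abs(diff(s$values)) / mean(s$values)))
  expect_equal(v$downsampled$`1440m`$offsets, 48)
  expect_equal(v$detection_changes, status_change_counts(!s$below_lod))
})
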