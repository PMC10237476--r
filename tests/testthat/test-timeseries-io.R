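test_that("read_event_csv parses censored and missing cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  ev <- read_event_csv(path)
  expect_s3_class(ev, "fib_event")
  expect_equal(nrow(ev$data), 8)
  expect_equal(ev$interval, 30)
  expect_true(ev$data$ent_blod[3])
  expect_true(is.na(ev$data$ent[3]))
  expect_false(any(ev$data$ent_blod[-3]))
  expect_true(is.na(ev$data$turb[5]))
})

test_that("read_event_csv rejects broken timestamp columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  raw$timestamp[2] <- raw$timestamp[1]           # duplicate
  utils::write.csv(raw, path, row.names = FALSE)
  expect_error(read_event_csv(path), "duplicat")

  raw$timestamp <- NULL
  utils::write.csv(raw, path, row.names = FALSE)
  expect_error(read_event_csv(path), "timestamp")
})

test_that("censored substitution sets below-LOD values to 1 and nothing else", {
  s <- make_series(c(NA, 10, 500, 24196),
                   below_lod = c(TRUE, FALSE, FALSE, FALSE))
  out <- substitute_censored(s)
  expect_equal(out$values, c(1, 10, 500, 24196))
  expect_true(min(out$values) >= out$substitute_value)

  over <- make_series(c(20, 30000))
  expect_warning(substitute_censored(over), "upper LOD")
})

test_that("exceedance uses strict inequality at the regulatory threshold", {
  ent <- make_series(c(103, 104, 105), indicator = "ent")
  expect_equal(flag_exceedance(ent), c(FALSE, FALSE, TRUE))
  ec <- make_series(c(400, 401), indicator = "ec")
  expect_equal(flag_exceedance(ec), c(FALSE, TRUE))
  tc <- make_series(c(10000, 10001), indicator = "tc")
  expect_equal(flag_exceedance(tc), c(FALSE, TRUE))
})

test_that("interpolation fills interior gaps linearly and extends the ends", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(1, NA, NA, 4)), c(1, 2, 3, 4))
  expect_equal(interpolate_missing(c(5, 6, 7)), c(5, 6, 7))
  expect_equal(interpolate_missing(c(NA, 2, 3, NA)), c(2, 2, 3, 3))
  expect_error(interpolate_missing(c(1:8, rep(NA, 4))), "quality guard")
})

test_that("external series align by exact match or linear interpolation", {
  src_t <- grid_times(26, interval = 6)
  src_v <- seq_along(src_t)
  grid <- grid_times(6, interval = 30)
  expect_equal(align_external(src_t, src_v, grid), src_v[seq(1, 26, by = 5)])

  mid <- grid_times(2, interval = 30)[2] - 15 * 60   # between source points
  expect_equal(align_external(src_t, src_v, mid), 3.5)
  expect_error(align_external(src_t, src_v, src_t[1] - 3600), "cover")
})

test_that("derived features obey the projection, dummy and night contracts", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  ev <- process_event(read_event_csv(path))
  d <- ev$data

  # wind blowing toward the beach normal: fully offshore component
  expect_equal(d$owind, rep(3, nrow(d)), tolerance = 1e-12)
  expect_equal(d$awind, rep(0, nrow(d)), tolerance = 1e-12)
  expect_equal(d$owind^2 + d$awind^2, d$wspd^2, tolerance = 1e-9)

  dummies <- d[, c("cloud_clear", "cloud_overcast", "cloud_partly")]
  expect_true(all(rowSums(dummies) == 1))

  expect_equal(d$tide_high, d$tide > 1)
  expect_equal(d$log_chl[1], 0)                  # chl = 0 -> log10(0 + 1)
  expect_true(all(d$rad[!d$daytime] == 0))
  expect_true(all(d$ent >= 1))
  expect_equal(d$hours_from_noon[1], 4)          # 08:00 start

  # random-direction projection identity
  set.seed(1)
  wspd <- runif(50, 0, 8); wdir <- runif(50, 0, 360)
  ev2 <- fib_event(data.frame(timestamp = grid_times(50),
                              wspd = wspd, wdir = wdir))
  d2 <- derive_features(ev2)$data
  expect_equal(d2$owind^2 + d2$awind^2, wspd^2, tolerance = 1e-9)
})

test_that("unknown cloud categories are fatal", {
  ev <- fib_event(data.frame(timestamp = grid_times(4),
                             cloud = c("clear", "foggy", "clear", "clear")))
  expect_error(derive_features(ev), "unknown cloud")
})

test_that("event CSV round-trips to printed precision", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  ev <- process_event(read_event_csv(path))
  out <- withr::local_tempfile(fileext = ".csv")
  write_event_csv(ev, out)
  back <- read_event_csv(out)
  for (col in c("ent", "tide", "wtemp", "turb")) {
    expect_equal(back$data[[col]], ev$data[[col]], tolerance = 1e-8)
  }
  expect_equal(back$data$timestamp, ev$data$timestamp)
})

test_that("fib_series enforces its grid invariants", {
  t8 <- grid_times(8)
  expect_error(fib_series(1:8, rev(t8)), "increasing")
  expect_error(fib_series(1:8, t8[c(1:7, 7)]), "increasing")
  uneven <- t8; uneven[3] <- uneven[3] + 60
  expect_error(fib_series(1:8, uneven), "constant-interval")
})
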