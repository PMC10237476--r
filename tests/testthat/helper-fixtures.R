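# Shared fixtures built in code.

grid_times <- function(n, interval = 30, start = "2022-08-01 08:00:00") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * interval * 60
}

make_series <- function(values, indicator = "ent", interval = 30,
                        below_lod = NULL) {
  fib_series(values, grid_times(length(values), interval),
             indicator = indicator, below_lod = below_lod)
}

# Minimal raw-event CSV with a censored cell, a missing turbidity cell and
# every column the reader understands.
write_fixture_csv <- function(path, n = 8) {
  ts <- format(grid_times(n), "%Y-%m-%dT%H:%M:%S")
  ent <- as.character(round(seq(20, 160, length.out = n)))
  ent[3] <- "<10"
  turb <- as.character(seq(5, 40, length.out = n))
  turb[5] <- ""
  df <- data.frame(
    timestamp = ts, tc = 300 + seq_len(n), ec = 50 + seq_len(n), ent = ent,
    wtemp = 15 + 0.1 * seq_len(n), sal = 34, chl = seq(0, 7, length.out = n),
    turb = turb, rad = c(rep(500, n - 2), 0, 0),
    tide = seq(0.2, 1.5, length.out = n), temp = 15.3, dtemp = 13.5,
    pres = 1013, wspd = 3, wdir = 320, vis = 9,
    cloud = rep(c("clear", "overcast"), length.out = n),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Three columns whose sample correlation matrix is exactly the target
# (orthonormal basis orthogonal to the intercept, mixed by Cholesky).
exact_corr_design <- function(n = 30, R = matrix(c(1, .5, .5,
                                                   .5, 1, .5,
                                                   .5, .5, 1), 3)) {
  set.seed(42)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  X <- Q %*% chol(R) * sqrt(n - 1)
  colnames(X) <- paste0("v", 1:3)
  X
}
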