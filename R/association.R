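#' Spearman rank correlation with tie correction
#'
#' Tie-corrected (average-rank) Spearman correlation with a p-value from
#' the large-sample t approximation. Pairs with a missing value in either
#' argument are dropped.
#'
#' @param x,y Numeric vectors of equal length (n >= 5 after NA removal).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant input")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Lagged cross-correlation between FIB and an environmental variable
#'
#' For each lag L, the environmental value observed L minutes before each
#' FIB sample is paired with that sample and the Spearman correlation of
#' the overlap is computed. Lagged values that precede the series start are
#' dropped pairwise, so a 3-hour maximum lag on a 30-minute grid loses at
#' most six pairs.
#'
#' @param fib Numeric FIB series (log10 concentration by convention;
#'   Spearman is invariant to the monotone log transform).
#' @param env Environmental series on the same grid.
#' @param lags Lags in minutes (multiples of `interval`).
#' @param interval Grid interval in minutes.
#' @param variable Name recorded in the result.
#' @return A `lag_correlation`: `variable`, `lags`, `rho`, `p`, `best_lag`.
#' @export
cross_correlation <- function(fib, env, lags = seq(0, 180, by = 30),
                              interval = 30, variable = "env") {
  fib <- as.numeric(fib); env <- as.numeric(env)
  if (length(fib) != length(env)) stop("series must share the grid")
  steps <- lags / interval
  if (any(abs(steps - round(steps)) > 1e-9)) {
    stop("each lag must be a multiple of the grid interval")
  }
  n <- length(fib)
  res <- lapply(as.integer(round(steps)), function(k) {
    shifted <- if (k == 0) env else c(rep(NA_real_, k), env[seq_len(n - k)])
    ok <- is.finite(fib) & is.finite(shifted)
    if (sum(ok) < 10 ||
        stats::sd(fib[ok]) == 0 || stats::sd(shifted[ok]) == 0) {
      return(list(rho = NA_real_, p = NA_real_))
    }
    spearman_cor(fib[ok], shifted[ok])
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- structure(
    list(variable = variable, lags = lags, rho = rho, p = p),
    class = "lag_correlation"
  )
  out$best_lag <- if (any(is.finite(rho))) select_lag(out)$best_lag else NA_real_
  out
}

#' Select the lag with the strongest correlation
#'
#' Keeps only the lagged version of a variable with the largest magnitude
#' Spearman correlation; ties are broken toward the smaller lag so that an
#' uninformative flat profile defaults to the unlagged variable.
#'
#' @param corr A `lag_correlation` from [cross_correlation()].
#' @return List with `variable`, `best_lag`, `rho` at that lag.
#' @export
select_lag <- function(corr) {
  stopifnot(inherits(corr, "lag_correlation"))
  a <- abs(corr$rho)
  if (all(is.na(a))) stop("no finite correlation at any lag")
  a[is.na(a)] <- -Inf
  best <- which.max(a)  # which.max returns the first (smallest-lag) maximum
  list(variable = corr$variable, best_lag = corr$lags[best],
       rho = corr$rho[best])
}

#' Kruskal-Wallis comparison of concentrations across groups
#'
#' Tie-corrected Kruskal-Wallis rank-sum test with the chi-square reference
#' distribution on k - 1 degrees of freedom, used to compare FIB
#' concentrations between temporal environmental categories (day vs night,
#' high vs low tide, cloud category).
#'
#' @param values Concentration series.
#' @param groups Categorical series of equal length.
#' @return List with `H`, `df`, `p`, `n_groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- is.finite(as.numeric(values)) & !is.na(groups)
  values <- as.numeric(values)[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least two non-empty groups")
  if (any(table(groups) < 2)) {
    warning("a group has fewer than 2 members; test may be unreliable")
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n_groups = nlevels(groups))
}

# Environmental variables entering the lag screen and the models, in the
# order they are reported. daytime and hours_from_noon are exempt from
# lagging (they encode the diel clock itself).
lagged_variables <- function() {
  c("wtemp", "sal", "log_chl", "log_turb", "rad", "tide", "tide_high",
    "temp", "dtemp", "pres", "wspd", "awind", "owind", "vis",
    "cloud_overcast", "cloud_partly", "cloud_clear")
}

unlagged_variables <- function() c("daytime", "hours_from_noon")

#' Cross-correlation screen of all environmental variables
#'
#' Runs [cross_correlation()] of one indicator's log10 concentration
#' against every available environmental variable over the lag grid, and
#' records the selected best lag per variable. Cloud categories enter as
#' their 0/1 dummies; `daytime` and `hours_from_noon` are reported at lag 0
#' only.
#'
#' @param event A processed [fib_event()].
#' @param indicator `"tc"`, `"ec"` or `"ent"`.
#' @param max_lag Maximum lag in minutes (default 180).
#' @return A list of class `association_report`: per-variable
#'   `lag_correlation`s plus a `best_lags` table.
#' @export
association_report <- function(event, indicator = "ent", max_lag = 180) {
  d <- event$data
  y <- d[[paste0("log_", indicator)]]
  if (is.null(y)) stop("event is not processed: missing log_", indicator)
  lags <- seq(0, max_lag, by = event$interval)
  vars <- intersect(lagged_variables(), names(d))
  corrs <- lapply(vars, function(v) {
    cross_correlation(y, as.numeric(d[[v]]), lags = lags,
                      interval = event$interval, variable = v)
  })
  names(corrs) <- vars
  for (v in intersect(unlagged_variables(), names(d))) {
    corrs[[v]] <- cross_correlation(y, as.numeric(d[[v]]), lags = 0,
                                    interval = event$interval, variable = v)
  }
  # a variable constant over the record carries no information; drop it
  corrs <- Filter(function(cc) any(is.finite(cc$rho)), corrs)
  best <- do.call(rbind, lapply(corrs, function(cc) {
    s <- select_lag(cc)
    data.frame(variable = s$variable, lag = s$best_lag, rho = s$rho)
  }))
  rownames(best) <- NULL
  structure(list(indicator = indicator, correlations = corrs,
                 best_lags = best),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("<association_report> %s: %d variables screened\n",
              toupper(x$indicator), nrow(x$best_lags)))
  print(transform(x$best_lags, rho = round(rho, 3)))
  invisible(x)
}
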