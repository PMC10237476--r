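shift_steps <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  c(rep(NA_real_, k), x[seq_len(n - k)])
}

#' Z-score a raw design matrix
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator), so that fitted coefficients are comparable measures
#' of relative importance. Constant columns cannot be scaled and are
#' dropped with a warning. The per-column mean and sd are retained for the
#' inverse transform.
#'
#' @param x Numeric matrix or data.frame of predictors.
#' @return List with `x` (z-scored matrix) and `norm_params` (`mean`, `sd`).
#' @export
zscore_design <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("design must not contain missing values")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  mus <- colMeans(x)
  z <- sweep(sweep(x, 2, mus, "-"), 2, sds, "/")
  list(x = z, norm_params = list(mean = mus, sd = sds))
}

#' Build the per-indicator lagged, normalized design matrix
#'
#' For one indicator, screens every environmental variable over the lag
#' grid ([cross_correlation()]), keeps only the best-correlated lag of each
#' ([select_lag()]), shifts each variable by its selected lag, drops the
#' leading rows lost to lagging, and z-scores the columns. `daytime` and
#' `hours_from_noon` enter unlagged. The binary target is detection above
#' the lower LOD; the concentration target is log10 substituted
#' concentration (0 for censored samples).
#'
#' @param event A processed [fib_event()].
#' @param indicator `"tc"`, `"ec"` or `"ent"`.
#' @param max_lag Maximum screened lag, minutes.
#' @param assoc Optional precomputed [association_report()] to reuse.
#' @return An object of class `lagged_design`.
#' @export
build_lagged_design <- function(event, indicator = "ent", max_lag = 180,
                                assoc = NULL) {
  if (is.null(assoc)) {
    assoc <- association_report(event, indicator, max_lag = max_lag)
  }
  d <- event$data
  step <- event$interval
  lags <- stats::setNames(assoc$best_lags$lag, assoc$best_lags$variable)
  cols <- lapply(names(lags), function(v) {
    shift_steps(as.numeric(d[[v]]), as.integer(round(lags[[v]] / step)))
  })
  x <- do.call(cbind, cols)
  colnames(x) <- names(lags)
  keep <- stats::complete.cases(x)
  # lag-induced loss is confined to the first max(lag)/step rows
  x <- x[keep, , drop = FALSE]

  s <- substitute_censored(event_fib_series(event, indicator))
  z <- zscore_design(x)
  structure(
    list(indicator = indicator,
         x = z$x,
         lags = lags[colnames(z$x)],
         target_binary = !s$below_lod[keep],
         target_conc = log10(s$values[keep]),
         norm_params = z$norm_params),
    class = "lagged_design"
  )
}

#' Fit the random-forest detection part
#'
#' Classifies whether a sample is above the lower LOD using a random
#' forest with 100 trees, bootstrap resampling per tree, Gini splits and
#' floor(sqrt(p)) candidate variables per split (unlimited depth);
#' prediction is by majority vote and accuracy is evaluated in-sample (the
#' model is descriptive, not predictive). If the target has a single class
#' (as for an indicator never measured below the LOD) there is no binary
#' part and `NULL` is returned with a message.
#'
#' @param x Numeric predictor matrix (z-scored).
#' @param y Logical detection target.
#' @param seed Integer seed; the fit is bit-reproducible given the seed.
#' @return List with `forest`, `accuracy`, `predictions` (0/1), or `NULL`.
#' @export
fit_binary_forest <- function(x, y, seed = 0) {
  y <- as.logical(y)
  if (length(unique(y)) < 2) {
    message("no binary part: detection target has a single class")
    return(NULL)
  }
  x <- as.data.frame(x)
  yf <- factor(as.integer(y), levels = c(0, 1))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = yf, ntree = 100,
    mtry = max(1, floor(sqrt(ncol(x)))), replace = TRUE
  )
  pred <- stats::predict(forest, newdata = x)
  list(forest = forest, accuracy = mean(pred == yf),
       predictions = as.integer(as.character(pred)))
}

perm_importance <- function(forest, x, y, n_shuffles = 5) {
  x <- as.data.frame(x)
  yf <- factor(as.integer(as.logical(y)), levels = c(0, 1))
  baseline <- mean(stats::predict(forest, newdata = x) == yf)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(n_shuffles), function(r) {
      xs <- x
      xs[[j]] <- sample(xs[[j]])
      baseline - mean(stats::predict(forest, newdata = xs) == yf)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  stats::setNames(imp, colnames(x))
}

#' Prune the detection forest by permutation feature importance
#'
#' A variable's permutation importance is the mean drop in in-sample
#' accuracy over five independent shuffles of that variable's column at
#' evaluation time (the forest is not refit per shuffle). Variables whose
#' mean importance is not positive are removed, the forest is refit on the
#' remainder, and the reported importances come from the refit forest (so
#' they are normalized to the final variable set). If pruning would remove
#' everything, the single most important variable is kept with a warning.
#'
#' @param binary A fit from [fit_binary_forest()].
#' @param x,y The design matrix and detection target used for the fit.
#' @param seed Integer seed controlling shuffles and the refit.
#' @param n_shuffles Shuffles per variable (default 5).
#' @return List with `forest`, `keep`, `removed`, `importances` (refit
#'   forest), `accuracy`, `predictions`.
#' @export
permutation_prune <- function(binary, x, y, seed = 0, n_shuffles = 5) {
  stopifnot(!is.null(binary$forest))
  x <- as.data.frame(x)
  set.seed(seed + 1L)
  imp0 <- perm_importance(binary$forest, x, y, n_shuffles)
  keep <- names(imp0)[imp0 > 0]
  if (!length(keep)) {
    warning("all variables had non-positive importance; keeping the top one")
    keep <- names(imp0)[which.max(imp0)]
  }
  refit <- fit_binary_forest(x[, keep, drop = FALSE], y, seed = seed)
  set.seed(seed + 2L)
  imp <- perm_importance(refit$forest, x[, keep, drop = FALSE], y, n_shuffles)
  list(forest = refit$forest, keep = keep,
       removed = setdiff(names(imp0), keep),
       importances = imp, accuracy = refit$accuracy,
       predictions = refit$predictions)
}

#' Variance inflation factor of one design column
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from an ordinary
#' least-squares regression of column `j` on all the other columns plus an
#' intercept. Perfect collinearity yields `Inf`; a lone column has VIF 1.
#'
#' @param x Numeric design matrix.
#' @param j Column index or name.
#' @return VIF, a unitless value >= 1.
#' @export
vif <- function(x, j) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(1)
  if (is.character(j)) j <- match(j, colnames(x))
  yj <- x[, j]
  others <- cbind(1, x[, -j, drop = FALSE])
  fit <- stats::lm.fit(others, yj)
  sst <- sum((yj - mean(yj))^2)
  if (sst == 0) return(Inf)
  r2 <- 1 - sum(fit$residuals^2) / sst
  if (r2 > 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

vif_values <- function(x) {
  x <- as.matrix(x)
  stats::setNames(vapply(seq_len(ncol(x)), function(j) vif(x, j), numeric(1)),
                  colnames(x))
}

#' Iteratively prune the design until all VIFs are below a threshold
#'
#' While any variable's VIF is at or above the threshold, the variable with
#' the greatest VIF is removed (ties broken by column order) and the VIFs
#' are recomputed. The removal order is the multicollinearity audit trail.
#'
#' @param x Numeric design matrix.
#' @param threshold VIF threshold (default 5).
#' @return List with `x` (pruned), `removed` (in removal order), `vifs`
#'   (final values).
#' @export
vif_prune_loop <- function(x, threshold = 5) {
  x <- as.matrix(x)
  removed <- character(0)
  repeat {
    v <- vif_values(x)
    if (!length(v) || max(v) < threshold) break
    worst <- which.max(v)  # first maximum = smallest column index on ties
    removed <- c(removed, colnames(x)[worst])
    x <- x[, -worst, drop = FALSE]
  }
  list(x = x, removed = removed, vifs = vif_values(x))
}

qd_filter <- function(v, ar) {
  # quasi-difference: z_t = v_t - sum_k ar_k v_{t-k}, dropping the first
  # length(ar) observations
  p <- length(ar)
  n <- length(v)
  z <- v[(p + 1):n]
  for (k in seq_len(p)) z <- z - ar[k] * v[(p + 1 - k):(n - k)]
  z
}

#' Generalized least squares with autoregressive errors
#'
#' Fits `y = intercept + x b + e` where the residual process `e` is
#' autoregressive of the given order, by iterative feasible GLS:
#' \enumerate{
#'   \item ordinary least squares of `y` on the design plus intercept;
#'   \item estimate the AR coefficients by least squares of the residual on
#'     its first `order` lags;
#'   \item quasi-difference `y`, the intercept and every column by the AR
#'     filter and refit by OLS;
#'   \item repeat steps 2-3 `iterations` times, re-deriving residuals on
#'     the original scale from the current coefficients each round.
#' }
#' Coefficient standard errors, t statistics and p-values come from the
#' final whitened regression. With `order = 0` the fit is exactly ordinary
#' least squares.
#'
#' @param x Numeric predictor matrix (no intercept column), or `NULL` for
#'   an intercept-only model.
#' @param y Numeric response (log10 concentration by convention).
#' @param order AR order of the residual process (default 2).
#' @param iterations Feasible-GLS iterations (default 5).
#' @return An object of class `gls_ar` with `coefficients` (intercept
#'   first), `se`, `t`, `p`, `ar`, `fitted` (original scale), `residuals`,
#'   `whitened_residuals`, `df`, `sigma2`.
#' @export
fit_gls_ar <- function(x, y, order = 2, iterations = 5) {
  y <- as.numeric(y)
  if (is.null(x)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(intercept)"))
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    X <- cbind("(intercept)" = 1, x)
  }
  n <- nrow(X)
  if (n <= ncol(X) + order + 1) stop("too few observations for this design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is non-invertible; offending column(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- qr.coef(qrX, y)
  ar <- numeric(0)
  Xw <- X; yw <- y
  if (order > 0) {
    for (it in seq_len(iterations)) {
      e <- as.numeric(y - X %*% beta)
      if (stats::sd(e) < 1e-10) {      # exact fit: nothing left to whiten
        ar <- numeric(order)
        Xw <- X; yw <- y
        break
      }
      E <- stats::embed(e, order + 1)
      ar <- qr.coef(qr(E[, -1, drop = FALSE]), E[, 1])
      yw <- qd_filter(y, ar)
      Xw <- apply(X, 2, qd_filter, ar = ar)
      beta <- qr.coef(qr(Xw), yw)
    }
  }

  fitw <- stats::lm.fit(Xw, yw)
  df <- nrow(Xw) - ncol(Xw)
  sigma2 <- sum(fitw$residuals^2) / df
  XtXi <- chol2inv(qr.R(qr(Xw)))
  se <- sqrt(diag(XtXi) * sigma2)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  fitted <- as.numeric(X %*% beta)

  structure(
    list(coefficients = beta, se = stats::setNames(se, names(beta)),
         t = tstat, p = stats::setNames(p, names(beta)),
         ar = as.numeric(ar), order = order,
         fitted = fitted, residuals = y - fitted,
         whitened_residuals = as.numeric(fitw$residuals),
         df = df, sigma2 = sigma2, n = n),
    class = "gls_ar"
  )
}

#' @export
print.gls_ar <- function(x, ...) {
  cat(sprintf("<gls_ar> AR(%d) errors, n = %d\n", x$order, x$n))
  tab <- data.frame(coefficient = round(x$coefficients, 4),
                    se = round(x$se, 4), p = signif(x$p, 3))
  print(tab)
  if (length(x$ar)) cat("AR coefficients:", round(x$ar, 3), "\n")
  invisible(x)
}

#' @export
predict.gls_ar <- function(object, newx = NULL, ...) {
  if (is.null(newx)) return(object$fitted)
  newx <- as.matrix(newx)
  b <- object$coefficients
  vars <- setdiff(names(b), "(intercept)")
  if (!all(vars %in% colnames(newx))) {
    stop("newx is missing column(s): ",
         paste(setdiff(vars, colnames(newx)), collapse = ", "))
  }
  as.numeric(b["(intercept)"] + newx[, vars, drop = FALSE] %*% b[vars])
}

#' 95% confidence intervals for GLS coefficients
#'
#' @param object A [fit_gls_ar()] fit.
#' @param parm Coefficients to report (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix of lower/upper bounds.
#' @export
confint.gls_ar <- function(object, parm = NULL, level = 0.95, ...) {
  b <- object$coefficients
  if (is.null(parm)) parm <- names(b)
  q <- stats::qt(1 - (1 - level) / 2, object$df)
  cbind(lower = b[parm] - q * object$se[parm],
        upper = b[parm] + q * object$se[parm])
}

#' Goodness-of-fit metrics for concentration predictions
#'
#' `R2 = 1 - SSE/SST`, RMSE in log10 units, and (when whitened residuals
#' are supplied) the Durbin-Watson statistic
#' `sum(diff(e)^2) / sum(e^2)`, which is near 2 when the AR error model has
#' absorbed the serial correlation.
#'
#' @param observed,predicted Equal-length numeric vectors (log10 scale;
#'   below-LOD observations encoded as 0).
#' @param whitened_residuals Optional residual vector for Durbin-Watson.
#' @return List with `r2`, `rmse` and optionally `durbin_watson`.
#' @export
model_metrics <- function(observed, predicted, whitened_residuals = NULL) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) stop("length mismatch")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed series has zero variance")
  out <- list(
    r2 = 1 - sum((observed - predicted)^2) / sst,
    rmse = sqrt(mean((observed - predicted)^2))
  )
  if (!is.null(whitened_residuals)) {
    e <- as.numeric(whitened_residuals)
    out$durbin_watson <- sum(diff(e)^2) / sum(e^2)
  }
  out
}

#' Fit the full two-part hurdle model for one indicator
#'
#' The binary part (random forest, [fit_binary_forest()] +
#' [permutation_prune()]) classifies detection above the lower LOD; it is
#' skipped when the indicator was never censored. The concentration part
#' ([fit_gls_ar()] with AR(2) errors) is fit on detected samples only,
#' after iterative VIF pruning ([vif_prune_loop()]) of the design restricted
#' to those samples. Overall predictions are the product of the binary
#' class (0/1) and the concentration-part prediction, so a predicted
#' non-detect maps to log10 of the substitute value (0). Metrics are
#' in-sample: these are descriptive models of association, not forecasts.
#'
#' @param design A [build_lagged_design()] result.
#' @param seed Integer seed for the forest and permutation shuffles.
#' @param vif_threshold VIF pruning threshold (default 5).
#' @param ar_order,iterations Concentration-part error order and
#'   feasible-GLS iterations.
#' @return An object of class `hurdle_model`.
#' @export
fit_hurdle <- function(design, seed = 0, vif_threshold = 5,
                       ar_order = 2, iterations = 5) {
  stopifnot(inherits(design, "lagged_design"))
  x <- design$x
  det <- design$target_binary
  y <- design$target_conc

  binary <- fit_binary_forest(x, det, seed = seed)
  if (!is.null(binary)) {
    binary <- permutation_prune(binary, x, det, seed = seed)
  }

  x_det <- x[det, , drop = FALSE]
  pruned <- vif_prune_loop(x_det, threshold = vif_threshold)
  conc_vars <- colnames(pruned$x)
  conc <- fit_gls_ar(pruned$x, y[det], order = ar_order,
                     iterations = iterations)

  conc_pred_all <- predict(conc, newx = x[, conc_vars, drop = FALSE])
  bin_pred <- if (is.null(binary)) rep(1L, nrow(x)) else {
    as.integer(as.character(
      stats::predict(binary$forest,
                     newdata = as.data.frame(x[, binary$keep, drop = FALSE]))
    ))
  }
  overall_pred <- bin_pred * conc_pred_all

  metrics <- list(
    binary_accuracy = if (is.null(binary)) NA_real_ else binary$accuracy,
    concentration = model_metrics(y[det], conc$fitted,
                                  whitened_residuals = conc$whitened_residuals),
    overall = model_metrics(y, overall_pred)
  )

  structure(
    list(indicator = design$indicator,
         binary_part = binary,
         conc_part = conc,
         conc_vars = conc_vars,
         pruned_by_vif = pruned$removed,
         vifs = pruned$vifs,
         lags = design$lags,
         n_below_lod = sum(!det),
         metrics = metrics,
         predictions = overall_pred,
         seed = seed),
    class = "hurdle_model"
  )
}

#' @export
print.hurdle_model <- function(x, ...) {
  cat(sprintf("<hurdle_model> %s: %d below LOD of %d samples\n",
              toupper(x$indicator), x$n_below_lod, length(x$predictions)))
  if (is.null(x$binary_part)) {
    cat("  binary part: none (single detection class)\n")
  } else {
    cat(sprintf("  binary part: %d variables retained, in-sample accuracy %.3g\n",
                length(x$binary_part$keep), x$binary_part$accuracy))
  }
  cat(sprintf("  concentration part: %d variables (VIF-pruned: %s)\n",
              length(x$conc_vars),
              if (length(x$pruned_by_vif)) paste(x$pruned_by_vif, collapse = ", ")
              else "none"))
  m <- x$metrics
  cat(sprintf("  conc R2 %.3f RMSE %.3f DW %.2f | overall R2 %.3f RMSE %.3f\n",
              m$concentration$r2, m$concentration$rmse,
              m$concentration$durbin_watson, m$overall$r2, m$overall$rmse))
  invisible(x)
}

#' Predict from a fitted hurdle model
#'
#' Overall prediction = binary class (0/1) times the concentration-part
#' prediction; for an indicator with no binary part the concentration part
#' is used alone. Deterministic: predicting twice on the same design gives
#' identical output.
#'
#' @param model A [fit_hurdle()] fit.
#' @param design A `lagged_design` (or plain matrix) normalized the same
#'   way as the training design.
#' @return Numeric vector of log10 concentration predictions.
#' @export
hurdle_predict <- function(model, design) {
  stopifnot(inherits(model, "hurdle_model"))
  x <- if (inherits(design, "lagged_design")) design$x else as.matrix(design)
  need <- unique(c(model$conc_vars,
                   if (!is.null(model$binary_part)) model$binary_part$keep))
  if (!all(need %in% colnames(x))) {
    stop("design is missing variable(s): ",
         paste(setdiff(need, colnames(x)), collapse = ", "))
  }
  conc <- predict(model$conc_part, newx = x[, model$conc_vars, drop = FALSE])
  if (is.null(model$binary_part)) return(conc)
  bin <- as.integer(as.character(
    stats::predict(model$binary_part$forest,
                   newdata = as.data.frame(x[, model$binary_part$keep,
                                             drop = FALSE]))
  ))
  bin * conc
}
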