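test_that("z-scoring normalizes columns and drops constants", {
  z <- zscore_design(cbind(a = c(0, 2), b = c(5, 1)))
  expect_equal(z$x[, "a"], c(-1, 1) / sqrt(2))
  expect_equal(z$norm_params$mean[["a"]], 1)

  set.seed(51)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  z <- zscore_design(x)
  expect_true(all(abs(colMeans(z$x)) < 1e-8))
  expect_true(all(abs(apply(z$x, 2, sd) - 1) < 1e-8))
  # an already-standard column passes through
  xs <- scale(x)[, , drop = FALSE]
  expect_equal(unname(zscore_design(xs)$x), unname(xs), tolerance = 1e-12)

  expect_warning(z2 <- zscore_design(cbind(a = rnorm(10), k = rep(3, 10))),
                 "constant")
  expect_equal(colnames(z2$x), "a")
})

test_that("binary forest separates a separable toy and skips single-class targets", {
  set.seed(52)
  x <- cbind(x1 = c(rnorm(30, -2), rnorm(30, 2)))
  y <- rep(c(FALSE, TRUE), each = 30)
  fit <- fit_binary_forest(x, y, seed = 1)
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$predictions, as.integer(y))

  expect_message(out <- fit_binary_forest(x, rep(TRUE, 60), seed = 1),
                 "no binary part")
  expect_null(out)
})

test_that("forest fitting and pruning are bit-reproducible under a fixed seed", {
  set.seed(53)
  x <- matrix(rnorm(96 * 5), 96, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- x[, 1] + 0.5 * rnorm(96) > 0
  f1 <- fit_binary_forest(x, y, seed = 9)
  f2 <- fit_binary_forest(x, y, seed = 9)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$accuracy, f2$accuracy)
  p1 <- permutation_prune(f1, x, y, seed = 9)
  p2 <- permutation_prune(f2, x, y, seed = 9)
  expect_identical(p1$keep, p2$keep)
  expect_identical(p1$importances, p2$importances)
})

test_that("permutation pruning keeps informative variables and drops pure noise", {
  set.seed(54)
  n <- 120
  label <- rep(c(FALSE, TRUE), each = n / 2)
  kept_inf <- 0; dropped_noise <- 0
  for (s in 1:8) {
    x <- cbind(signal = as.numeric(label) + rnorm(n, sd = 0.1),
               noise = rnorm(n))
    fit <- fit_binary_forest(x, label, seed = s)
    pr <- permutation_prune(fit, x, label, seed = s)
    kept_inf <- kept_inf + ("signal" %in% pr$keep)
    dropped_noise <- dropped_noise + ("noise" %in% pr$removed)
  }
  expect_equal(kept_inf, 8)              # label-aligned variable always kept
  expect_gte(dropped_noise, 5)           # pure noise removed in the majority
})

test_that("VIF matches closed forms", {
  # exactly orthogonal centered columns
  X <- exact_corr_design(R = diag(3))
  expect_equal(vif(X, 1), 1, tolerance = 1e-8)

  # pairwise r = 0.5 triplet has VIF 1.5 analytically
  X5 <- exact_corr_design()
  for (j in 1:3) expect_equal(vif(X5, j), 1.5, tolerance = 1e-8)

  dup <- cbind(a = rnorm(20))
  dup <- cbind(dup, b = dup[, "a"])
  expect_equal(vif(dup, 1), Inf)
})

test_that("VIF pruning terminates below the threshold and logs removals", {
  set.seed(55)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  pr <- vif_prune_loop(x)
  expect_equal(colnames(pr$x), c("a", "b", "c"))   # all VIF < 5: identity
  expect_length(pr$removed, 0)

  xdup <- cbind(x, a2 = x[, "a"] + rnorm(100, sd = 1e-8))
  pr2 <- vif_prune_loop(xdup)
  expect_length(pr2$removed, 1)
  expect_true(pr2$removed %in% c("a", "a2"))
  expect_true(max(pr2$vifs) < 5)

  # random collinear designs: always terminates with max VIF < threshold
  for (s in 1:10) {
    set.seed(100 + s)
    base <- matrix(rnorm(80 * 3), 80, 3)
    x <- cbind(base,
               base %*% runif(3) + rnorm(80, sd = 0.1),
               base %*% runif(3) + rnorm(80, sd = 0.1))
    colnames(x) <- paste0("v", 1:5)
    pr <- vif_prune_loop(x)
    expect_true(length(pr$vifs) >= 1 && max(pr$vifs) < 5)
  }
})

test_that("order-0 GLS reproduces ordinary least squares exactly", {
  set.seed(56)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 1 + x %*% c(0.5, -0.3, 0, 0.2) + rnorm(50)
  g <- fit_gls_ar(x, y, order = 0)
  ref <- lm(y ~ x)
  expect_equal(unname(g$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(g$se), unname(coef(summary(ref))[, 2]), tolerance = 1e-10)
  expect_equal(unname(g$p), unname(coef(summary(ref))[, 4]), tolerance = 1e-10)

  # intercept-only model on centered response
  yc <- y - mean(y)
  g0 <- fit_gls_ar(NULL, yc, order = 0)
  expect_equal(unname(g0$coefficients), mean(yc), tolerance = 1e-12)
})

test_that("GLS with AR(2) errors recovers coefficients and the AR structure", {
  set.seed(57)
  n <- 3000
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  e <- as.numeric(stats::filter(rnorm(n + 200, sd = 0.5), c(0.5, 0.2),
                                method = "recursive"))[201:(n + 200)]
  y <- 2 + x %*% c(0.7, -0.4) + e
  g <- fit_gls_ar(x, y, order = 2, iterations = 5)
  expect_equal(unname(g$coefficients), c(2, 0.7, -0.4), tolerance = 0.05)
  expect_equal(g$ar, c(0.5, 0.2), tolerance = 0.06)

  # independent AR-estimation cross-check on the OLS residuals
  res <- residuals(lm(y ~ x))
  ref <- stats::ar.ols(res, order.max = 2, aic = FALSE, demean = TRUE)
  expect_equal(g$ar, as.numeric(ref$ar), tolerance = 0.02)

  # whitened residuals should pass Durbin-Watson near 2
  dw <- sum(diff(g$whitened_residuals)^2) / sum(g$whitened_residuals^2)
  expect_equal(dw, 2, tolerance = 0.1)

  # noise-free response is reproduced exactly
  y0 <- 1 + x %*% c(0.3, 0.1)
  g0 <- fit_gls_ar(x, y0, order = 2)
  expect_equal(unname(g0$coefficients), c(1, 0.3, 0.1), tolerance = 1e-8)

  dupx <- cbind(x, a2 = x[, "a"])
  expect_error(fit_gls_ar(dupx, y), "non-invertible.*a2")
})

test_that("model metrics follow their definitions", {
  obs <- c(1, 2, 3, 4)
  expect_equal(model_metrics(obs, obs), list(r2 = 1, rmse = 0))
  expect_equal(model_metrics(obs, rep(mean(obs), 4))$r2, 0)
  set.seed(58)
  e <- rnorm(500)
  expect_equal(model_metrics(e, rep(0, 500), whitened_residuals = e)$durbin_watson,
               2, tolerance = 0.15)
  expect_error(model_metrics(rep(1, 4), obs), "zero variance")
})

test_that("the hurdle combines parts multiplicatively and predicts idempotently", {
  g <- generate_event(seed = 12, truths = list(ent = synthetic_truth("ent")))
  design <- build_lagged_design(g$event, "ent")
  m <- fit_hurdle(design, seed = 3)

  p1 <- hurdle_predict(m, design)
  p2 <- hurdle_predict(m, design)
  expect_identical(p1, p2)
  expect_identical(p1, m$predictions)

  # predicted non-detects map to log10 of the substitute value (0)
  bin <- as.integer(as.character(predict(
    m$binary_part$forest,
    newdata = as.data.frame(design$x[, m$binary_part$keep, drop = FALSE]))))
  expect_true(all(p1[bin == 0] == 0))
  conc <- predict(m$conc_part, newx = design$x[, m$conc_vars, drop = FALSE])
  expect_equal(p1[bin == 1], conc[bin == 1])

  expect_true(max(m$vifs) < 5)
  expect_true(length(m$conc_part$ar) == 2)
})

test_that("an uncensored indicator gets no binary part and conc-only predictions", {
  g <- generate_event(seed = 13, truths = list(tc = synthetic_truth("tc")))
  design <- build_lagged_design(g$event, "tc")
  expect_true(all(design$target_binary))
  expect_message(m <- fit_hurdle(design, seed = 0), "no binary part")
  expect_null(m$binary_part)
  expect_true(is.na(m$metrics$binary_accuracy))
  expect_equal(hurdle_predict(m, design),
               predict(m$conc_part, newx = design$x[, m$conc_vars, drop = FALSE]))
})
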