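test_that("OLS recovers exact coefficients and matches the normal equations", {
  d <- short_design("informed")
  p <- ncol(d$X)
  set.seed(10)
  b <- rnorm(p)
  y <- as.numeric(d$X %*% b)
  fit <- fit_ols(y, d)
  expect_equal(unname(fit$betas[, 1]), b, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # random 30-scan problem against an explicit pseudoinverse oracle
  X <- cbind(1, matrix(rnorm(30 * 3), 30, 3))
  colnames(X) <- c("constant", "a", "b", "c")
  dd <- structure(list(X = X, tr = 1, n_scans = 30, microtime_dt = 0.1,
                       basis = "canonical", conditions = list(),
                       params = default_params), class = "design_matrix")
  y2 <- rnorm(30)
  fit2 <- fit_ols(y2, dd)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% y2
  expect_equal(unname(fit2$betas[, 1]), as.numeric(oracle), tolerance = 1e-9)
  expect_equal(fit2$df, 30 - 4)
  res <- y2 - X %*% oracle
  expect_equal(unname(fit2$residual_variance), sum(res^2) / 26,
               tolerance = 1e-9)
})

test_that("data orthogonal to all regressors yields null fit", {
  d <- short_design("canonical")
  set.seed(11)
  y <- rnorm(short_n)
  y <- qr.resid(qr(d$X), y)
  fit <- fit_ols(y, d)
  expect_lt(abs(fit$betas[1, 1]), 1e-10)
  expect_lt(fit$r_squared, 1e-10)
})

test_that("OLS validates rank and finiteness", {
  d <- short_design("canonical")
  dbad <- d; dbad$X <- cbind(d$X, d$X[, 1])
  expect_error(fit_ols(rnorm(short_n), dbad), "rank")
  ybad <- rnorm(short_n); ybad[5] <- NA
  expect_error(fit_ols(ybad, d), "finite")
})

test_that("t-statistic matches the explicit covariance oracle", {
  d <- short_design("informed")
  set.seed(12)
  y <- as.numeric(d$X %*% rnorm(ncol(d$X))) + rnorm(short_n)
  fit <- fit_ols(y, d)
  w <- canonical_weights(d)
  got <- t_statistic(fit, w)
  X <- d$X
  sigma2 <- sum(qr.resid(qr(X), y)^2) / (short_n - ncol(X))
  co <- solve(t(X) %*% X)
  oracle <- as.numeric(t(w) %*% qr.coef(qr(X), y)) /
    sqrt(sigma2 * as.numeric(t(w) %*% co %*% w))
  expect_equal(got$t[1], oracle, tolerance = 1e-8)
  expect_equal(got$df, short_n - ncol(X))

  expect_equal(t_statistic(fit, numeric(ncol(X)))$t, 0)
})

test_that("zero residual variance produces an infinite-T sentinel with warning", {
  d <- short_design("canonical")
  y <- as.numeric(d$X %*% c(1, 0.5))
  fit <- fit_ols(y, d)
  expect_warning(ts <- t_statistic(fit, c(1, 0)), "zero residual")
  expect_identical(ts$t[1], Inf)
})

test_that("informed basis set improves T on shifted data (mean over seeds)", {
  d_can <- short_design("canonical")
  d_inf <- short_design("informed")
  tt <- vapply(1:20, function(s) {
    y <- simulate_voxel_series(voxel_sim_spec(
      shift = 2, noise_sd = 0.5, seed = 300 + s, n_scans = short_n,
      tr = short_tr, events = short_events))$series
    c(t_statistic(fit_ols(y, d_can), canonical_weights(d_can))$t,
      t_statistic(fit_ols(y, d_inf), canonical_weights(d_inf))$t)
  }, numeric(2))
  expect_gt(mean(tt[2, ]), mean(tt[1, ]))
})

test_that("contrast images are linear in weights and tagged", {
  ev_a <- event_timeline(seq(0, 160, by = 40), 10, condition = "a")
  ev_b <- event_timeline(seq(20, 180, by = 40), 10, condition = "b")
  d <- build_design(list(ev_a, ev_b), short_tr, short_n, "canonical",
                    default_params)
  set.seed(13)
  Y <- matrix(rnorm(short_n * 5), short_n, 5)
  fit <- fit_ols(Y, d)
  wa <- canonical_weights(d, "a")
  ci <- contrast_image(fit, wa, "canonical")
  expect_equal(ci$values, unname(fit$betas[1, ]))
  wab <- canonical_weights(d, c("a", "b"), c(1, -1))
  expect_equal(contrast_image(fit, wab)$values,
               unname(fit$betas[1, ] - fit$betas[d$conditions$b$canonical, ]))
  expect_equal(contrast_image(fit, 3 * wab)$values,
               3 * contrast_image(fit, wab)$values)
  expect_identical(ci$model_tag, "canonical")
})

test_that("shift-grid pattern: canonical fit peaks at zero shift; beta1 unchanged by the derivative", {
  d_can <- short_design("canonical")
  d_inf <- short_design("informed")
  shifts <- seq(-2, 2, by = 0.5)
  res <- vapply(shifts, function(sh) {
    y <- simulate_voxel_series(voxel_sim_spec(
      shift = sh, noise_sd = 0, n_scans = short_n, tr = short_tr,
      events = short_events))$series
    fc <- fit_ols(y, d_can); fi <- fit_ols(y, d_inf)
    c(b_can = fc$betas[1, 1], r2_can = fc$r_squared,
      b_inf = fi$betas[1, 1], r2_inf = fi$r_squared)
  }, c(b_can = 0, r2_can = 0, b_inf = 0, r2_inf = 0))
  i0 <- which(shifts == 0)
  # beta1 and R^2 maximal at zero shift, decreasing with |shift|
  expect_true(all(res["b_can", -i0] < res["b_can", i0]))
  expect_true(all(diff(res["r2_can", 1:i0]) > 0))
  expect_true(all(diff(res["r2_can", i0:length(shifts)]) < 0))
  # adding the orthogonalized derivative never decreases R^2 ...
  expect_true(all(res["r2_inf", ] >= res["r2_can", ] - 1e-12))
  # ... and leaves beta1 untouched
  expect_equal(res["b_inf", ], res["b_can", ], tolerance = 1e-8)
})
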