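test_that("boost amplitude: 3-4-5 arithmetic, sign carrying, degenerate beta1", {
  expect_equal(as.numeric(boost_amplitude(3, 0, 1, 1)), 3)
  expect_equal(as.numeric(boost_amplitude(3, 4, 1, 1)), 5)
  expect_equal(as.numeric(boost_amplitude(-3, 4, 1, 1)), -5)

  H <- boost_amplitude(c(0, 2), c(5, 0), 1, 1)
  expect_equal(as.numeric(H), c(0, 2))
  expect_identical(attr(H, "n_sentinel"), 1L)

  expect_error(boost_amplitude(1, 1, 0, 1), "sums of squares")
})

test_that("H dominates |beta1| and is invariant to derivative rescaling", {
  set.seed(20)
  b1 <- rnorm(200); b2 <- rnorm(200)
  ssq1 <- 103; ssq2 <- 4.4
  H <- as.numeric(boost_amplitude(b1, b2, ssq1, ssq2))
  expect_true(all(abs(H) >= abs(b1) * sqrt(ssq1) - 1e-12))
  expect_true(all(sign(H[b1 != 0]) == sign(b1[b1 != 0])))

  # rescale the derivative basis by c: beta2 -> beta2 / c, ssq2 -> c^2 ssq2
  for (cc in c(0.1, 2, 17)) {
    H2 <- as.numeric(boost_amplitude(b1, b2 / cc, ssq1, cc^2 * ssq2))
    expect_equal(H2, H, tolerance = 1e-12)
  }
})

test_that("time-to-peak: canonical response peaks at 5 s; shifted projections follow the oracle", {
  expect_equal(time_to_peak(1, 0), 5, tolerance = 0.05)
  expect_equal(time_to_peak(2.5, 0), 5, tolerance = 0.05)

  # oracle: brute-force argmax of the least-squares reconstruction of a
  # shifted kernel on a 0.01 s grid (independent of time_to_peak internals)
  basis <- informed_basis(default_params)
  oracle_ttp <- function(delta) {
    co <- project_on_basis(shifted_hrf(default_params, delta)$values, basis)
    tt <- seq(0, 32, by = 0.01)
    sc <- attr(basis$canonical, "scale")
    f1 <- hrfboost:::double_gamma(tt, default_params) * sc
    d_grid <- hrfboost:::double_gamma_deriv(basis$canonical$times,
                                            default_params) * sc
    f2 <- hrfboost:::double_gamma_deriv(tt, default_params) * sc *
      diff(range(basis$derivative$values)) / diff(range(d_grid))
    tt[which.max(co[1] * f1 + co[2] * f2)]
  }
  for (delta in c(-1, -0.5, 0.5, 1)) {
    co <- project_on_basis(shifted_hrf(default_params, delta)$values, basis)
    expect_equal(time_to_peak(co[1], co[2]), oracle_ttp(delta),
                 tolerance = 0.06)
  }
  # frozen oracle values: the -1 s shift is recovered exactly, the +1 s
  # reconstruction peak is compressed to ~5.75 s (see vignette)
  co_m <- project_on_basis(shifted_hrf(default_params, -1)$values, basis)
  co_p <- project_on_basis(shifted_hrf(default_params, +1)$values, basis)
  expect_equal(time_to_peak(co_m[1], co_m[2]), 4.0, tolerance = 0.1)
  expect_equal(time_to_peak(co_p[1], co_p[2]), 5.75, tolerance = 0.1)

  # deactivations take the mirrored response's peak
  expect_equal(time_to_peak(-co_m[1], -co_m[2]), 4.0, tolerance = 0.1)
  expect_true(is.na(time_to_peak(0, 1)))
  expect_error(time_to_peak(NaN, 1), "finite")
})

test_that("temporal-range masks behave as set operations", {
  ttp <- c(5, 5, 5)
  expect_true(all(build_mask(ttp, c(4, 6))))
  ttp2 <- c(3.2, 4.5, 5, 6.8, NA, 10)
  m_con <- build_mask(ttp2, ttp_range("boost_constrained"))
  m_full <- build_mask(ttp2, ttp_range("boost_full"))
  expect_true(all(m_full[m_con]))          # constrained subset of full
  expect_false(m_con[5]); expect_false(m_full[5])  # NA policy
  expect_error(build_mask(ttp2, c(6, 4)), "low < high")
})

test_that("boosted contrast: no-op outside the mask, exact at zero shift, recovers shifted amplitude", {
  d <- short_design("informed")
  w <- canonical_weights(d)
  A <- 2.4

  y0 <- simulate_voxel_series(voxel_sim_spec(
    shift = 0, amplitude = A, noise_sd = 0, n_scans = short_n,
    tr = short_tr, events = short_events))$series
  fit0 <- fit_ols(y0, d)
  plain <- contrast_image(fit0, w)$values
  out_of_range <- boosted_contrast(fit0, w, range = c(20, 25))
  expect_equal(out_of_range$contrast$values, plain, tolerance = 1e-12)
  expect_false(any(out_of_range$boost$mask))

  b0 <- boosted_contrast(fit0, w, ttp_range("boost_constrained"))
  expect_equal(b0$contrast$values, plain, tolerance = 1e-6)
  expect_equal(b0$contrast$values[1], A, tolerance = 1e-6)

  y1 <- simulate_voxel_series(voxel_sim_spec(
    shift = 1, amplitude = A, noise_sd = 0, n_scans = short_n,
    tr = short_tr, events = short_events))$series
  fit1 <- fit_ols(y1, d)
  unboosted <- contrast_image(fit1, w)$values[1]
  boosted <- boosted_contrast(fit1, w,
                              ttp_range("boost_constrained"))$contrast$values[1]
  expect_lt(unboosted, A)                  # canonical-only underestimates
  expect_equal(boosted, A, tolerance = 0.05 * A)
  expect_gt(boosted, unboosted)

  expect_error(boosted_contrast(fit_ols(y1, short_design("canonical")), c(1, 0),
                                c(4, 6)), "informed")
})

test_that("boosting reduces amplitude error on a latency-heterogeneous noiseless cohort", {
  d <- short_design("informed")
  w <- canonical_weights(d)
  lat <- seq(-1, 1, by = 0.25)
  A <- 1
  err <- vapply(lat, function(dl) {
    y <- simulate_voxel_series(voxel_sim_spec(
      shift = dl, amplitude = A, noise_sd = 0, n_scans = short_n,
      tr = short_tr, events = short_events))$series
    fit <- fit_ols(y, d)
    c(abs(contrast_image(fit, w)$values[1] - A),
      abs(boosted_contrast(fit, w, c(4, 6))$contrast$values[1] - A))
  }, numeric(2))
  expect_lt(mean(err[2, ]), mean(err[1, ]))
})
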