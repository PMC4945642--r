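test_that("noiseless unshifted voxel is fit perfectly by the canonical model", {
  sp <- voxel_sim_spec(shift = 0, amplitude = 1.7, noise_sd = 0,
                       n_scans = short_n, tr = short_tr,
                       events = short_events)
  y <- simulate_voxel_series(sp)$series
  fit <- fit_ols(y, short_design("canonical"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$betas[1, 1]), 1.7, tolerance = 1e-8)
})

test_that("a 2 s shift degrades the canonical fit; the derivative restores it", {
  sp <- voxel_sim_spec(shift = 2, noise_sd = 0, n_scans = short_n,
                       tr = short_tr, events = short_events)
  y <- simulate_voxel_series(sp)$series
  r2_can <- fit_ols(y, short_design("canonical"))$r_squared
  r2_inf <- fit_ols(y, short_design("informed"))$r_squared
  expect_lt(r2_can, 1 - 0.05)
  expect_gt(r2_inf, 1 - 0.02)
})

test_that("voxel simulation is a pure function of its spec", {
  sp <- voxel_sim_spec(shift = 1, noise_sd = 0.5, seed = 99,
                       n_scans = 100, tr = 0.5,
                       events = periodic_events(total_duration = 50))
  expect_identical(simulate_voxel_series(sp)$series,
                   simulate_voxel_series(sp)$series)
  sp2 <- sp; sp2$seed <- 100L
  expect_false(identical(simulate_voxel_series(sp)$series,
                         simulate_voxel_series(sp2)$series))
})

test_that("degenerate cohort recovers the imposed latency voxelwise", {
  sp <- tiny_cohort_spec(n_subjects = 3, latency_mean = 1, latency_sd = 0,
                         amplitude_sd = 0, noise_sd = 0)
  co <- simulate_cohort(sp)
  expect_equal(co$truth$latency_s, rep(1, 3))
  d <- build_design(co$design_args$events, co$design_args$tr,
                    co$design_args$n_scans, "informed", default_params)
  fit <- fit_ols(co$subjects[[1]], d)
  act <- which(as.vector(sp$active_mask))
  ttp <- time_to_peak(fit$betas[1, act], fit$betas[2, act])
  # fitted peak time tracks 5 s + latency (basis reconstruction compresses
  # late shifts slightly; see the methods vignette)
  expect_true(all(abs(ttp - 6) <= 0.35))
  expect_equal(stats::median(ttp), 6, tolerance = 0.35)
})

test_that("cohort simulation validates its mask and reproduces under a seed", {
  expect_error(cohort_spec(active_mask = array(FALSE, c(10, 10, 8)),
                           volume_shape = c(10, 10, 8)), "no voxels")
  sp <- tiny_cohort_spec(n_subjects = 2)
  a <- simulate_cohort(sp); b <- simulate_cohort(sp)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
})

test_that("group mean of canonical contrasts matches the projection-attenuation oracle", {
  # latency-heterogeneous, noise across subjects, no smoothing so that the
  # oracle applies exactly at active voxels
  n_cohorts <- 40
  lat_m <- 0.75; lat_sd <- 0.5; amp_m <- 1
  d_can <- build_design(periodic_events(total_duration = 200), 2, 100,
                        "canonical", default_params)
  # oracle: attenuation a(delta) = lm coefficient of the shifted regressor
  # on the canonical design column, averaged over the latency distribution
  u <- boxcar(periodic_events(total_duration = 200),
              default_params$microtime_dt, 200 + 32)
  atten <- function(delta) {
    xs <- convolve_to_scans(u, shifted_hrf(default_params, delta), 2, 100,
                            default_params$microtime_dt)
    unname(coef(lm(xs ~ 0 + d_can$X[, 1] + d_can$X[, 2]))[1])
  }
  set.seed(123)
  lat_draws <- hrfboost:::rtruncnorm_pm2(4000, lat_m, lat_sd)
  theo <- amp_m * mean(vapply(lat_draws, atten, numeric(1)))

  means <- vapply(seq_len(n_cohorts), function(r) {
    sp <- cohort_spec(n_subjects = 8, volume_shape = c(6, 6, 6),
                      active_mask = default_active_mask(c(6, 6, 6), 2),
                      latency_mean = lat_m, latency_sd = lat_sd,
                      amplitude_mean = amp_m, amplitude_sd = 0.2,
                      noise_sd = 0.5, smoothing_fwhm = 0, seed = 5000 + r,
                      events = periodic_events(total_duration = 200),
                      tr = 2, n_scans = 100)
    co <- simulate_cohort(sp)
    fl <- lapply(co$subjects, function(Y) fit_ols(Y, d_can))
    M <- vapply(fl, function(f) f$betas[1, ], numeric(prod(sp$volume_shape)))
    mean(rowMeans(M)[as.vector(sp$active_mask)])
  }, numeric(1))
  se <- sd(means) / sqrt(n_cohorts)
  expect_lt(abs(mean(means) - theo), 3 * se)
})

test_that("smooth field generator matches its closed-form autocorrelation", {
  f0 <- simulate_smooth_field(c(40, 40, 40), 1, 0, seed = 2)
  r0 <- mean(f0[-40, , ] * f0[-1, , ])
  expect_lt(abs(r0), 3 / sqrt(39 * 40 * 40))

  f <- simulate_smooth_field(c(48, 48, 48), 3, 8, seed = 3)
  expect_equal(var(as.numeric(f)), 1, tolerance = 0.02)
  r1 <- mean(f[-48, , ] * f[-1, , ])
  # ACF of Gaussian-smoothed white noise at lag d: exp(-2 ln2 d^2 / fwhm^2)
  expect_equal(r1, exp(-2 * log(2) * 9 / 64), tolerance = 0.02)
})

test_that("cohort presets are configuration only", {
  ch <- cohort_preset("child", volume_shape = c(8, 8, 6))
  ad <- cohort_preset("adult", volume_shape = c(8, 8, 6))
  expect_s3_class(ch, "cohort_spec")
  expect_gt(ch$latency_mean, ad$latency_mean)
  expect_gt(ch$latency_sd, ad$latency_sd)
  expect_identical(ch$volume_shape, c(8L, 8L, 6L))
})
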