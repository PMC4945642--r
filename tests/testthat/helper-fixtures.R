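# Shared fixtures: all built in code at test time.

default_params <- hrf_parameters()

# short slow event-related run: 10 s on / 10 s off over 200 s, 0.5 s sampling
short_events <- periodic_events(total_duration = 200)
short_tr <- 0.5
short_n <- 400

short_design <- function(basis = "informed") {
  build_design(short_events, short_tr, short_n, basis, default_params)
}

# tiny cohort used by several module tests; small enough to simulate in ~1 s
tiny_cohort_spec <- function(...) {
  args <- modifyList(
    list(n_subjects = 6, volume_shape = c(10, 10, 8), voxel_size = 3,
         noise_sd = 2, smoothing_fwhm = 8, n_scans = 100, tr = 2,
         events = periodic_events(total_duration = 200), seed = 11),
    list(...))
  do.call(cohort_spec, args)
}

# independent projection oracle: least-squares coefficients of a sampled
# kernel on the two basis kernels, via base qr (not fit_ols)
project_on_basis <- function(kernel_values, basis = informed_basis()) {
  B <- cbind(basis$canonical$values, basis$derivative$values)
  qr.coef(qr(B), kernel_values)
}
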