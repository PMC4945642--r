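#' Hemodynamic response function parameters
#'
#' Parameter set for the canonical double-gamma HRF: the positive response is
#' a gamma density peaking at `(peak_delay - peak_dispersion)` s for unit
#' dispersion, the undershoot a later gamma density subtracted after scaling
#' by `1/undershoot_ratio`... more precisely the kernel is
#' \deqn{h(t) = g(t; \alpha_1, b_1) - g(t; \alpha_2, b_2)/r}
#' with gamma densities parameterized so that `peak_delay` and
#' `undershoot_delay` are the delay parameters (shape = delay/dispersion,
#' scale = dispersion) and `r = undershoot_ratio^{-1}`... The defaults
#' (delays 6 and 16 s, dispersions 1 s, ratio 1/6, 32 s support) are the
#' de-facto standard double-gamma used by the major analysis suites; the
#' resulting kernel peaks 5 s after stimulus onset.
#'
#' @param peak_delay delay of the positive response, seconds.
#' @param undershoot_delay delay of the undershoot, seconds.
#' @param peak_dispersion dispersion (gamma scale) of the response, seconds.
#' @param undershoot_dispersion dispersion of the undershoot, seconds.
#' @param undershoot_ratio relative amplitude of the undershoot (the
#'   undershoot density is divided by `1/undershoot_ratio`; default 1/6).
#' @param kernel_length support of the sampled kernel, seconds.
#' @param microtime_dt microtime resolution, seconds; must be at most 0.5 s
#'   so that the 0.5 s simulation grid is representable.
#' @return An object of class `hrf_parameters`.
#' @export
hrf_parameters <- function(peak_delay = 6, undershoot_delay = 16,
                           peak_dispersion = 1, undershoot_dispersion = 1,
                           undershoot_ratio = 1 / 6,
                           kernel_length = 32, microtime_dt = 0.1) {
  vals <- c(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            undershoot_ratio = undershoot_ratio,
            kernel_length = kernel_length, microtime_dt = microtime_dt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all HRF parameters must be finite and strictly positive")
  if (microtime_dt > 0.5)
    stop("microtime_dt must be <= 0.5 s")
  structure(as.list(vals), class = "hrf_parameters")
}

#' @export
print.hrf_parameters <- function(x, ...) {
  cat("double-gamma HRF parameters:\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

as_hrf_parameters <- function(params) {
  if (inherits(params, "hrf_parameters")) return(params)
  do.call(hrf_parameters, as.list(params))
}

## closed-form double gamma density difference, un-normalized
double_gamma <- function(t, params) {
  p <- params
  a1 <- p$peak_delay / p$peak_dispersion
  a2 <- p$undershoot_delay / p$undershoot_dispersion
  stats::dgamma(t, shape = a1, scale = p$peak_dispersion) -
    stats::dgamma(t, shape = a2, scale = p$undershoot_dispersion) *
      p$undershoot_ratio
}

## analytic time derivative of double_gamma:
## d/dt g(t; a, s) = g(t; a, s) * ((a - 1)/t - 1/s), with the t = 0 limit 0
## for shapes > 1
double_gamma_deriv <- function(t, params) {
  p <- params
  a1 <- p$peak_delay / p$peak_dispersion
  a2 <- p$undershoot_delay / p$undershoot_dispersion
  g1 <- stats::dgamma(t, shape = a1, scale = p$peak_dispersion)
  g2 <- stats::dgamma(t, shape = a2, scale = p$undershoot_dispersion)
  tt <- ifelse(t > 0, t, Inf)   # limit at origin is 0 for shape > 1
  g1 * ((a1 - 1) / tt - 1 / p$peak_dispersion) -
    p$undershoot_ratio * g2 * ((a2 - 1) / tt - 1 / p$undershoot_dispersion)
}

new_kernel <- function(times, values, kind, params) {
  if (any(!is.finite(values))) stop("kernel values must be finite")
  structure(list(times = times, values = values, kind = kind,
                 params = params),
            class = "sampled_kernel")
}

#' @export
print.sampled_kernel <- function(x, ...) {
  cat(sprintf("sampled_kernel [%s]: %d samples, dt = %g s, peak %.3f at %g s\n",
              x$kind, length(x$times), x$times[2] - x$times[1],
              max(x$values), x$times[which.max(x$values)]))
  invisible(x)
}

microtime_grid <- function(params) {
  seq(0, params$kernel_length, by = params$microtime_dt)
}

#' Canonical double-gamma HRF
#'
#' Samples the canonical HRF on the microtime grid `[0, kernel_length]` and
#' scales it to unit peak, so that a regression coefficient on a regressor
#' built from this kernel is directly interpretable as response amplitude in
#' signal units.
#'
#' @param params an [hrf_parameters()] object (defaults used when missing).
#' @return A `sampled_kernel` with `kind = "canonical"`. The attribute
#'   `"scale"` records the factor applied to the raw density difference; the
#'   generating parameters travel with the kernel.
#' @examples
#' h <- canonical_hrf()
#' h$times[which.max(h$values)]   # 5 s
#' @export
canonical_hrf <- function(params = hrf_parameters()) {
  params <- as_hrf_parameters(params)
  tt <- microtime_grid(params)
  v <- double_gamma(tt, params)
  sc <- 1 / max(v)
  k <- new_kernel(tt, v * sc, "canonical", params)
  attr(k, "scale") <- sc
  k
}

#' First temporal derivative basis function
#'
#' Computes the temporal-derivative basis analytically from the gamma closed
#' form (no finite-difference grid dependence), inherits the canonical
#' kernel's unit-peak scale factor, then rescales so its peak-to-peak
#' amplitude matches the conventional 1 s finite-difference construction
#' `h(t) - h(t - 1)`. The result has a positive lobe before the canonical
#' peak and a negative lobe after it, so that `canonical - delta * derivative`
#' is the first-order approximation of the canonical HRF delayed by `delta`.
#'
#' @param kernel the canonical `sampled_kernel` the derivative accompanies.
#' @param params HRF parameters; defaults to the kernel's own.
#' @return A `sampled_kernel` with `kind = "derivative"` on the same grid.
#' @export
temporal_derivative <- function(kernel, params = kernel$params) {
  params <- as_hrf_parameters(params)
  if (!isTRUE(all.equal(kernel$times, microtime_grid(params))))
    stop("kernel grid does not match the parameter microtime grid")
  tt <- kernel$times
  sc <- attr(kernel, "scale")
  if (is.null(sc)) sc <- 1 / max(double_gamma(tt, params))
  d_raw <- double_gamma_deriv(tt, params) * sc
  ## finite-difference reference: (h(t) - h(t - 1 s)) / 1 s, zero-padded
  h <- double_gamma(tt, params) * sc
  lag <- round(1 / params$microtime_dt)
  h_lag <- c(rep(0, lag), h[seq_len(length(h) - lag)])
  fd <- h - h_lag
  d <- d_raw * (diff(range(fd)) / diff(range(d_raw)))
  k <- new_kernel(tt, d, "derivative", params)
  attr(k, "scale") <- sc
  k
}

#' Latency-shifted canonical HRF
#'
#' Translates the canonical HRF by `delta` seconds on the microtime grid
#' (positive `delta` = later peak), rounding `delta` to the nearest microtime
#' step and zero-padding at the grid edge. At the default 0.1 s microtime
#' resolution the simulation shift grid (-2..2 s in 0.5 s steps) is exact.
#'
#' @param params HRF parameters.
#' @param delta latency shift in seconds; |delta| must be at most 4 s.
#' @return A `sampled_kernel` with `kind = "shifted"`; the realized shift is
#'   stored in the `"delta"` attribute.
#' @export
shifted_hrf <- function(params = hrf_parameters(), delta = 0) {
  params <- as_hrf_parameters(params)
  if (!is.finite(delta) || abs(delta) > 4)
    stop("|delta| must be <= 4 s")
  k <- canonical_hrf(params)
  n_shift <- round(delta / params$microtime_dt)
  v <- k$values
  n <- length(v)
  if (n_shift > 0) {
    v <- c(rep(0, n_shift), v[seq_len(n - n_shift)])
  } else if (n_shift < 0) {
    v <- c(v[(-n_shift + 1):n], rep(0, -n_shift))
  }
  out <- new_kernel(k$times, v, if (n_shift == 0) "canonical" else "shifted",
                    params)
  attr(out, "scale") <- attr(k, "scale")
  attr(out, "delta") <- n_shift * params$microtime_dt
  out
}

#' Informed basis set
#'
#' The K = 2 basis set: canonical HRF plus its first temporal derivative,
#' sampled on a common microtime grid.
#'
#' @param params HRF parameters.
#' @return List with elements `canonical` and `derivative`.
#' @export
informed_basis <- function(params = hrf_parameters()) {
  h <- canonical_hrf(params)
  list(canonical = h, derivative = temporal_derivative(h))
}

#' Write / read a sampled kernel as two-column delimited text
#'
#' @param kernel a `sampled_kernel`.
#' @param path file path.
#' @return `write_kernel_tsv` returns `path` invisibly; `read_kernel_tsv`
#'   returns a `sampled_kernel` with `kind = "imported"` (parameters are not
#'   recoverable from the samples and are left NULL).
#' @export
write_kernel_tsv <- function(kernel, path) {
  df <- data.frame(time_s = kernel$times, value = kernel$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  dt <- unique(round(diff(df$time_s), 10))
  if (length(dt) != 1L || dt <= 0)
    stop("kernel times must be a uniform strictly increasing grid")
  new_kernel(df$time_s, df$value, "imported", NULL)
}
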