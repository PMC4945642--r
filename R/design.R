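#' Event timeline
#'
#' A set of events (onset, duration, amplitude) for one condition, the
#' stimulus function u(t) of the convolution model.
#'
#' @param onsets event onsets, seconds, non-negative.
#' @param durations event durations, seconds (recycled if scalar).
#' @param amplitudes event amplitudes (recycled if scalar; default 1).
#' @param condition condition label.
#' @return An object of class `event_timeline`.
#' @export
event_timeline <- function(onsets, durations, amplitudes = 1,
                           condition = "task") {
  n <- length(onsets)
  durations <- rep_len(durations, n)
  amplitudes <- rep_len(amplitudes, n)
  if (n == 0) {
    return(structure(list(onsets = numeric(0), durations = numeric(0),
                          amplitudes = numeric(0), condition = condition),
                     class = "event_timeline"))
  }
  if (any(onsets < 0) || is.unsorted(onsets))
    stop("onsets must be non-negative and sorted")
  if (any(durations < 0)) stop("durations must be >= 0")
  structure(list(onsets = onsets, durations = durations,
                 amplitudes = amplitudes, condition = condition),
            class = "event_timeline")
}

#' Periodic event train
#'
#' Events of length `on` seconds alternating with `off` seconds of rest,
#' starting at t = 0. The defaults (10 s on, 10 s off) give one event
#' presentation every 20 s, i.e. a 0.05 Hz slow event-related design.
#'
#' @param on event duration, seconds.
#' @param off rest duration, seconds.
#' @param total_duration total run length, seconds.
#' @param amplitude event amplitude.
#' @param condition condition label.
#' @return An `event_timeline`.
#' @export
periodic_events <- function(on = 10, off = 10, total_duration = 400,
                            amplitude = 1, condition = "task") {
  onsets <- seq(0, total_duration - on, by = on + off)
  event_timeline(onsets, on, amplitude, condition)
}

#' Event presentation rate of a timeline
#'
#' @param events an `event_timeline` with at least two events.
#' @return Presentation rate in Hz (reciprocal of the mean inter-onset
#'   interval).
#' @export
event_rate <- function(events) {
  if (length(events$onsets) < 2) stop("need at least two events")
  1 / mean(diff(events$onsets))
}

#' Read / write BIDS-style events.tsv
#'
#' Tab-separated file with columns `onset`, `duration`, `trial_type` and an
#' optional `amplitude` column defaulting to 1.
#'
#' @param path file path.
#' @return `read_events_tsv` returns a list of `event_timeline`, one per
#'   `trial_type`.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("onset", "duration")
  if (!all(need %in% names(df)))
    stop("events.tsv must contain columns onset and duration")
  if (is.null(df$trial_type)) df$trial_type <- "task"
  if (is.null(df$amplitude)) df$amplitude <- 1
  df <- df[order(df$onset), ]
  lapply(split(df, df$trial_type), function(g)
    event_timeline(g$onset, g$duration, g$amplitude, g$trial_type[1]))
}

#' @rdname read_events_tsv
#' @param events an `event_timeline` or list of them.
#' @export
write_events_tsv <- function(events, path) {
  if (inherits(events, "event_timeline")) events <- list(events)
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(onset = e$onsets, duration = e$durations,
               trial_type = e$condition, amplitude = e$amplitudes)))
  df <- df[order(df$onset), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stimulus boxcar at microtime resolution
#'
#' @param events an `event_timeline`.
#' @param dt sampling step, seconds.
#' @param total_duration series length, seconds (must cover all events).
#' @return Numeric vector of length `ceiling(total_duration / dt)`; samples
#'   inside an event carry its amplitude, others 0.
#' @export
boxcar <- function(events, dt, total_duration) {
  n <- ceiling(total_duration / dt)
  u <- numeric(n)
  ev <- events
  if (length(ev$onsets) == 0) return(u)
  if (max(ev$onsets + ev$durations) > total_duration)
    stop("total_duration does not cover all events")
  ends <- ev$onsets + ev$durations
  if (length(ev$onsets) > 1 &&
      any(ev$onsets[-1] < ends[-length(ends)] - 1e-9))
    stop("overlapping events within one condition")
  tt <- (seq_len(n) - 1) * dt
  for (i in seq_along(ev$onsets)) {
    idx <- tt >= ev$onsets[i] - 1e-9 & tt < ends[i] - 1e-9
    u[idx] <- ev$amplitudes[i]
  }
  u
}

#' Convolve a stimulus series with a kernel and sample at scan times
#'
#' Discrete convolution at microtime resolution (`sum u(s) k(t - s) `; the
#' kernel is treated as a sampled impulse response, no dt weighting so that
#' a unit-amplitude sustained stimulus asymptotes at `sum(k)`), then sampled
#' at acquisition times `t = scan_index * tr` (0-based).
#'
#' @param u stimulus series at microtime resolution.
#' @param kernel a `sampled_kernel` sharing the stimulus dt.
#' @param tr repetition time, seconds.
#' @param n_scans number of scans.
#' @param dt microtime step of `u`, seconds; defaults to the kernel grid step.
#' @return Regressor values at scan resolution, length `n_scans`.
#' @export
convolve_to_scans <- function(u, kernel, tr, n_scans,
                              dt = kernel$times[2] - kernel$times[1]) {
  kdt <- kernel$times[2] - kernel$times[1]
  if (abs(kdt - dt) > 1e-9)
    stop("stimulus and kernel microtime steps differ")
  conv <- stats::convolve(u, rev(kernel$values), type = "open")
  conv <- conv[seq_along(u)]
  idx <- round((seq_len(n_scans) - 1) * tr / dt) + 1
  if (max(idx) > length(conv))
    stop("scan grid extends beyond the stimulus series")
  conv[idx]
}

#' Orthogonalize one regressor against another
#'
#' Removes from `x2` its projection onto `x1`, so that the canonical
#' regression coefficient keeps its interpretation when the derivative
#' regressor is added.
#'
#' @param x2 regressor to orthogonalize.
#' @param x1 reference regressor (nonzero norm).
#' @return `x2 - (<x2,x1>/<x1,x1>) x1`.
#' @export
orthogonalize <- function(x2, x1) {
  n1 <- sum(x1^2)
  if (n1 <= 0) stop("cannot orthogonalize against a zero-norm regressor")
  x2 - as.numeric(crossprod(x2, x1) / n1) * x1
}

#' Discrete-cosine drift basis
#'
#' High-pass nuisance set: a constant column plus DCT columns whose periods
#' exceed `cutoff` seconds (the conventional high-pass filter, default
#' cutoff 128 s).
#'
#' @param n_scans number of scans.
#' @param tr repetition time, seconds.
#' @param cutoff cutoff period, seconds; must exceed `2 * tr`. `Inf` yields
#'   the constant column only.
#' @return Matrix `n_scans x (1 + K)` with columns `constant`, `dct1`, ...;
#'   columns are mutually orthogonal with unit norm (constant scaled).
#' @export
drift_basis <- function(n_scans, tr, cutoff = 128) {
  if (cutoff <= 2 * tr) stop("cutoff must exceed 2 * tr")
  # components k = 1..K have period 2*N*tr/k; keep strictly slower than cutoff
  K <- if (is.finite(cutoff)) max(0, ceiling(2 * n_scans * tr / cutoff) - 1)
       else 0
  t0 <- seq_len(n_scans) - 1
  out <- matrix(1 / sqrt(n_scans), n_scans, 1 + K)
  if (K > 0) {
    for (k in seq_len(K))
      out[, k + 1] <- sqrt(2 / n_scans) *
        cos(pi * (2 * t0 + 1) * k / (2 * n_scans))
  }
  colnames(out) <- c("constant", if (K > 0) paste0("dct", seq_len(K)))
  out
}

#' Build a first-level design matrix
#'
#' Per condition, the canonical regressor comes first; under the informed
#' basis the derivative regressor follows, residualized against the span of
#' its own condition's canonical regressor and the constant so that the
#' canonical coefficient is numerically identical to the one obtained from a
#' canonical-only model. Nuisance columns (constant, drift, motion) close the
#' matrix.
#'
#' @param events an `event_timeline` or list of them (one per condition).
#' @param tr repetition time, seconds.
#' @param n_scans number of scans.
#' @param basis `"informed"` (canonical + temporal derivative) or
#'   `"canonical"`.
#' @param params [hrf_parameters()].
#' @param drift_cutoff high-pass cutoff in seconds, or `Inf` for a constant
#'   column only (the single-voxel simulation default).
#' @param motion optional `n_scans x 6` matrix of realignment covariates.
#' @param orthogonalize_derivative residualize the derivative column against
#'   {canonical, constant} (default TRUE, the conventional choice).
#' @return An object of class `design_matrix`: the matrix `X` with labeled
#'   columns plus metadata (`tr`, `n_scans`, `microtime_dt`, `conditions`,
#'   per-condition canonical/derivative column indices, `basis`, `params`).
#' @export
build_design <- function(events, tr, n_scans,
                         basis = c("informed", "canonical"),
                         params = hrf_parameters(),
                         drift_cutoff = Inf, motion = NULL,
                         orthogonalize_derivative = TRUE) {
  basis <- match.arg(basis)
  params <- as_hrf_parameters(params)
  if (inherits(events, "event_timeline")) events <- list(events)
  dt <- params$microtime_dt
  total <- n_scans * tr + params$kernel_length
  bs <- informed_basis(params)
  nuis <- drift_basis(n_scans, tr, drift_cutoff)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_scans)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
  }
  cols <- list(); labels <- character(0)
  cond_index <- list()
  for (e in events) {
    u <- boxcar(e, dt, total)
    x1 <- convolve_to_scans(u, bs$canonical, tr, n_scans, dt)
    lab1 <- paste0(e$condition, "_canonical")
    cols <- c(cols, list(x1)); labels <- c(labels, lab1)
    ci <- list(canonical = length(cols), derivative = NA_integer_)
    if (basis == "informed") {
      x2 <- convolve_to_scans(u, bs$derivative, tr, n_scans, dt)
      if (orthogonalize_derivative) {
        x2 <- orthogonalize(x2, rep(1, n_scans))  # remove constant part
        x2 <- orthogonalize(x2, x1 - mean(x1))    # then centered canonical
      }
      cols <- c(cols, list(x2))
      labels <- c(labels, paste0(e$condition, "_derivative"))
      ci$derivative <- length(cols)
    }
    cond_index[[e$condition]] <- ci
  }
  X <- do.call(cbind, c(cols, list(nuis), if (!is.null(motion)) list(motion)))
  colnames(X) <- c(labels, colnames(nuis),
                   if (!is.null(motion)) colnames(motion))
  structure(list(X = X, tr = tr, n_scans = n_scans,
                 microtime_dt = dt, basis = basis,
                 conditions = cond_index, params = params),
            class = "design_matrix")
}

#' Per-column sums of squares of a design matrix
#'
#' The quantities `sum_t x_k(t)^2` entering the derivative-boost formula,
#' recomputed on demand from the stored columns.
#'
#' @param design a `design_matrix`.
#' @return Named numeric vector.
#' @export
column_ssq <- function(design) {
  colSums(design$X^2)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d scans x %d columns (tr = %g s, basis = %s)\n",
              x$n_scans, ncol(x$X), x$tr, x$basis))
  cat("columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Export a design matrix as TSV
#'
#' @param design a `design_matrix`.
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design$X), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
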