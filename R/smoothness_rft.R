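#' Estimate intrinsic spatial smoothness
#'
#' Per-axis FWHM of the Gaussian kernel that, applied to white noise, would
#' reproduce the observed lag-one neighbor correlation of the (standardized)
#' image: `fwhm_vox = sqrt(-2 log(2) / log(rho))` per axis, the
#' neighbor-correlation form of the Flitney-Jenkinson estimator. Neighbor
#' products are taken only between in-mask pairs; the image is demeaned over
#' the mask first, making the estimate invariant to affine intensity
#' rescaling.
#'
#' @param vol 3D array, or a list of 3D arrays (per-image estimates are
#'   averaged; the usual case is one estimate per subject contrast image).
#' @param mask logical 3D array; default: all voxels.
#' @param voxel_size voxel edge, mm (scalar or length 3).
#' @param min_voxels minimum masked voxels required (default 1000).
#' @return Object of class `smoothness_estimate`: `fwhm` (mm per axis),
#'   `fwhm_voxels`, geometric-mean `fwhm_mean`, `resel_count`,
#'   `n_voxels_used`.
#' @export
estimate_fwhm <- function(vol, mask = NULL, voxel_size = 1,
                          min_voxels = 1000) {
  if (is.list(vol)) {
    ests <- lapply(vol, estimate_fwhm, mask = mask,
                   voxel_size = voxel_size, min_voxels = min_voxels)
    fw_vox <- rowMeans(vapply(ests, function(e) e$fwhm_voxels, numeric(3)))
    return(smoothness_from_fwhm(fw_vox, rep_len(voxel_size, 3),
                                ests[[1]]$n_voxels_used,
                                if (is.null(mask)) dim(vol[[1]]) else NULL,
                                mask))
  }
  stopifnot(length(dim(vol)) == 3)
  voxel_size <- rep_len(voxel_size, 3)
  if (is.null(mask)) mask <- array(TRUE, dim(vol))
  nv <- sum(mask)
  if (nv < min_voxels)
    stop(sprintf("too few masked voxels (%d < %d)", nv, min_voxels))
  v <- vol
  v[!mask] <- NA
  v <- v - mean(v, na.rm = TRUE)
  if (stats::sd(v[mask]) == 0) stop("constant image: smoothness undefined")
  rho <- vapply(1:3, function(a) axis_lag1_cor(v, mask, a), numeric(1))
  ## clamp: white noise can give rho <= 0; the implied FWHM is << 1 voxel
  rho <- pmin(pmax(rho, 1e-8), 1 - 1e-8)
  fw_vox <- sqrt(-2 * log(2) / log(rho))
  smoothness_from_fwhm(fw_vox, voxel_size, nv, dim(vol), mask)
}

smoothness_from_fwhm <- function(fw_vox, voxel_size, nv, shape, mask) {
  structure(list(fwhm = fw_vox * voxel_size,
                 fwhm_voxels = fw_vox,
                 fwhm_mean = prod(fw_vox * voxel_size)^(1 / 3),
                 resel_count = nv / prod(fw_vox),
                 n_voxels_used = nv),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness: FWHM = [%s] mm (geo mean %.2f), %.1f resels over %d voxels\n",
              paste(sprintf("%.2f", x$fwhm), collapse = ", "),
              x$fwhm_mean, x$resel_count, x$n_voxels_used))
  invisible(x)
}

axis_lag1_cor <- function(v, mask, axis) {
  d <- dim(v)
  idx1 <- lapply(d, seq_len)
  idx2 <- idx1
  idx1[[axis]] <- seq_len(d[axis] - 1)
  idx2[[axis]] <- seq_len(d[axis] - 1) + 1
  a <- do.call(`[`, c(list(v), idx1))
  b <- do.call(`[`, c(list(v), idx2))
  ok <- do.call(`[`, c(list(mask), idx1)) & do.call(`[`, c(list(mask), idx2))
  a <- a[ok]; b <- b[ok]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Resel count
#'
#' Resolution elements: masked voxel count divided by the product of the
#' per-axis FWHM in voxels.
#'
#' @param mask logical array (or a voxel count).
#' @param fwhm_voxels per-axis FWHM in voxels (length 3, > 0).
#' @return Number of resels.
#' @export
resel_count <- function(mask, fwhm_voxels) {
  if (any(fwhm_voxels <= 0)) stop("fwhm_voxels must be > 0")
  nv <- if (is.numeric(mask) && length(mask) == 1) mask else sum(mask)
  nv / prod(rep_len(fwhm_voxels, 3))
}

## Lattice resel vector [R0, R1, R2, R3] of a mask (Worsley's point/edge/
## face/cube counts), needed for the expected Euler characteristic.
resel_vector <- function(mask, fwhm_voxels) {
  f <- rep_len(fwhm_voxels, 3)
  r <- 1 / f
  m <- mask * 1L
  d <- dim(m)
  shift <- function(ax) {
    src <- lapply(d, seq_len); src[[ax]] <- seq_len(d[ax] - 1) + 1L
    dst <- lapply(d, seq_len); dst[[ax]] <- seq_len(d[ax] - 1)
    out <- array(0L, d)
    do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
  }
  mx <- shift(1); my <- shift(2); mz <- shift(3)
  P <- sum(m)
  Ex <- sum(m * mx); Ey <- sum(m * my); Ez <- sum(m * mz)
  Fxy <- sum(m * mx * my * shift_both(m, 1, 2))
  Fxz <- sum(m * mx * mz * shift_both(m, 1, 3))
  Fyz <- sum(m * my * mz * shift_both(m, 2, 3))
  C <- sum(m * mx * my * mz * shift_both(m, 1, 2) * shift_both(m, 1, 3) *
             shift_both(m, 2, 3) * shift_both(shift_both(m, 1, 2), 3, 3))
  R0 <- P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C
  R1 <- (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
    (Ez - Fxz - Fyz + C) * r[3]
  R2 <- (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] +
    (Fyz - C) * r[2] * r[3]
  R3 <- C * r[1] * r[2] * r[3]
  c(R0, R1, R2, R3)
}

shift_both <- function(m, a1, a2) {
  d <- dim(m)
  src <- lapply(d, seq_len); dst <- lapply(d, seq_len)
  for (ax in unique(c(a1, a2))) {
    src[[ax]] <- seq_len(d[ax] - 1) + 1L
    dst[[ax]] <- seq_len(d[ax] - 1)
  }
  out <- array(0L, d)
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
}

## Euler characteristic densities, dimensions 0..3.
## stat = "z": Gaussian field; stat = "t": t-field with df degrees of freedom.
ec_density <- function(u, df = NULL, stat = c("z", "t")) {
  stat <- match.arg(stat)
  a <- 4 * log(2)
  if (stat == "z") {
    e <- exp(-u^2 / 2)
    c(stats::pnorm(u, lower.tail = FALSE),
      sqrt(a) / (2 * pi) * e,
      a / (2 * pi)^1.5 * u * e,
      a^1.5 / (2 * pi)^2 * (u^2 - 1) * e)
  } else {
    v <- df
    core <- (1 + u^2 / v)^(-(v - 1) / 2)
    c(stats::pt(u, v, lower.tail = FALSE),
      sqrt(a) / (2 * pi) * core,
      a / (2 * pi)^1.5 *
        exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v / 2) * u * core,
      a^1.5 / (2 * pi)^2 * ((v - 1) / v * u^2 - 1) * core)
  }
}

## Corrected p-value for a cluster of extent k_resel at primary height u:
## Poisson clumping with the D = 3 Gaussian-field extent tail
## P(n >= k) = exp(-beta k^(2/3)), beta = (Gamma(5/2)/En)^(2/3).
rft_cluster_p <- function(k_resel, u, df, resels, stat) {
  rho <- ec_density(u, df, stat)
  Em <- max(sum(resels * rho), 1e-24)
  tail_p <- if (stat == "z") stats::pnorm(u, lower.tail = FALSE)
            else stats::pt(u, df, lower.tail = FALSE)
  EN <- tail_p * resels[4]
  En <- max(EN / Em, 1e-24)
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  pn <- exp(-beta * k_resel^(2 / 3))
  1 - exp(-Em * pn)
}

#' RFT cluster-extent inference
#'
#' Thresholds a t-statistic image at an uncorrected primary level (default
#' p < 0.001, one-sided), labels suprathreshold voxels into 18-connected
#' clusters, and assigns each cluster a family-wise-error-corrected p-value
#' from the Gaussian-random-field cluster-extent approximation using
#' resel-normalized extents. Fields with fewer than about 30 degrees of
#' freedom use t-field Euler-characteristic densities; larger df use the
#' Gaussian densities at the Gaussianized threshold.
#'
#' @param t_map 3D array of t-values.
#' @param df degrees of freedom (>= 1).
#' @param smoothness a `smoothness_estimate` for the component images.
#' @param mask logical array; default all voxels.
#' @param primary_p primary (cluster-forming) uncorrected p (default 0.001).
#' @param alpha cluster-level FWE threshold for the `significant` flag
#'   (default 0.05). All clusters are returned with their corrected p.
#' @param connectivity 6, 18 (default, the SPM convention) or 26.
#' @return Object of class `cluster_result`: data.frame `clusters`
#'   (cluster_id, n_voxels, peak_t, peak_x/y/z, p_fwe, significant), the
#'   label array, thresholds, and the resel vector used.
#' @export
cluster_inference <- function(t_map, df, smoothness, mask = NULL,
                              primary_p = 0.001, alpha = 0.05,
                              connectivity = 18) {
  stopifnot(length(dim(t_map)) == 3, df >= 1)
  if (is.null(mask)) mask <- array(TRUE, dim(t_map))
  fw <- smoothness$fwhm_voxels
  if (prod(fw)^(1 / 3) < 3)
    warning("smoothness below ~3 voxels FWHM: RFT approximations degrade; consider permutation inference")
  u <- stats::qt(primary_p, df, lower.tail = FALSE)
  stat <- if (df >= 30) "z" else "t"
  u_ec <- if (stat == "z") stats::qnorm(primary_p, lower.tail = FALSE) else u
  resels <- resel_vector(mask, fw)
  supra <- which(t_map >= u & mask)
  labels <- array(0L, dim(t_map))
  clusters <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                         peak_t = numeric(0), peak_x = integer(0),
                         peak_y = integer(0), peak_z = integer(0),
                         p_fwe = numeric(0), significant = logical(0))
  if (length(supra) > 0) {
    comp <- connected_components(supra, dim(t_map), connectivity)
    labels[supra] <- comp
    ids <- sort(unique(comp))
    rows <- lapply(ids, function(id) {
      vox <- supra[comp == id]
      k <- length(vox)
      pk <- vox[which.max(t_map[vox])]
      co <- arrayInd(pk, dim(t_map))
      p <- rft_cluster_p(k / prod(fw), u_ec, df, resels, stat)
      data.frame(cluster_id = id, n_voxels = k, peak_t = t_map[pk],
                 peak_x = co[1], peak_y = co[2], peak_z = co[3],
                 p_fwe = p, significant = p <= alpha)
    })
    clusters <- do.call(rbind, rows)
    clusters <- clusters[order(-clusters$n_voxels), ]
    rownames(clusters) <- NULL
  }
  structure(list(clusters = clusters, labels = labels,
                 primary_threshold_p = primary_p,
                 primary_threshold_t = u, alpha_fwe = alpha,
                 resels = resels, connectivity = connectivity,
                 df = df, stat = stat),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s) above t = %.2f (p < %g), %d significant at FWE %g\n",
              nrow(x$clusters), x$primary_threshold_t,
              x$primary_threshold_p, sum(x$clusters$significant),
              x$alpha_fwe))
  if (nrow(x$clusters) > 0) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Export a cluster table as TSV
#'
#' @param result a `cluster_result`.
#' @param path file path.
#' @param voxel_size mm per voxel for peak coordinates.
#' @export
write_cluster_tsv <- function(result, path, voxel_size = 1) {
  cl <- result$clusters
  vs <- rep_len(voxel_size, 3)
  out <- data.frame(cluster_id = cl$cluster_id, n_voxels = cl$n_voxels,
                    peak_t = cl$peak_t,
                    peak_x_mm = (cl$peak_x - 1) * vs[1],
                    peak_y_mm = (cl$peak_y - 1) * vs[2],
                    peak_z_mm = (cl$peak_z - 1) * vs[3],
                    p_fwe = cl$p_fwe)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Deterministic connected-component labeling over a sparse voxel set.
## Returns, per input voxel, a component id numbered by first (smallest
## linear index) member so labeling is invariant to visiting order.
connected_components <- function(vox_idx, shape, connectivity = 18) {
  offs <- neighbor_offsets(connectivity)
  n <- length(vox_idx)
  co <- arrayInd(vox_idx, shape)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- (co[, 3] - 1) * (shape[1] * shape[2]) + (co[, 2] - 1) * shape[1] +
    co[, 1]
  ord <- order(key)
  skey <- key[ord]
  for (o in seq_len(nrow(offs))) {
    nx <- co[, 1] + offs[o, 1]; ny <- co[, 2] + offs[o, 2]
    nz <- co[, 3] + offs[o, 3]
    ok <- nx >= 1 & nx <= shape[1] & ny >= 1 & ny <= shape[2] &
      nz >= 1 & nz <= shape[3]
    nk <- (nz - 1) * (shape[1] * shape[2]) + (ny - 1) * shape[1] + nx
    pos <- match(nk[ok], skey)
    hit <- which(ok)[!is.na(pos)]
    tgt <- ord[pos[!is.na(pos)]]
    for (j in seq_along(hit)) {
      a <- find(hit[j]); b <- find(tgt[j])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, sort(unique(roots)))
}

## half-space is not enough for union-find via matching; full offset set used
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}
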