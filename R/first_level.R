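#' Ordinary least-squares GLM fit
#'
#' Voxelwise independent OLS of BOLD data on a design matrix. Accepts a
#' single time series, a `n_scans x V` matrix of voxels, or a 4D array
#' (x, y, z, t) with a 3D logical mask. No prewhitening is applied: the
#' synthetic noise model is white, and the consequences of omitting AR
#' modeling are documented in the methods vignette.
#'
#' @param y numeric vector (length `n_scans`), matrix (`n_scans x V`), or 4D
#'   array with `mask`.
#' @param design a `design_matrix`.
#' @param mask 3D logical array selecting voxels when `y` is 4D.
#' @return An object of class `glm_fit`: `betas` (`p x V`), `residual_variance`
#'   (RSS / df per voxel), `df` = `n_scans - rank(X)`, `r_squared` computed
#'   against mean-removed data, `xtx_inv`, and the design.
#' @export
fit_ols <- function(y, design, mask = NULL) {
  X <- design$X
  if (is.array(y) && length(dim(y)) == 4) {
    if (is.null(mask)) stop("a 3D mask is required for 4D input")
    dims <- dim(y)
    ymat <- t(matrix(y, prod(dims[1:3]), dims[4])[as.vector(mask), ,
                                                  drop = FALSE])
    fit <- fit_ols(ymat, design)
    fit$mask <- mask
    return(fit)
  }
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  if (nrow(y) != nrow(X)) stop("data length does not match n_scans")
  if (any(!is.finite(y))) stop("non-finite values in data")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  betas <- qr.coef(qrX, y)
  fitted <- X %*% betas
  res <- y - fitted
  df <- nrow(X) - qrX$rank
  rss <- colSums(res^2)
  tss <- colSums(sweep(y, 2, colMeans(y))^2)
  r2 <- ifelse(tss > 0, pmax(0, pmin(1, 1 - rss / tss)), 0)
  structure(list(betas = betas,
                 residual_variance = rss / df,
                 df = df,
                 r_squared = r2,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 design = design),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: %d voxels, %d parameters, df = %d\n",
              ncol(x$betas), nrow(x$betas), x$df))
  invisible(x)
}

check_weights <- function(fit, weights) {
  if (length(weights) != nrow(fit$betas))
    stop("contrast weight length must equal the design column count")
  as.numeric(weights)
}

#' Contrast T-statistic
#'
#' `T = w'beta / sqrt(sigma2 * w' (X'X)^{-1} w)` per voxel. Voxels with zero
#' estimated residual variance get an infinite-T sentinel (signed by the
#' contrast value, `NaN` for a zero contrast) and a warning reports the count.
#'
#' @param fit a `glm_fit`.
#' @param weights contrast weight vector (design column order).
#' @return List with `t` (per voxel) and `df`.
#' @export
t_statistic <- function(fit, weights) {
  w <- check_weights(fit, weights)
  cb <- as.numeric(crossprod(w, fit$betas))
  vw <- as.numeric(crossprod(w, fit$xtx_inv %*% w))
  if (vw == 0) return(list(t = rep(0, length(cb)), df = fit$df))
  se2 <- fit$residual_variance * vw
  # exact-fit voxels (zero residual variance up to rounding) get the sentinel
  degen <- se2 <= 0 | cb^2 > 1e24 * se2
  tvals <- ifelse(degen, sign(cb) * Inf, cb / sqrt(se2))
  nz <- sum(degen)
  if (nz > 0)
    warning(sprintf("%d voxel(s) with zero residual variance: infinite-T sentinel", nz))
  list(t = tvals, df = fit$df)
}

#' Contrast of parameter estimates
#'
#' @param fit a `glm_fit`.
#' @param weights contrast weight vector.
#' @param model_tag label recorded with the image (`canonical`,
#'   `boost_constrained`, `boost_full`, ...).
#' @return An object of class `contrast_image`: per-voxel values, the
#'   weights, and the tag.
#' @export
contrast_image <- function(fit, weights, model_tag = fit$design$basis) {
  w <- check_weights(fit, weights)
  structure(list(values = as.numeric(crossprod(w, fit$betas)),
                 contrast_weights = w, model_tag = model_tag),
            class = "contrast_image")
}

#' Canonical contrast weights for a set of conditions
#'
#' Builds a weight vector placing `coef[i]` on the canonical column of
#' condition `i` and zero elsewhere.
#'
#' @param design a `design_matrix`.
#' @param conditions condition labels.
#' @param coef per-condition coefficients (default 1).
#' @return Numeric weight vector of length `ncol(X)`.
#' @export
canonical_weights <- function(design, conditions = names(design$conditions),
                              coef = 1) {
  coef <- rep_len(coef, length(conditions))
  w <- numeric(ncol(design$X))
  for (i in seq_along(conditions)) {
    ci <- design$conditions[[conditions[i]]]
    if (is.null(ci)) stop("unknown condition: ", conditions[i])
    w[ci$canonical] <- coef[i]
  }
  w
}
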