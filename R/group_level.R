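#' Second-level one-sample t-test (summary statistics random effects)
#'
#' Pools first-level contrast estimates (or boosted amplitudes) from N
#' subjects voxelwise into `t = mean / sqrt(var / N)` with `df = N - 1`,
#' where `var` is the unbiased between-subject variance. Voxels whose values
#' are identical across subjects (zero variance) get a signed infinite-t
#' sentinel; their count is warned about and recorded.
#'
#' @param images `V x N` matrix, or list of N equal-length vectors /
#'   equal-shape arrays, or list of `contrast_image`s.
#' @return Object of class `group_stat_map`: `group_mean`,
#'   `between_subject_variance`, `t_values`, `df`, `n_subjects`,
#'   `n_zero_variance`.
#' @export
one_sample_t <- function(images) {
  Y <- as_image_matrix(images)
  N <- ncol(Y)
  if (N < 2) stop("need at least 2 subjects")
  m <- rowMeans(Y)
  v <- rowSums((Y - m)^2) / (N - 1)
  tval <- ifelse(v > 0, m / sqrt(v / N), sign(m) * Inf)
  nz <- sum(v == 0)
  if (nz > 0)
    warning(sprintf("%d voxel(s) with zero between-subject variance", nz))
  structure(list(group_mean = m, between_subject_variance = v,
                 t_values = tval, df = N - 1, n_subjects = N,
                 n_zero_variance = nz),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("group_stat_map: N = %d (df = %d), %d voxels, max |t| = %.2f\n",
              x$n_subjects, x$df, length(x$t_values),
              max(abs(x$t_values[is.finite(x$t_values)]))))
  invisible(x)
}

#' Second-level paired t-test
#'
#' One-sample t-test on the voxelwise subject differences `a - b` (matched
#' subject order); its results do not depend on the between-subject variance
#' of the common response.
#'
#' @param images_a,images_b same containers as [one_sample_t()], equal N.
#' @return A `group_stat_map` of the differences.
#' @export
paired_t <- function(images_a, images_b) {
  A <- as_image_matrix(images_a)
  B <- as_image_matrix(images_b)
  if (!all(dim(A) == dim(B)))
    stop("paired samples must have matching subjects and voxel counts")
  one_sample_t(A - B)
}

#' Between-subject variance map
#'
#' Unbiased voxelwise variance of first-level contrast estimates across
#' subjects — the denominator driver of the group t-statistic.
#'
#' @param images same containers as [one_sample_t()].
#' @return Numeric vector of per-voxel variances.
#' @export
variance_map <- function(images) {
  Y <- as_image_matrix(images)
  if (ncol(Y) < 2) stop("need at least 2 subjects")
  m <- rowMeans(Y)
  rowSums((Y - m)^2) / (ncol(Y) - 1)
}

as_image_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  if (is.list(images)) {
    vecs <- lapply(images, function(im) {
      if (inherits(im, "contrast_image")) as.numeric(im$values)
      else as.numeric(im)
    })
    if (length(unique(lengths(vecs))) != 1)
      stop("images are not co-dimensioned")
    return(do.call(cbind, vecs))
  }
  stop("unsupported image container")
}
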