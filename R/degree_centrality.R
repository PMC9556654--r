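# Extract the in-mask time-series matrix (t x V), dropping zero-variance
# voxels from the mask with a warning. Returns the matrix, the (possibly
# reduced) linear mask indices, and the columns standardized to zero mean
# and unit Euclidean norm so correlations are plain inner products.
.masked_standardized_ts <- function(series, mask) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "volume_mask"))
  dm <- dim(series$data)
  stopifnot(identical(dm[1:3], dim(mask$data)))
  idx <- which(mask$data)
  Y <- matrix(series$data, nrow = prod(dm[1:3]), ncol = dm[4])
  X <- t(Y[idx, , drop = FALSE])              # t x V
  X <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  bad <- nrm == 0 | !is.finite(nrm)
  if (any(bad)) {
    warning(sprintf("dropping %d zero-variance voxel(s) from the mask",
                    sum(bad)))
    idx <- idx[!bad]
    X <- X[, !bad, drop = FALSE]
    nrm <- nrm[!bad]
  }
  if (length(idx) < 2L) stop("mask must contain at least 2 usable voxels")
  list(X = sweep(X, 2, nrm, `/`), idx = idx)
}

#' Voxel-wise binarized degree centrality
#'
#' For each in-mask voxel i, counts the other in-mask voxels j whose
#' Pearson correlation with i exceeds `threshold_r` (strict inequality;
#' negative correlations never count). Computed in row blocks of
#' `chunk_size` voxels so the full V x V correlation matrix is never
#' materialized; the result is independent of `chunk_size`.
#'
#' @param series a preprocessed [bold_series()].
#' @param mask a [volume_mask()]; zero-variance voxels are dropped with a
#'   warning.
#' @param threshold_r correlation threshold in (-1, 1); default 0.25.
#' @param chunk_size voxels per correlation block (default 256).
#' @return 3D integer array of degrees (0 outside the mask).
#' @export
voxelwise_degree <- function(series, mask, threshold_r = 0.25,
                             chunk_size = 256L) {
  if (chunk_size < 1L) stop("chunk_size must be at least 1")
  if (threshold_r <= -1 || threshold_r >= 1) {
    stop("threshold_r must lie in (-1, 1)")
  }
  st <- .masked_standardized_ts(series, mask)
  X <- st$X
  V <- ncol(X)
  deg <- integer(V)
  starts <- seq.int(1L, V, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, V)
    R <- crossprod(X[, s:e, drop = FALSE], X)   # block x V correlations
    R[R > 1] <- 1
    R[R < -1] <- -1
    # self-correlation is exactly 1 > threshold_r, so subtract it
    deg[s:e] <- as.integer(rowSums(R > threshold_r) - 1L)
  }
  out <- array(0L, dim = dim(mask$data))
  out[st$idx] <- deg
  out
}

#' Standardize a degree-centrality map within a mask
#'
#' Method `"zscore"` (default) z-scores the binarized degree counts within
#' the mask: `Z(i) = (DC(i) - mean) / sd`. Method `"fisher_weighted"`
#' replaces the binary count by the sum of Fisher r-to-z transformed
#' suprathreshold correlations (`sum of atanh(r_ij)` over j with
#' `r_ij > threshold_r`) before z-scoring, which needs the time series and
#' so takes a [bold_series()] via `series`.
#'
#' @param raw_degree 3D numeric array (ignored for `"fisher_weighted"` when
#'   `series` is given).
#' @param mask a [volume_mask()].
#' @param method "zscore" or "fisher_weighted".
#' @param series,threshold_r,chunk_size used only by `"fisher_weighted"`.
#' @return 3D numeric array of standardized values, 0 outside the mask; the
#'   within-mask mean is 0 and SD is 1.
#' @export
standardize_dc <- function(raw_degree, mask, method = c("zscore", "fisher_weighted"),
                           series = NULL, threshold_r = 0.25, chunk_size = 256L) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "volume_mask"))
  if (method == "fisher_weighted") {
    if (is.null(series)) stop("fisher_weighted standardization needs `series`")
    raw_degree <- fisher_weighted_degree(series, mask, threshold_r, chunk_size)
  }
  idx <- which(mask$data)
  vals <- raw_degree[idx]
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    stop("degree map is constant within the mask; cannot z-score")
  }
  out <- array(0, dim = dim(raw_degree))
  out[idx] <- (vals - mean(vals)) / s
  out
}

#' Fisher-weighted voxel-wise degree
#'
#' Degree variant in which each suprathreshold edge contributes its Fisher
#' r-to-z transformed correlation `atanh(r)` instead of 1. Correlations are
#' clamped away from +/-1 before the transform.
#'
#' @inheritParams voxelwise_degree
#' @return 3D numeric array of summed edge weights (0 outside the mask).
#' @export
fisher_weighted_degree <- function(series, mask, threshold_r = 0.25,
                                   chunk_size = 256L) {
  if (chunk_size < 1L) stop("chunk_size must be at least 1")
  st <- .masked_standardized_ts(series, mask)
  X <- st$X
  V <- ncol(X)
  wdeg <- numeric(V)
  eps <- 1e-12
  starts <- seq.int(1L, V, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, V)
    R <- crossprod(X[, s:e, drop = FALSE], X)
    R[R > 1 - eps] <- 1 - eps
    R[R < -1 + eps] <- -1 + eps
    W <- atanh(R) * (R > threshold_r)
    # remove the self term (correlation clamped to 1 - eps)
    wdeg[s:e] <- rowSums(W) - atanh(1 - eps)
  }
  out <- array(0, dim = dim(mask$data))
  out[st$idx] <- wdeg
  out
}

#' Degree-centrality map pipeline for one subject
#'
#' Binarized degree, z-standardization within the mask, then Gaussian
#' smoothing of the standardized map (6 mm FWHM by default, matching common
#' degree-centrality protocols). With `smooth_fwhm_mm = 0` the result equals
#' `standardize_dc(voxelwise_degree(...))` exactly. Voxels outside the mask
#' are written as 0 and the mask label is stored alongside.
#'
#' @inheritParams voxelwise_degree
#' @param method standardization method, see [standardize_dc()].
#' @param smooth_fwhm_mm FWHM of the post-standardization smoothing.
#' @return A [dc_map()].
#' @export
dc_pipeline <- function(series, mask, threshold_r = 0.25,
                        smooth_fwhm_mm = 6, method = "zscore",
                        chunk_size = 256L) {
  raw <- voxelwise_degree(series, mask, threshold_r, chunk_size)
  std <- standardize_dc(raw, mask, method, series = series,
                        threshold_r = threshold_r, chunk_size = chunk_size)
  if (smooth_fwhm_mm > 0) {
    std <- smooth_volume(std, smooth_fwhm_mm,
                         voxel_size_mm = .voxel_sizes(series$affine))
  }
  dc_map(raw, std, threshold_r, method, mask$label, series$subject_id)
}
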