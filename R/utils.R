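#' @keywords internal
"_PACKAGE"

# FWHM of a Gaussian = sigma * 2*sqrt(2*log(2))
.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Convert 1-based voxel indices to world (mm) coordinates
#'
#' Applies the NIfTI voxel-to-world affine. NIfTI affines act on 0-based
#' voxel indices, so R's 1-based indices are shifted down by one first.
#'
#' @param ijk integer vector of length 3, or an n x 3 matrix of 1-based
#'   voxel indices.
#' @param affine 4 x 4 voxel-to-world transform.
#' @return numeric vector or n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, nrow = 1)
  h <- cbind(m - 1, 1)
  w <- h %*% t(affine)
  w <- w[, 1:3, drop = FALSE]
  if (!is.matrix(ijk)) drop(w) else w
}

# Diagonal RAS+ affine for isotropic voxels (origin at the first voxel).
.ras_affine <- function(voxel_size_mm) {
  a <- diag(c(rep(voxel_size_mm, 3), 1))
  a
}

# Voxel sizes (mm) per axis from an affine: column norms of the 3x3 block.
.voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# 1-D Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
.gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D or 4D array along one spatial axis (1-3) with a symmetric
# kernel, reflect padding. Vectorized shift-and-accumulate: a 4D input is
# convolved across all its volumes in one pass.
.conv_axis <- function(vol, kernel, axis) {
  n <- dim(vol)[axis]
  klen <- length(kernel)
  if (klen == 1L) return(vol * kernel)
  r <- (klen - 1L) %/% 2L
  nd <- length(dim(vol))
  out <- array(0, dim = dim(vol))
  idx_all <- seq_len(n)
  for (d in -r:r) {
    src <- idx_all + d
    # reflect at the boundaries (symmetric reflection, repeated so that
    # kernels wider than the axis still resolve to valid indices)
    if (n == 1L) {
      src[] <- 1L
    } else {
      while (any(src < 1L | src > n)) {
        src[src < 1L] <- 2L - src[src < 1L]
        src[src > n] <- 2L * n - src[src > n]
      }
    }
    w <- kernel[d + r + 1L]
    out <- out + w * switch(axis,
      if (nd == 3L) vol[src, , , drop = FALSE] else vol[src, , , , drop = FALSE],
      if (nd == 3L) vol[, src, , drop = FALSE] else vol[, src, , , drop = FALSE],
      if (nd == 3L) vol[, , src, drop = FALSE] else vol[, , src, , drop = FALSE])
  }
  out
}

# Spatial Gaussian smoothing of a 3D volume or 4D series (volume-wise);
# per-axis sigma in voxel units.
.smooth3d <- function(vol, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      vol <- .conv_axis(vol, .gauss_kernel_1d(sigma_vox[ax]), ax)
    }
  }
  vol
}

# Connected components of a logical 3D array.
# connectivity: 6, 18 or 26. Returns integer labels (0 = background).
.label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  dm <- dim(mask)
  idx <- which(mask)
  nv <- length(idx)
  lab <- array(0L, dim = dm)
  if (nv == 0L) return(lab)
  ai <- arrayInd(idx, dm)
  # half set of neighbour offsets (the rest are mirror images)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- rowSums(abs(offs)) > 0
  if (connectivity == 6L)  keep <- keep & rowSums(abs(offs)) == 1
  if (connectivity == 18L) keep <- keep & rowSums(abs(offs)) <= 2
  offs <- offs[keep, , drop = FALSE]
  # keep only lexicographically positive half to avoid duplicate edges
  pos <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs <- offs[pos, , drop = FALSE]
  pos_of <- integer(prod(dm))       # map linear voxel index -> node id
  pos_of[idx] <- seq_len(nv)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
          nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * dm[1] * dm[2] + (nb[ok, 2] - 1L) * dm[1] + nb[ok, 1]
    nbid <- pos_of[lin]
    from <- which(ok)[nbid > 0L]
    to <- nbid[nbid > 0L]
    for (e in seq_along(from)) {
      ra <- find(from[e]); rb <- find(to[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# Truncated normal sampling by inverse-CDF (vectorized).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pl, pu)
  stats::qnorm(u, mean, sd)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return 2|a & b| / (|a| + |b|); NaN if both are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
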