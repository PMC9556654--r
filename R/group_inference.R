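#' Build a two-group design for voxel-wise inference
#'
#' Constructs the design matrix `[intercept, group, covariates]` with the
#' contrast on the group column (patient minus control). Character or factor
#' covariates are expanded to treatment-coded dummies.
#'
#' @param group character/factor vector with values "patient" and "control".
#' @param covariates optional data.frame of per-subject covariates (e.g.
#'   age and sex, the usual matching variables).
#' @return A list of class `group_design` with elements `X`, `contrast`,
#'   `group`.
#' @export
group_design <- function(group, covariates = NULL) {
  group <- as.character(group)
  if (!all(group %in% c("patient", "control"))) {
    stop("group values must be 'patient' or 'control'")
  }
  if (sum(group == "patient") < 2L || sum(group == "control") < 2L) {
    stop("need at least 2 subjects per group")
  }
  X <- cbind(intercept = 1, group = as.numeric(group == "patient"))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(group))
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; redundant column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  contrast <- as.numeric(colnames(X) == "group")
  structure(list(X = X, contrast = contrast, group = group),
            class = "group_design")
}

# Stack standardized DC maps into a V x n matrix over the mask.
.stack_maps <- function(dc_maps, mask) {
  idx <- which(mask$data)
  Y <- vapply(dc_maps, function(m) {
    arr <- if (inherits(m, "dc_map")) m$standardized else m
    stopifnot(identical(dim(arr), dim(mask$data)))
    arr[idx]
  }, numeric(length(idx)))
  list(Y = matrix(Y, nrow = length(idx)), idx = idx)
}

#' Voxel-wise two-group GLM (ANCOVA) on degree-centrality maps
#'
#' Per voxel, fits standardized DC on `[intercept, group, covariates]` by
#' ordinary least squares and forms the t-statistic for the
#' patient-minus-control contrast. With no covariates this is exactly the
#' pooled-variance two-sample t-test at every voxel.
#'
#' @param dc_maps list of [dc_map()]s (their `standardized` component) or of
#'   3D arrays, aligned with the rows of the design.
#' @param design a [group_design()].
#' @param mask a [volume_mask()].
#' @param affine optional 4 x 4 affine carried into cluster reports.
#' @return A list of class `stat_map` with `tmap` (3D array, 0 outside the
#'   mask), `df`, `residuals` (V x n matrix), `mask`, `affine`, `design`.
#' @export
fit_voxelwise_glm <- function(dc_maps, design, mask, affine = NULL) {
  stopifnot(inherits(design, "group_design"), inherits(mask, "volume_mask"))
  X <- design$X
  n <- nrow(X)
  if (length(dc_maps) != n) {
    stop(sprintf("%d maps but %d design rows", length(dc_maps), n))
  }
  st <- .stack_maps(dc_maps, mask)
  Y <- t(st$Y)                                 # n x V
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)                      # p x V
  res <- qr.resid(qrX, Y)                      # n x V
  df <- n - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  cvar <- drop(t(design$contrast) %*% XtXinv %*% design$contrast)
  eff <- drop(design$contrast %*% beta)
  tval <- eff / sqrt(sigma2 * cvar)
  tval[!is.finite(tval)] <- 0
  tmap <- array(0, dim = dim(mask$data))
  tmap[st$idx] <- tval
  structure(list(tmap = tmap, df = df, residuals = t(res), mask = mask,
                 affine = affine, design = design),
            class = "stat_map")
}

#' Estimate residual spatial smoothness (FWHM) and resel count
#'
#' Standard normalized-gradient variance estimator: residual fields are
#' scaled to unit variance per voxel, squared forward differences along
#' each axis are averaged over in-mask voxel pairs and subjects, the
#' discrete-lattice variance is mapped back to the continuous Gaussian
#' autocorrelation scale, and `FWHM = sqrt(4 log 2 / lambda)` per axis.
#' The resel count is the mask volume divided by the product of the
#' per-axis FWHMs in voxel units.
#'
#' @param residuals V x n matrix of in-mask residuals (as stored in a
#'   `stat_map`) or a list of 3D residual arrays.
#' @param mask a [volume_mask()].
#' @param voxel_size_mm voxel sizes, scalar or length 3.
#' @return List with `fwhm_mm` (length 3), `fwhm_vox`, `resel_count`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm = 3) {
  stopifnot(inherits(mask, "volume_mask"))
  dm <- dim(mask$data)
  idx <- which(mask$data)
  if (length(idx) < 2L) stop("mask must contain more than one voxel")
  if (is.list(residuals)) {
    residuals <- vapply(residuals, function(a) a[idx], numeric(length(idx)))
  }
  n <- ncol(residuals)
  if (n < 2L) stop("need at least 2 residual maps")
  # unit-variance standardization per voxel across maps
  ss <- sqrt(rowSums(residuals^2))
  ss[ss == 0] <- Inf
  U <- residuals / ss
  vol <- function(v) { a <- array(0, dm); a[idx] <- v; a }
  inmask <- array(FALSE, dm); inmask[idx] <- TRUE
  lambda <- numeric(3)
  vsz <- rep_len(voxel_size_mm, 3)
  for (ax in 1:3) {
    sel_lo <- switch(ax,
      inmask[-dm[1], , , drop = FALSE] & inmask[-1, , , drop = FALSE],
      inmask[, -dm[2], , drop = FALSE] & inmask[, -1, , drop = FALSE],
      inmask[, , -dm[3], drop = FALSE] & inmask[, , -1, drop = FALSE])
    npair <- sum(sel_lo)
    if (npair == 0L) { lambda[ax] <- NA_real_; next }
    acc <- 0
    for (s in seq_len(n)) {
      a <- vol(U[, s])
      d <- switch(ax,
        a[-1, , , drop = FALSE] - a[-dm[1], , , drop = FALSE],
        a[, -1, , drop = FALSE] - a[, -dm[2], , drop = FALSE],
        a[, , -1, drop = FALSE] - a[, , -dm[3], drop = FALSE])
      acc <- acc + sum(d[sel_lo]^2)
    }
    lambda[ax] <- acc / npair
  }
  lambda[is.na(lambda)] <- mean(lambda, na.rm = TRUE)
  # discrete forward-difference variance -> continuous Gaussian ACF scale;
  # clamp so unsmoothed (white) fields map to a sub-voxel, nonzero FWHM
  lam_max <- 2 * (1 - exp(-2))
  lam <- pmin(lambda, lam_max)
  lam_cont <- -2 * log(1 - lam / 2)
  fwhm_vox <- sqrt(4 * log(2) / lam_cont)
  list(fwhm_mm = fwhm_vox * vsz,
       fwhm_vox = fwhm_vox,
       resel_count = length(idx) / prod(fwhm_vox))
}

# Connected suprathreshold clusters of one sign.
# Returns a data.frame with peak voxel indices and extents.
.extract_clusters <- function(tmap, threshold, sign = c("increase", "decrease"),
                              connectivity = 26L) {
  sign <- match.arg(sign)
  supra <- if (sign == "increase") tmap > threshold else tmap < -threshold
  lab <- .label_components(supra, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) return(NULL)
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    vox <- which(lab == l)
    tv <- tmap[vox]
    pk <- vox[which.max(abs(tv))]
    pk_ijk <- arrayInd(pk, dim(tmap))[1, ]
    out[[l]] <- data.frame(sign = sign,
                           peak_i = pk_ijk[1], peak_j = pk_ijk[2],
                           peak_k = pk_ijk[3],
                           n_voxels = length(vox),
                           peak_t = tv[which.max(abs(tv))],
                           label = l, stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, out), labels = lab)
}

# Lattice resel counts R0..R3 of a mask for given per-axis FWHM (voxels),
# from the point/edge/face/cube counts of the voxel lattice.
.resel_counts <- function(mask_arr, fwhm_vox) {
  dm <- dim(mask_arr)
  m <- mask_arr
  ex <- m[-dm[1], , , drop = FALSE] & m[-1, , , drop = FALSE]
  ey <- m[, -dm[2], , drop = FALSE] & m[, -1, , drop = FALSE]
  ez <- m[, , -dm[3], drop = FALSE] & m[, , -1, drop = FALSE]
  fxy <- ex[, -dm[2], , drop = FALSE] & ex[, -1, , drop = FALSE]
  fxz <- ex[, , -dm[3], drop = FALSE] & ex[, , -1, drop = FALSE]
  fyz <- ey[, , -dm[3], drop = FALSE] & ey[, , -1, drop = FALSE]
  cb <- fxy[, , -dm[3], drop = FALSE] & fxy[, , -1, drop = FALSE]
  P <- sum(m); Ex <- sum(ex); Ey <- sum(ey); Ez <- sum(ez)
  Fxy <- sum(fxy); Fxz <- sum(fxz); Fyz <- sum(fyz); C <- sum(cb)
  r <- fwhm_vox
  c(R0 = P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C,
    R1 = (Ex - Fxy - Fxz + C) / r[1] + (Ey - Fxy - Fyz + C) / r[2] +
         (Ez - Fxz - Fyz + C) / r[3],
    R2 = (Fxy - C) / (r[1] * r[2]) + (Fxz - C) / (r[1] * r[3]) +
         (Fyz - C) / (r[2] * r[3]),
    R3 = C / prod(r))
}

# EC densities of a t-field with v df at threshold u (0- to 3-dimensional).
.t_ec_densities <- function(u, v) {
  a <- 4 * log(2)
  b <- (1 + u^2 / v)^(-(v - 1) / 2)
  c(stats::pt(u, v, lower.tail = FALSE),
    sqrt(a) / (2 * pi) * b,
    a / (2 * pi)^(3 / 2) * exp(lgamma((v + 1) / 2) - lgamma(v / 2)) /
      sqrt(v / 2) * b * u,
    a^(3 / 2) / (2 * pi)^2 * b * ((v - 1) / v * u^2 - 1))
}

# RFT expected number of clusters (per tail, expected Euler characteristic)
# and expected suprathreshold voxel count at threshold u with df v.
.rft_cluster_quantities <- function(u, v, resels, n_mask_vox) {
  Em <- max(sum(resels * .t_ec_densities(u, v)), 1e-12)
  EN <- n_mask_vox * stats::pt(u, v, lower.tail = FALSE)
  list(Em = Em, EN = max(EN, 1e-12))
}

# RFT corrected p for a cluster of k voxels, searching both tails.
.rft_cluster_p <- function(k, Em, EN) {
  En <- EN / Em                     # expected cluster size in voxels
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  p_ge_k <- exp(-beta * k^(2 / 3))
  1 - exp(-2 * Em * p_ge_k)
}

#' Cluster-level correction by Gaussian random-field theory
#'
#' Thresholds the t-map at the two-tailed quantile for `voxel_p`, extracts
#' connected components separately for the positive and negative tails, and
#' assigns each cluster a family-wise corrected p-value from the standard
#' random-field expected-cluster-extent approximation for t-fields, using
#' the resel count from [estimate_smoothness()]. Clusters with corrected
#' p <= `alpha` and at least `min_extent` voxels are retained.
#'
#' @param stat a `stat_map` from [fit_voxelwise_glm()].
#' @param voxel_p two-tailed cluster-forming voxel p (default 0.01).
#' @param alpha cluster-level significance (default 0.05).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_extent minimum reportable cluster extent in voxels
#'   (default 50, the scale of whole-brain analyses; lower it for
#'   coarse-grid data).
#' @param voxel_size_mm voxel sizes for smoothness estimation.
#' @return A `cluster_table` data.frame (possibly empty), sorted by
#'   descending absolute peak t, with attributes `threshold_t`,
#'   `smoothness`, `label_map`.
#' @export
grf_cluster_correct <- function(stat, voxel_p = 0.01, alpha = 0.05,
                                connectivity = 26L, min_extent = 50L,
                                voxel_size_mm = 3) {
  stopifnot(inherits(stat, "stat_map"))
  if (voxel_p <= 0 || voxel_p >= 0.5) stop("voxel_p must lie in (0, 0.5)")
  u <- stats::qt(1 - voxel_p / 2, stat$df)
  sm <- estimate_smoothness(stat$residuals, stat$mask, voxel_size_mm)
  resels <- .resel_counts(stat$mask$data, sm$fwhm_vox)
  q <- .rft_cluster_quantities(u, stat$df, resels, sum(stat$mask$data))
  rows <- list()
  label_map <- array(0L, dim = dim(stat$tmap))
  next_id <- 1L
  for (sgn in c("increase", "decrease")) {
    ex <- .extract_clusters(stat$tmap, u, sgn, connectivity)
    if (is.null(ex)) next
    tb <- ex$table
    tb$corrected_p <- vapply(tb$n_voxels, .rft_cluster_p, numeric(1),
                             Em = q$Em, EN = q$EN)
    tb$cluster_id <- NA_integer_
    keep <- tb$corrected_p <= alpha & tb$n_voxels >= min_extent
    for (r in which(keep)) {
      label_map[ex$labels == tb$label[r]] <- next_id
      tb$cluster_id[r] <- next_id
      next_id <- next_id + 1L
    }
    if (any(keep)) rows[[sgn]] <- tb[keep, ]
  }
  out <- .finalize_cluster_table(rows, stat$affine)
  attr(out, "threshold_t") <- u
  attr(out, "smoothness") <- sm
  attr(out, "label_map") <- label_map
  out
}

# Fast two-tailed t statistics for simple regression of residualized maps
# on a residualized group regressor (used by the permutation loop).
.perm_t <- function(Yr, gr, df) {
  gg <- sum(gr^2)
  num <- drop(crossprod(Yr, gr))               # V
  yy <- colSums(Yr^2)
  rss <- pmax(yy - num^2 / gg, 0)
  se <- sqrt(rss / df) * sqrt(1 / gg)
  tv <- num / gg / se
  tv[!is.finite(tv)] <- 0
  tv
}

# Maximum cluster extent over both tails at threshold u.
.max_extent <- function(tmap, u, connectivity) {
  m <- 0L
  for (sgn in c("increase", "decrease")) {
    ex <- .extract_clusters(tmap, u, sgn, connectivity)
    if (!is.null(ex)) m <- max(m, max(ex$table$n_voxels))
  }
  m
}

#' Cluster-level correction by permutation of group labels
#'
#' Nonparametric alternative to [grf_cluster_correct()]. Covariate effects
#' are removed by the Freedman-Lane scheme (maps and the group regressor
#' are residualized against the covariates, then subject order is
#' permuted); the null distribution of the maximal suprathreshold cluster
#' extent over both tails yields rank-based corrected p-values with +1
#' smoothing. Fully seed-reproducible.
#'
#' @inheritParams fit_voxelwise_glm
#' @param voxel_p two-tailed cluster-forming voxel p.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param alpha cluster-level significance.
#' @param connectivity 6, 18 or 26.
#' @param min_extent minimum reportable cluster extent in voxels.
#' @param affine optional affine for world coordinates in the report.
#' @return A `cluster_table` (possibly empty) with attribute `threshold_t`
#'   and `null_max_extent` (the permutation distribution).
#' @export
permutation_cluster_correct <- function(dc_maps, design, mask,
                                        voxel_p = 0.01, n_perm = 1000L,
                                        seed = 1L, alpha = 0.05,
                                        connectivity = 26L, min_extent = 50L,
                                        affine = NULL) {
  stopifnot(inherits(design, "group_design"), inherits(mask, "volume_mask"))
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse corrected-p scale")
  st <- .stack_maps(dc_maps, mask)
  n <- length(dc_maps)
  X <- design$X
  gcol <- which(design$contrast == 1)
  Z <- X[, -gcol, drop = FALSE]                # intercept + covariates
  qrZ <- qr(Z)
  Yr <- t(qr.resid(qrZ, t(st$Y)))              # V x n residualized maps
  gr <- qr.resid(qrZ, X[, gcol])
  df <- n - qr(X)$rank
  u <- stats::qt(1 - voxel_p / 2, df)
  dm <- dim(mask$data)
  to_vol <- function(v) { a <- array(0, dm); a[st$idx] <- v; a }
  t_obs <- to_vol(.perm_t(t(Yr), gr, df))
  set.seed(as.integer(seed))
  null_max <- integer(n_perm)
  YrT <- t(Yr)                                  # n x V, permute rows of gr
  for (p in seq_len(n_perm)) {
    gp <- gr[sample.int(n)]
    null_max[p] <- .max_extent(to_vol(.perm_t(YrT, gp, df)), u, connectivity)
  }
  rows <- list()
  label_map <- array(0L, dim = dm)
  next_id <- 1L
  for (sgn in c("increase", "decrease")) {
    ex <- .extract_clusters(t_obs, u, sgn, connectivity)
    if (is.null(ex)) next
    tb <- ex$table
    tb$corrected_p <- vapply(tb$n_voxels, function(k) {
      (1 + sum(null_max >= k)) / (n_perm + 1)
    }, numeric(1))
    tb$cluster_id <- NA_integer_
    keep <- tb$corrected_p <= alpha & tb$n_voxels >= min_extent
    for (r in which(keep)) {
      label_map[ex$labels == tb$label[r]] <- next_id
      tb$cluster_id[r] <- next_id
      next_id <- next_id + 1L
    }
    if (any(keep)) rows[[sgn]] <- tb[keep, ]
  }
  out <- .finalize_cluster_table(rows, affine)
  attr(out, "threshold_t") <- u
  attr(out, "null_max_extent") <- null_max
  attr(out, "label_map") <- label_map
  out
}

# Assemble, order and world-map a cluster table from per-sign rows.
.finalize_cluster_table <- function(rows, affine) {
  if (length(rows) == 0L) return(.empty_cluster_table())
  tb <- do.call(rbind, rows)
  tb$label <- NULL
  if (is.null(affine)) affine <- diag(4)
  w <- voxel_to_world(as.matrix(tb[, c("peak_i", "peak_j", "peak_k")]), affine)
  tb$peak_x_mm <- w[, 1]; tb$peak_y_mm <- w[, 2]; tb$peak_z_mm <- w[, 3]
  tb <- tb[order(-abs(tb$peak_t)), ]
  tb <- tb[, c("cluster_id", "sign", "peak_x_mm", "peak_y_mm", "peak_z_mm",
               "peak_i", "peak_j", "peak_k", "n_voxels", "peak_t",
               "corrected_p")]
  rownames(tb) <- NULL
  class(tb) <- c("cluster_table", "data.frame")
  tb
}

#' Format a cluster table for reporting
#'
#' Maps peak voxel indices to world mm coordinates through the affine and
#' sorts rows by descending absolute peak t (decreases keep their negative
#' t-values). Returns the table with recomputed world coordinates; an empty
#' table keeps its header.
#'
#' @param table a `cluster_table`.
#' @param affine 4 x 4 voxel-to-world transform.
#' @return The ordered `cluster_table`.
#' @export
report_clusters <- function(table, affine) {
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) == 0L) return(table)
  w <- voxel_to_world(as.matrix(table[, c("peak_i", "peak_j", "peak_k")]),
                      affine)
  table$peak_x_mm <- w[, 1]; table$peak_y_mm <- w[, 2]; table$peak_z_mm <- w[, 3]
  table <- table[order(-abs(table$peak_t)), ]
  rownames(table) <- NULL
  table
}
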