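# Independent oracles and small fixture builders used across the suite.

# Dense brute-force binarized degree: full correlation matrix via stats::cor.
bf_degree <- function(X, threshold_r = 0.25) {
  R <- stats::cor(X)
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  as.integer(colSums(R > threshold_r))
}

# Textbook pooled-variance two-sample t statistic (group a minus group b).
bf_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Wrap a t x V time-series matrix as a bold_series on a V x 1 x 1 grid,
# with the matching all-TRUE mask.
series_from_matrix <- function(X, tr = 2, voxel_mm = 3) {
  V <- ncol(X); nt <- nrow(X)
  dat <- array(0, dim = c(V, 1, 1, nt))
  dat[, 1, 1, ] <- t(X)
  list(series = bold_series(dat, diag(c(rep(voxel_mm, 3), 1)), tr),
       mask = volume_mask(array(TRUE, dim = c(V, 1, 1))))
}

# Random low-rank-plus-noise time-series matrix with nontrivial correlations.
random_correlated_ts <- function(nt, V, k = 3) {
  Z <- matrix(stats::rnorm(nt * k), nt, k)
  L <- matrix(stats::runif(k * V, -1, 1), k, V)
  Z %*% L + matrix(stats::rnorm(nt * V), nt, V)
}

# Small planted-effect cohort used by several inference/classification
# tests: 16^3 grid, six default hub regions, patients first.
small_planted_cohort <- function(n_per_group = 15, n_timepoints = 100,
                                 magnitude = 0.5, seed = 42) {
  spec <- cohort_spec(n_per_group = n_per_group,
                      grid_shape = c(16L, 16L, 16L),
                      n_timepoints = n_timepoints,
                      effect_magnitude = magnitude, seed = seed)
  generate_cohort(spec)
}

# Standardized DC maps for a cohort (no map smoothing, to keep planted
# geometry sharp where tests reason about voxel sets).
cohort_dc_maps <- function(cohort, smooth_fwhm_mm = 0) {
  lapply(cohort$bold, function(b) {
    dc_pipeline(b, cohort$mask, smooth_fwhm_mm = smooth_fwhm_mm)
  })
}
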