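make_series <- function(nt = 212, dims = c(4, 4, 4), tr = 2, seed = 1) {
  set.seed(seed)
  bold_series(array(stats::rnorm(prod(dims) * nt), dim = c(dims, nt)),
              diag(c(3, 3, 3, 1)), tr)
}

test_that("initial volume discarding trims exactly and rejects overruns", {
  s <- make_series(nt = 212)
  out <- discard_initial_volumes(s, 5)
  expect_equal(dim(out$data)[4], 207)
  expect_identical(out$data[, , , 1], s$data[, , , 6])   # frames unaltered
  expect_identical(discard_initial_volumes(s, 0), s)
  s10 <- make_series(nt = 10)
  expect_error(discard_initial_volumes(s10, 10), "discard")
})

test_that("motion QC applies strict per-direction thresholds", {
  zero <- matrix(0, 20, 6)
  expect_false(motion_qc(zero)$excluded)
  spike <- zero; spike[7, 2] <- 2.5
  qc <- motion_qc(spike)
  expect_true(qc$excluded)
  expect_match(qc$report$reason, "translation")
  boundary <- zero; boundary[3, 1] <- 2.0; boundary[9, 5] <- 2.0
  expect_false(motion_qc(boundary)$excluded)   # strict > 2, not >=
  rot <- zero; rot[5, 6] <- -2.4
  expect_true(motion_qc(rot)$excluded)
  bad <- zero; bad[1, 1] <- NaN
  expect_error(motion_qc(bad), "non-finite")
})

test_that("QC recovers a planted excluded set exactly", {
  planted <- c(2.6, 1.2, 0.4, 3.1, 1.9)
  excl <- vapply(seq_along(planted), function(i) {
    motion_qc(generate_motion_trace(60, planted[i], 0.5, seed = i))$excluded
  }, logical(1))
  expect_identical(excl, planted > 2)
})

test_that("nuisance regression returns exact OLS residuals", {
  s <- make_series(nt = 60, dims = c(3, 3, 3))
  # intercept only (trend included internally): voxel means ~ 0
  out <- regress_nuisance(s)
  expect_lt(max(abs(apply(out$data, 1:3, mean))), 1e-12)
  # a voxel equal to a confound column is annihilated
  conf <- matrix(stats::rnorm(60 * 2), 60, 2)
  s2 <- s; s2$data[1, 1, 1, ] <- conf[, 1]
  out2 <- regress_nuisance(s2, conf)
  expect_lt(max(abs(out2$data[1, 1, 1, ])), 1e-10)
  # residuals match a brute-force normal-equations solve
  set.seed(8)
  conf8 <- matrix(stats::rnorm(60 * 8), 60, 8)
  out3 <- regress_nuisance(s, conf8)
  X <- cbind(1, seq_len(60) - 30.5, conf8)
  Y <- t(matrix(s$data, 27, 60))
  res_bf <- Y - X %*% solve(t(X) %*% X, t(X) %*% Y)
  expect_lt(max(abs(t(res_bf) - matrix(out3$data, 27, 60))), 1e-10)
  # residuals orthogonal to every confound column
  proj <- abs(t(res_bf) %*% conf8)
  expect_lt(max(proj / (sqrt(colSums(res_bf^2)) %o% sqrt(colSums(conf8^2)))),
            1e-10)
})

test_that("rank-deficient confounds fall back to a pseudo-inverse", {
  s <- make_series(nt = 40, dims = c(2, 2, 2))
  conf <- cbind(1:40, (1:40) * 2)    # collinear with each other and trend
  expect_warning(out <- regress_nuisance(s, conf), "rank-deficient")
  expect_lt(max(abs(colSums(matrix(out$data, 8, 40) %*% conf))), 1e-6)
})

test_that("bandpass keeps the pass band and removes stop band and DC", {
  nt <- 200; tr <- 2
  tt <- seq_len(nt) * tr
  mk <- function(f) {
    x <- sin(2 * pi * f * tt)
    s <- bold_series(array(rep(x, each = 8), dim = c(2, 2, 2, nt)),
                     diag(c(3, 3, 3, 1)), tr)
    drop(bandpass(s)$data[1, 1, 1, ])
  }
  x05 <- sin(2 * pi * 0.05 * tt)
  expect_gt(stats::sd(mk(0.05)) / stats::sd(x05), 0.95)
  x20 <- sin(2 * pi * 0.2 * tt)
  expect_lt(stats::sd(mk(0.2)) / stats::sd(x20), 0.10)
  const <- bold_series(array(7, dim = c(2, 2, 2, nt)), diag(c(3, 3, 3, 1)), tr)
  expect_lt(max(abs(bandpass(const)$data)), 1e-10)
  expect_error(bandpass(const, high_hz = 0.3), "Nyquist")
})

test_that("Gaussian smoothing matches its closed form and conserves mass", {
  delta <- array(0, dim = c(13, 13, 13)); delta[7, 7, 7] <- 1
  sm <- smooth_volume(delta, 6, voxel_size_mm = 3)
  sig <- 6 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sig, 0.8493218, tolerance = 1e-6)
  r <- ceiling(4 * sig)
  k <- exp(-((-r:r)^2) / (2 * sig^2)); k <- k / sum(k)
  # separable closed form at center and one-off voxels
  expect_equal(sm[7, 7, 7], k[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm[8, 7, 7], k[r + 2] * k[r + 1]^2, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-9)        # interior support
  expect_identical(smooth_volume(delta, 0, voxel_size_mm = 3), delta)
  const <- array(3, dim = c(9, 9, 9))
  expect_equal(smooth_volume(const, 8, voxel_size_mm = 3), const,
               tolerance = 1e-12)
  expect_error(smooth_volume(delta, -1, voxel_size_mm = 3), "non-negative")
})

test_that("the preprocessing pipeline is deterministic and order-fixed", {
  s <- make_series(nt = 60, dims = c(4, 4, 4), seed = 3)
  mot <- generate_motion_trace(60, 0.8, 0.6, seed = 2)
  a <- preprocess_bold(s, mot, n_discard = 5, smooth_fwhm_mm = 6)
  b <- preprocess_bold(s, mot, n_discard = 5, smooth_fwhm_mm = 6)
  expect_identical(a$series$data, b$series$data)
  expect_equal(dim(a$series$data)[4], 55)
  # excluded subject propagates a NULL series with the reason
  mover <- generate_motion_trace(60, 2.8, 0.5, seed = 4)
  out <- preprocess_bold(s, mover)
  expect_null(out$series)
  expect_true(out$report$excluded)
})

test_that("voxel series are decorrelated from confounds by the nuisance stage", {
  s <- make_series(nt = 80, dims = c(3, 3, 3), seed = 5)
  mot <- generate_motion_trace(80, 1.0, 0.7, seed = 6)
  kept <- mot[6:80, ]
  res <- regress_nuisance(discard_initial_volumes(s, 5), kept)
  Y <- matrix(res$data, 27, 75)
  expect_lt(max(abs(stats::cor(t(Y), kept))), 1e-6)
  # the later zero-phase filter can only reintroduce a modest component
  out <- preprocess_bold(s, mot, n_discard = 5, smooth_fwhm_mm = 0,
                         low_hz = 0.01, high_hz = 0.2)
  Yf <- matrix(out$series$data, 27, 75)
  expect_lt(max(abs(stats::cor(t(Yf), kept))), 0.2)
})
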