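#' Discard initial BOLD volumes
#'
#' Drops the first `n_discard` frames of a BOLD series (signal-equilibration
#' scans); the remaining frames are unaltered.
#'
#' @param series a [bold_series()].
#' @param n_discard number of leading volumes to drop (default 5).
#' @return A [bold_series()] with `t - n_discard` timepoints.
#' @export
discard_initial_volumes <- function(series, n_discard = 5L) {
  stopifnot(inherits(series, "bold_series"))
  nt <- dim(series$data)[4]
  if (n_discard < 0) stop("n_discard must be non-negative")
  if (n_discard >= nt) {
    stop(sprintf("cannot discard %d volumes from a series of length %d",
                 n_discard, nt))
  }
  if (n_discard == 0L) return(series)
  bold_series(series$data[, , , (n_discard + 1L):nt, drop = FALSE],
              series$affine, series$tr_seconds, series$subject_id)
}

#' Head-motion quality control
#'
#' Flags a subject for exclusion when the absolute maximum of any single
#' translation column exceeds `threshold_mm` or of any rotation column
#' exceeds `threshold_deg` (strict inequality, per direction).
#'
#' @param trace motion matrix from [generate_motion_trace()] or read from a
#'   6-column text file: translations (mm) then rotations (degrees).
#' @param threshold_mm translation threshold in mm (default 2).
#' @param threshold_deg rotation threshold in degrees (default 2).
#' @param subject_id identifier carried into the report row.
#' @return A list with `excluded` (logical) and `report` (one-row
#'   data.frame with max_translation_mm, max_rotation_deg, excluded, reason).
#' @export
motion_qc <- function(trace, threshold_mm = 2, threshold_deg = 2,
                      subject_id = "subject") {
  trace <- as.matrix(trace)
  if (nrow(trace) < 1L || ncol(trace) != 6L) {
    stop("motion trace must be a non-empty 6-column matrix")
  }
  if (!all(is.finite(trace))) stop("motion trace contains non-finite values")
  max_mm <- max(abs(trace[, 1:3]))
  max_deg <- max(abs(trace[, 4:6]))
  excluded <- max_mm > threshold_mm || max_deg > threshold_deg
  reason <- if (!excluded) {
    ""
  } else if (max_mm > threshold_mm) {
    sprintf("max translation %.3f mm > %g mm", max_mm, threshold_mm)
  } else {
    sprintf("max rotation %.3f deg > %g deg", max_deg, threshold_deg)
  }
  list(
    excluded = excluded,
    report = data.frame(subject_id = subject_id,
                        max_translation_mm = max_mm,
                        max_rotation_deg = max_deg,
                        excluded = excluded, reason = reason,
                        stringsAsFactors = FALSE)
  )
}

#' Nuisance regression with linear detrending
#'
#' Removes confound time courses from every voxel by ordinary least
#' squares. An intercept and a linear trend are always appended to the
#' supplied confounds, so detrending and nuisance removal happen in one
#' joint regression. Returned voxel series are the OLS residuals,
#' numerically orthogonal to every confound column.
#'
#' @param series a [bold_series()].
#' @param confounds numeric t x k matrix (e.g. 6 motion parameters plus
#'   white-matter and ventricular mean signals), or NULL for
#'   intercept + trend only.
#' @return A [bold_series()] of residuals.
#' @export
regress_nuisance <- function(series, confounds = NULL) {
  stopifnot(inherits(series, "bold_series"))
  dm <- dim(series$data)
  nt <- dm[4]
  X <- cbind(intercept = 1, trend = seq_len(nt) - (nt + 1) / 2)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt) {
      stop(sprintf("confounds have %d rows but the series has %d timepoints",
                   nrow(confounds), nt))
    }
    X <- cbind(X, confounds)
  }
  Y <- matrix(series$data, nrow = prod(dm[1:3]), ncol = nt)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix; residualizing via pseudo-inverse")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    P <- sv$u[, keep, drop = FALSE]           # orthonormal basis of col(X)
    res <- Y - (Y %*% P) %*% t(P)
  } else {
    res <- t(qr.resid(qrX, t(Y)))
  }
  bold_series(array(res, dim = dm), series$affine, series$tr_seconds,
              series$subject_id)
}

# Frequency response of the zero-phase bandpass: unity in [low, high],
# raised-cosine roll-off of half-width `transition_hz` on each side.
.bandpass_response <- function(freq, low_hz, high_hz, transition_hz) {
  H <- numeric(length(freq))
  H[freq >= low_hz & freq <= high_hz] <- 1
  lo_ramp <- freq < low_hz & freq > low_hz - transition_hz
  H[lo_ramp] <- 0.5 * (1 + cos(pi * (low_hz - freq[lo_ramp]) / transition_hz))
  hi_ramp <- freq > high_hz & freq < high_hz + transition_hz
  H[hi_ramp] <- 0.5 * (1 + cos(pi * (freq[hi_ramp] - high_hz) / transition_hz))
  H
}

#' Zero-phase bandpass filtering of BOLD series
#'
#' Frequency-domain (FFT) filter with an ideal pass band and a raised-cosine
#' roll-off; multiplying the spectrum by a real response makes the filter
#' exactly zero-phase, so temporal correlations between voxels are not
#' shifted. The DC component is removed whenever `low_hz > 0`.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.01 and 0.1, the
#'   conventional resting-state band).
#' @param transition_hz half-width of the cosine roll-off (default 0.005 Hz).
#' @return A filtered [bold_series()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1,
                     transition_hz = 0.005) {
  stopifnot(inherits(series, "bold_series"))
  nyquist <- 1 / (2 * series$tr_seconds)
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyquist))
  }
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop("need 0 < low_hz < high_hz")
  }
  dm <- dim(series$data)
  nt <- dm[4]
  k <- 0:(nt - 1)
  freq <- pmin(k, nt - k) / (nt * series$tr_seconds)
  H <- .bandpass_response(freq, low_hz, high_hz, transition_hz)
  Y <- matrix(series$data, nrow = prod(dm[1:3]), ncol = nt)
  # FFT along time for all voxels at once
  spec_mat <- t(stats::mvfft(t(Y)))
  spec_mat <- spec_mat * rep(H, each = nrow(spec_mat))
  filt <- Re(t(stats::mvfft(t(spec_mat), inverse = TRUE))) / nt
  bold_series(array(filt, dim = dm), series$affine, series$tr_seconds,
              series$subject_id)
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with per-axis sigma
#' `fwhm / (2 * sqrt(2 * log(2)))` converted to voxel units from the voxel
#' sizes (anisotropic voxels get per-axis sigmas). Boundary handling is
#' reflection padding; `fwhm_mm = 0` is the identity.
#'
#' @param x a [bold_series()] (each volume smoothed independently) or a 3D
#'   numeric array.
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @param ... passed to methods.
#' @return Same type as `x`.
#' @export
smooth_volume <- function(x, fwhm_mm, ...) UseMethod("smooth_volume")

#' @rdname smooth_volume
#' @export
smooth_volume.bold_series <- function(x, fwhm_mm, ...) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(x)
  sigma_vox <- .fwhm_to_sigma(fwhm_mm) / .voxel_sizes(x$affine)
  bold_series(.smooth3d(x$data, sigma_vox), x$affine, x$tr_seconds,
              x$subject_id)
}

#' @rdname smooth_volume
#' @param voxel_size_mm voxel sizes (scalar or length-3) for the array method.
#' @export
smooth_volume.array <- function(x, fwhm_mm, voxel_size_mm = 3, ...) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  stopifnot(length(dim(x)) == 3L)
  if (fwhm_mm == 0) return(x)
  sigma_vox <- .fwhm_to_sigma(fwhm_mm) / rep_len(voxel_size_mm, 3)
  .smooth3d(x, sigma_vox)
}

#' Full BOLD preprocessing pipeline for one subject
#'
#' Fixed stage order: discard initial volumes, motion QC, joint
#' detrend + nuisance regression, bandpass filtering, optional spatial
#' smoothing. White-matter and ventricular confound signals, when masks are
#' supplied, are the mean time series within those masks computed after
#' volume discarding and before filtering.
#'
#' @param series a [bold_series()].
#' @param motion motion matrix with one row per original timepoint (rows for
#'   discarded volumes are dropped in step one) or per retained timepoint.
#' @param n_discard leading volumes to drop (default 5).
#' @param threshold_mm,threshold_deg motion QC thresholds (defaults 2 mm, 2 deg).
#' @param wm_mask,csf_mask optional [volume_mask()]s for white-matter and
#'   ventricular mean-signal confounds.
#' @param low_hz,high_hz bandpass edges (defaults 0.01 and 0.1 Hz).
#' @param smooth_fwhm_mm smoothing kernel FWHM (default 8 mm; 0 disables).
#' @return A list with `series` (preprocessed [bold_series()], or NULL when
#'   the subject is excluded) and `report` (one-row QC data.frame).
#' @export
preprocess_bold <- function(series, motion, n_discard = 5L,
                            threshold_mm = 2, threshold_deg = 2,
                            wm_mask = NULL, csf_mask = NULL,
                            low_hz = 0.01, high_hz = 0.1,
                            smooth_fwhm_mm = 8) {
  stopifnot(inherits(series, "bold_series"))
  motion <- as.matrix(motion)
  nt0 <- dim(series$data)[4]
  if (nrow(motion) == nt0) {
    motion_kept <- motion[(n_discard + 1L):nt0, , drop = FALSE]
  } else if (nrow(motion) == nt0 - n_discard) {
    motion_kept <- motion
  } else {
    stop(sprintf(paste0("motion trace has %d rows; expected %d (all volumes) ",
                        "or %d (after discarding)"),
                 nrow(motion), nt0, nt0 - n_discard))
  }
  series <- discard_initial_volumes(series, n_discard)
  qc <- motion_qc(motion, threshold_mm, threshold_deg, series$subject_id)
  if (qc$excluded) {
    return(list(series = NULL, report = qc$report))
  }
  confounds <- motion_kept
  for (mk in list(wm_mask, csf_mask)) {
    if (!is.null(mk)) {
      stopifnot(inherits(mk, "volume_mask"))
      Y <- matrix(series$data, nrow = prod(dim(series$data)[1:3]))
      confounds <- cbind(confounds, colMeans(Y[which(mk$data), , drop = FALSE]))
    }
  }
  series <- regress_nuisance(series, confounds)
  series <- bandpass(series, low_hz, high_hz)
  if (smooth_fwhm_mm > 0) series <- smooth_volume(series, smooth_fwhm_mm)
  list(series = series, report = qc$report)
}
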