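#' BOLD time-series container
#'
#' Holds one subject's 4D BOLD data (x, y, z, t) together with the
#' voxel-to-world affine and the repetition time.
#'
#' @param data 4D numeric array (x, y, z, t), all values finite, t >= 2.
#' @param affine 4 x 4 invertible voxel-to-world (mm) transform.
#' @param tr_seconds positive repetition time in seconds.
#' @param subject_id subject identifier string.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine, tr_seconds, subject_id = "subject") {
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[4] < 2L) stop("BOLD series must have at least 2 timepoints")
  if (!all(is.finite(data))) stop("BOLD series contains non-finite values")
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  structure(
    list(data = data, affine = affine, tr_seconds = tr_seconds,
         subject_id = as.character(subject_id)),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %s: %d x %d x %d voxels, %d timepoints, TR = %g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

#' 3D analysis mask
#'
#' @param data logical 3D array; must contain at least one TRUE voxel.
#' @param label one of "brain", "gray_matter", "white_matter", "ventricle".
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(data, label = "gray_matter") {
  stopifnot(length(dim(data)) == 3L)
  data <- array(as.logical(data), dim = dim(data))
  if (!any(data)) stop("mask is empty")
  label <- match.arg(label, c("brain", "gray_matter", "white_matter", "ventricle"))
  structure(list(data = data, label = label), class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask> %s: %s grid, %d voxels in mask\n",
              x$label, paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

#' @export
dim.volume_mask <- function(x) dim(x$data)

#' Per-subject degree-centrality map
#'
#' @param raw_degree 3D integer array of suprathreshold connection counts.
#' @param standardized 3D numeric array of standardized DC (0 outside mask),
#'   or NULL if standardization has not been applied.
#' @param threshold_r correlation threshold used for binarization.
#' @param method standardization method ("zscore" or "fisher_weighted").
#' @param mask_label label of the mask used.
#' @param subject_id subject identifier.
#' @return An object of class `dc_map`.
#' @export
dc_map <- function(raw_degree, standardized = NULL, threshold_r = 0.25,
                   method = "zscore", mask_label = "gray_matter",
                   subject_id = "subject") {
  structure(
    list(raw_degree = raw_degree, standardized = standardized,
         threshold_r = threshold_r, method = method,
         mask_label = mask_label, subject_id = as.character(subject_id)),
    class = "dc_map"
  )
}

#' @export
print.dc_map <- function(x, ...) {
  cat(sprintf("<dc_map> %s: grid %s, r > %g, method = %s\n",
              x$subject_id, paste(dim(x$raw_degree), collapse = " x "),
              x$threshold_r, x$method))
  invisible(x)
}

# Empty cluster table with the canonical columns.
.empty_cluster_table <- function() {
  ct <- data.frame(
    cluster_id = integer(0), sign = character(0),
    peak_x_mm = numeric(0), peak_y_mm = numeric(0), peak_z_mm = numeric(0),
    peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
    n_voxels = integer(0), peak_t = numeric(0), corrected_p = numeric(0),
    stringsAsFactors = FALSE
  )
  class(ct) <- c("cluster_table", "data.frame")
  ct
}
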