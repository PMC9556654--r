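#' Write a BOLD series to a NIfTI-1 file
#'
#' @param series a [bold_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(.voxel_sizes(series$affine), series$tr_seconds)
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a BOLD series from a NIfTI-1 file
#'
#' @param path NIfTI file with 4D data.
#' @param tr_seconds repetition time override; when NULL the pixdim time
#'   unit stored in the header is used.
#' @param subject_id subject identifier (defaults to the file stem).
#' @return A [bold_series()].
#' @export
read_bold <- function(path, tr_seconds = NULL, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4) pd[4] else NA_real_
    if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 2
  }
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  bold_series(array(as.numeric(img), dim = dim(img)), aff, tr_seconds,
              subject_id)
}

#' Write a 3D volume (mask, DC map, t-map, label map) as NIfTI-1
#'
#' @param vol 3D numeric/logical/integer array.
#' @param affine 4 x 4 voxel-to-world transform.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 3D volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @return List with `data` (3D array) and `affine`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)[1:3]),
       affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#'
#' One row per timepoint: three translations (mm), three rotations
#' (degrees). No header, matching the conventional realignment-parameter
#' file layout.
#'
#' @param trace 6-column numeric matrix.
#' @param path output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_motion_trace <- function(trace, path) {
  utils::write.table(format(trace, digits = 10, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion trace file must have 6 columns")
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}

#' Write a generated cohort to a directory
#'
#' Per-subject 4D NIfTI (`<id>_bold.nii.gz`) and motion trace
#' (`<id>_motion.txt`), the analysis mask (`mask.nii.gz`), the metadata
#' table (`cohort.csv`), the ground-truth effect mask
#' (`ground_truth.nii.gz`, values -1/0/+1 for effect direction) and a JSON
#' sidecar with the generator parameters.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  affine <- cohort$bold[[1]]$affine
  for (i in seq_along(cohort$bold)) {
    id <- cohort$bold[[i]]$subject_id
    write_bold(cohort$bold[[i]], file.path(dir, paste0(id, "_bold.nii.gz")))
    write_motion_trace(cohort$motion[[i]],
                       file.path(dir, paste0(id, "_motion.txt")))
  }
  write_volume(cohort$mask$data, affine, file.path(dir, "mask.nii.gz"))
  utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  write_volume(cohort$truth$effect_direction, affine,
               file.path(dir, "ground_truth.nii.gz"))
  spec <- cohort$truth$spec
  sidecar <- spec[setdiff(names(spec), "hub_regions")]
  sidecar$hub_regions <- lapply(spec$hub_regions, function(h) {
    list(center = h$center, radius = h$radius, sign = h$sign,
         magnitude = h$magnitude)
  })
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a cluster table as CSV
#'
#' Columns mirror a conventional cluster report: sign, peak world
#' coordinate (mm), peak voxel indices, extent, peak t, corrected p.
#'
#' @param table a `cluster_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
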