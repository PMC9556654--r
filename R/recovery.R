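#' Match surviving clusters to planted ground-truth regions
#'
#' For every planted hub region, finds the best-matching surviving cluster
#' of the same effect sign and reports its Dice overlap with the region
#' (intersected with the analysis mask). Used to validate that group
#' inference recovers the regions the generator planted, with the correct
#' direction.
#'
#' @param clusters a `cluster_table` from [grf_cluster_correct()] or
#'   [permutation_cluster_correct()] (its `label_map` attribute is used).
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param mask the cohort's [volume_mask()].
#' @return data.frame with one row per planted region: `region`, `sign`
#'   (+1/-1), `n_voxels`, `best_dice`, `matched_cluster` (NA when no
#'   same-sign cluster survived).
#' @export
planted_recovery <- function(clusters, truth, mask) {
  spec <- truth$spec
  label_map <- attr(clusters, "label_map")
  if (is.null(label_map)) stop("cluster table carries no label_map attribute")
  dm <- dim(mask$data)
  hubs <- Filter(function(h) h$magnitude > 0, spec$hub_regions)
  rows <- lapply(seq_along(hubs), function(k) {
    h <- hubs[[k]]
    reg <- array(FALSE, dm)
    reg[.sphere_voxels(h$center, h$radius, dm)] <- TRUE
    reg <- reg & mask$data
    want <- if (h$sign > 0) "increase" else "decrease"
    best <- 0; best_id <- NA_integer_
    if (nrow(clusters) > 0) {
      for (r in which(clusters$sign == want)) {
        d <- dice_coefficient(reg, label_map == clusters$cluster_id[r])
        if (d > best) { best <- d; best_id <- clusters$cluster_id[r] }
      }
    }
    data.frame(region = k, sign = h$sign, n_voxels = sum(reg),
               best_dice = best, matched_cluster = best_id)
  })
  do.call(rbind, rows)
}

#' Ground-truth region label map
#'
#' Builds an integer label map (1..K) of the planted hub regions of a
#' cohort, for feature extraction against the true regions rather than
#' data-derived clusters.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param mask the cohort's [volume_mask()].
#' @param effect_only keep only regions with magnitude > 0 (default FALSE:
#'   all hub regions are labeled).
#' @return integer 3D array; 0 outside the regions.
#' @export
truth_label_map <- function(truth, mask, effect_only = FALSE) {
  spec <- truth$spec
  dm <- dim(mask$data)
  hubs <- spec$hub_regions
  if (effect_only) hubs <- Filter(function(h) h$magnitude > 0, hubs)
  lab <- array(0L, dim = dm)
  for (k in seq_along(hubs)) {
    h <- hubs[[k]]
    vox <- .sphere_voxels(h$center, h$radius, dm)
    lab[vox[mask$data[vox]]] <- k
  }
  lab
}
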