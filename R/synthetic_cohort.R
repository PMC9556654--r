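#' Specify a synthetic two-group resting-state fMRI cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The defaults
#' emulate a two-group adolescent depression study: 71 subjects per group,
#' 212 timepoints at TR = 2 s on a 3 mm isotropic grid, and six spherical
#' hub regions (three with increased, three with decreased connectivity in
#' the patient group).
#'
#' Each hub region is a list with fields `center` (voxel index triple),
#' `radius` (voxels), `sign` (+1 for higher patient connectivity, -1 for
#' lower) and `magnitude` (fractional scaling of the patient-group latent
#' loading; 0 plants no effect).
#'
#' @param n_per_group subjects per group.
#' @param grid_shape integer vector of 3 voxel counts per axis.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_timepoints number of volumes per subject (>= 20).
#' @param tr_seconds repetition time in seconds.
#' @param hub_regions list of hub-region lists (see Details); NULL for the
#'   default six-region layout scaled to `grid_shape`.
#' @param effect_magnitude magnitude applied to the default hub regions when
#'   `hub_regions` is NULL.
#' @param n_latents number of latent network time courses; raised to the
#'   number of hub regions if smaller.
#' @param ar_coef AR(1) coefficient of the latent time courses.
#' @param noise_sigma per-voxel standard deviation of the spatially
#'   autocorrelated noise (after smoothing).
#' @param loading_range lower and upper bound of the uniform per-voxel
#'   latent-network loadings, relative to the unit-variance latent course.
#'   The spread places within-network pair correlations on both sides of
#'   the binarization threshold, so scaling the patient-group loadings
#'   moves edges across it in either direction.
#' @param n_periphery optional number of dispersed member voxels per
#'   network, sampled uniformly from the mask outside the network's core
#'   sphere (default 0: purely spherical networks). Dispersed members make
#'   a network spatially distributed but let planted effects bleed outside
#'   the hub region, so they are off for recovery studies.
#' @param spatial_fwhm_mm FWHM of the Gaussian kernel applied to the noise
#'   field (0 for white noise).
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 71L,
                        grid_shape = c(12L, 12L, 12L),
                        voxel_size_mm = 3,
                        n_timepoints = 212L,
                        tr_seconds = 2,
                        hub_regions = NULL,
                        effect_magnitude = 0.5,
                        n_latents = 5L,
                        ar_coef = 0.3,
                        noise_sigma = 1,
                        loading_range = c(0.35, 0.8),
                        n_periphery = 0L,
                        spatial_fwhm_mm = 6,
                        seed = 1L) {
  stopifnot(n_per_group >= 1, length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_size_mm > 0, tr_seconds > 0, noise_sigma > 0,
            spatial_fwhm_mm >= 0, ar_coef >= 0, ar_coef < 1,
            length(loading_range) == 2, loading_range[1] > 0,
            loading_range[2] >= loading_range[1], n_periphery >= 0)
  if (n_timepoints < 20) stop("n_timepoints must be at least 20")
  if (is.null(hub_regions)) {
    hub_regions <- .default_hub_regions(grid_shape, effect_magnitude)
  }
  for (h in hub_regions) {
    if (!all(c("center", "radius", "sign", "magnitude") %in% names(h))) {
      stop("each hub region needs fields center, radius, sign, magnitude")
    }
    if (h$magnitude < 0) stop("hub effect magnitude must be >= 0")
    if (!h$sign %in% c(-1, 1)) stop("hub sign must be +1 or -1")
    lo <- h$center - h$radius
    hi <- h$center + h$radius
    if (any(lo < 1) || any(hi > grid_shape)) {
      stop(sprintf(
        "hub region centered at (%s) with radius %g extends outside the %s grid",
        paste(h$center, collapse = ", "), h$radius,
        paste(grid_shape, collapse = " x ")))
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm,
         n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds,
         hub_regions = hub_regions,
         n_latents = as.integer(n_latents),
         ar_coef = ar_coef,
         noise_sigma = noise_sigma,
         loading_range = as.numeric(loading_range),
         n_periphery = as.integer(n_periphery),
         spatial_fwhm_mm = spatial_fwhm_mm,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Six spheres (3 positive, 3 negative) at the octahedron vertices around
# the grid center. Radii scale with the grid and are kept above the noise
# correlation length so that most within-sphere voxel pairs are at
# distances where the spatially smoothed noise no longer correlates them;
# only such pairs respond to loading changes with threshold crossings.
.default_hub_regions <- function(grid_shape, magnitude) {
  g <- min(grid_shape)
  ctr <- floor((grid_shape + 1) / 2)
  # largest half-integer radius whose six octahedral spheres neither
  # overlap (center distance off*sqrt(2) > 2r) nor leave the grid
  off <- NA
  for (radius in rev(seq(2, max(2, g / 4), by = 0.5))) {
    off_min <- floor(radius * sqrt(2)) + 1L
    off_max <- floor(min(min(ctr) - 1, g - max(ctr)) - radius)
    if (off_min <= off_max) { off <- off_min; break }
  }
  if (is.na(off)) stop("grid too small for the default six-region layout")
  off <- rep(off, 3)
  mk <- function(center, sign) list(center = center, radius = radius,
                                    sign = sign, magnitude = magnitude)
  list(
    mk(ctr + c(-off[1], 0, 0), +1),
    mk(ctr + c(+off[1], 0, 0), +1),
    mk(ctr + c(0, -off[2], 0), +1),
    mk(ctr + c(0, +off[2], 0), -1),
    mk(ctr + c(0, 0, -off[3]), -1),
    mk(ctr + c(0, 0, +off[3]), -1)
  )
}

# Linear indices of voxels within Euclidean distance `radius` of `center`.
.sphere_voxels <- function(center, radius, dm) {
  rng <- lapply(1:3, function(a) {
    max(1L, floor(center[a] - radius)):min(dm[a], ceiling(center[a] + radius))
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  (g[, 3] - 1L) * dm[1] * dm[2] + (g[, 2] - 1L) * dm[1] + g[, 1]
}

# Ellipsoidal "brain" mask inscribed in the grid.
.ellipsoid_mask <- function(dm) {
  ctr <- (dm + 1) / 2
  semi <- (dm - 1) / 2
  g <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])))
  inside <- ((g[, 1] - ctr[1]) / semi[1])^2 +
            ((g[, 2] - ctr[2]) / semi[2])^2 +
            ((g[, 3] - ctr[3]) / semi[3])^2 <= 1
  array(inside, dim = dm)
}

#' Generate a simulated head-motion parameter trace
#'
#' Produces a 6-column random-walk trace (3 translations in mm, 3 rotations
#' in degrees) rescaled so that the realized absolute maxima over the
#' translation and rotation blocks equal the requested maxima exactly.
#'
#' @param n_timepoints number of rows (>= 1).
#' @param max_abs_mm realized maximum absolute translation (mm); 0 gives
#'   all-zero translations.
#' @param max_abs_deg realized maximum absolute rotation (degrees).
#' @param seed integer seed.
#' @return Numeric matrix with columns trans_x, trans_y, trans_z (mm) and
#'   rot_x, rot_y, rot_z (degrees).
#' @export
generate_motion_trace <- function(n_timepoints, max_abs_mm = 0.5,
                                  max_abs_deg = 0.5, seed = 1L) {
  stopifnot(n_timepoints >= 1)
  if (max_abs_mm < 0 || max_abs_deg < 0) {
    stop("motion maxima must be non-negative")
  }
  set.seed(as.integer(seed))
  walk <- apply(matrix(stats::rnorm(n_timepoints * 6), ncol = 6), 2, cumsum)
  walk <- matrix(walk, ncol = 6)  # n_timepoints = 1 edge case
  rescale <- function(block, target) {
    m <- max(abs(block))
    if (target == 0 || m == 0) block * 0 else block * (target / m)
  }
  out <- cbind(rescale(walk[, 1:3, drop = FALSE], max_abs_mm),
               rescale(walk[, 4:6, drop = FALSE], max_abs_deg))
  colnames(out) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  out
}

# Table-1-style demographic and clinical metadata for both groups.
.generate_metadata <- function(n_per_group) {
  n <- n_per_group
  patient <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = "patient",
    age_years = round(.rtruncnorm(n, 15.1, 1.9, 14, 18), 1),
    sex = ifelse(stats::runif(n) < 0.62, "M", "F"),
    education = ifelse(stats::runif(n) < 0.887,
                       "high_school_or_lower", "undergraduate"),
    hrsd17 = as.integer(round(.rtruncnorm(n, 22.9, 4.3, 17, Inf))),
    illness_duration_months = round(.rtruncnorm(n, 6.3, 3.6, 0.5, 12), 1),
    stringsAsFactors = FALSE
  )
  control <- data.frame(
    subject_id = sprintf("sub-%03d", n + seq_len(n)),
    group = "control",
    age_years = round(.rtruncnorm(n, 16.5, 1.9, 14, 18), 1),
    sex = ifelse(stats::runif(n) < 0.61, "M", "F"),
    education = ifelse(stats::runif(n) < 0.875,
                       "high_school_or_lower", "undergraduate"),
    hrsd17 = as.integer(round(.rtruncnorm(n, 8.7, 5.8, 0, Inf))),
    illness_duration_months = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(patient, control)
}

# AR(1) latent time course with unit marginal variance.
.ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
}

#' Generate a synthetic two-group fMRI cohort with planted hub effects
#'
#' Simulates per-subject 4D BOLD data as a sum of shared low-rank latent
#' network signals and spatially autocorrelated Gaussian noise. Each latent
#' network is an AR(1) time course broadcast, with per-voxel loadings, to a
#' spherical voxel set; subjects in the patient group have their loadings in
#' each hub region multiplied by `1 + sign * magnitude`, so the true
#' binarized degree of hub voxels differs between groups whenever
#' magnitude > 0. Identical seeds give bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `bold` (list of [bold_series()], patients
#'   first), `motion` (list of motion matrices), `mask` ([volume_mask()]),
#'   `cohort` (metadata data.frame) and `truth` (list with `effect_mask`,
#'   `effect_direction` and the generator parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  dm <- spec$grid_shape
  nt <- spec$n_timepoints
  n_sub <- 2L * spec$n_per_group
  mask_arr <- .ellipsoid_mask(dm)

  # ---- cohort-level draws (seed) --------------------------------------
  set.seed(spec$seed)
  meta <- .generate_metadata(spec$n_per_group)
  n_hub <- length(spec$hub_regions)
  n_net <- max(spec$n_latents, n_hub)
  in_mask <- which(mask_arr)
  networks <- vector("list", n_net)
  core_of <- function(center, radius) .sphere_voxels(center, radius, dm)
  for (k in seq_len(n_net)) {
    if (k <= n_hub) {
      h <- spec$hub_regions[[k]]
      core <- core_of(h$center, h$radius)
      sgn <- h$sign; mag <- h$magnitude
    } else {
      # extra background networks on random in-mask centers, no group effect
      ctr <- arrayInd(sample(in_mask, 1), dm)[1, ]
      core <- core_of(ctr, 2)
      sgn <- 0; mag <- 0
    }
    # distributed periphery: long-range members whose correlations with the
    # core are free of the local noise autocorrelation
    pool <- setdiff(in_mask, core)
    periph <- if (spec$n_periphery > 0 && length(pool) > 0) {
      sample(pool, min(spec$n_periphery, length(pool)))
    } else integer(0)
    vox <- c(core, periph)
    # fixed per-voxel loadings, spread so pairwise correlations straddle
    # the binarization threshold and respond to the group scaling. Regions
    # planted to lose connectivity start from the upper part of the range
    # (strong hubs in controls, with room to fall below the threshold);
    # regions planted to gain start lower, with room to rise across it.
    # This keeps the net group shift of total degree near zero, so the
    # per-subject z-standardization does not tilt the background.
    rng <- spec$loading_range
    if (mag > 0 && sgn > 0) {
      rng <- c(rng[1], rng[1] + 0.3 * diff(rng))
    } else if (mag > 0 && sgn < 0) {
      rng <- c(rng[1] + 0.4 * diff(rng), rng[2])
    }
    networks[[k]] <- list(
      voxels = vox,
      is_core = c(rep(TRUE, length(core)), rep(FALSE, length(periph))),
      sign = sgn, magnitude = mag,
      loading = stats::runif(length(vox), rng[1], rng[2])
    )
  }
  # per-subject motion severity (kept below the default QC thresholds) and
  # motion-trace seeds, drawn from the cohort stream: deriving subject seeds
  # arithmetically (seed + i) correlates the early draws of consecutive
  # Mersenne-Twister streams and would leak group structure into null data
  motion_mm <- stats::runif(n_sub, 0.05, 1.2)
  motion_deg <- stats::runif(n_sub, 0.05, 1.2)
  motion_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)

  # noise scaling: Gaussian smoothing shrinks the white-noise variance by
  # the sum of squared kernel weights per axis; rescale so the per-voxel
  # noise SD equals noise_sigma after smoothing (interior voxels)
  sigma_vox <- rep(.fwhm_to_sigma(spec$spatial_fwhm_mm) / spec$voxel_size_mm, 3)
  shrink <- prod(vapply(sigma_vox,
                        function(s) sqrt(sum(.gauss_kernel_1d(s)^2)),
                        numeric(1)))
  noise_scale <- spec$noise_sigma / shrink

  affine <- .ras_affine(spec$voxel_size_mm)
  bold <- vector("list", n_sub)
  motion <- vector("list", n_sub)
  is_patient <- meta$group == "patient"

  # ---- per-subject data, drawn sequentially from the cohort stream ----
  for (i in seq_len(n_sub)) {
    nvox <- prod(dm)
    sig_flat <- matrix(0, nrow = nvox, ncol = nt)
    for (k in seq_len(n_net)) {
      net <- networks[[k]]
      z <- .ar1_series(nt, spec$ar_coef)
      subj_gain <- max(0.5, stats::rnorm(1, 1, 0.05))
      # group scaling applies to the hub core only; the periphery is shared
      gamma <- rep(1, length(net$voxels))
      if (is_patient[i] && net$magnitude > 0) {
        gamma[net$is_core] <- 1 + net$sign * net$magnitude
      }
      sig_flat[net$voxels, ] <- sig_flat[net$voxels, , drop = FALSE] +
        (net$loading * subj_gain * gamma) %o% z
    }
    noise <- array(stats::rnorm(nvox * nt), dim = c(dm, nt))
    if (spec$spatial_fwhm_mm > 0) {
      noise <- .smooth3d(noise, sigma_vox)
    }
    vol <- array(sig_flat, dim = c(dm, nt)) + noise_scale * noise + 100
    bold[[i]] <- bold_series(vol, affine, spec$tr_seconds, meta$subject_id[i])
  }
  # motion traces last: generate_motion_trace() reseeds the global RNG, so
  # it must not interleave with the cohort stream above
  for (i in seq_len(n_sub)) {
    motion[[i]] <- generate_motion_trace(nt, motion_mm[i], motion_deg[i],
                                         seed = motion_seeds[i])
  }

  effect_mask <- array(FALSE, dim = dm)
  effect_dir <- array(0, dim = dm)
  for (k in seq_len(n_hub)) {
    net <- networks[[k]]
    if (net$magnitude > 0) {
      core_vox <- net$voxels[net$is_core]
      effect_mask[core_vox] <- TRUE
      effect_dir[core_vox] <- net$sign
    }
  }
  effect_mask <- effect_mask & mask_arr   # effects live inside the analysis mask
  effect_dir[!effect_mask] <- 0

  list(
    bold = bold,
    motion = motion,
    mask = volume_mask(mask_arr, "gray_matter"),
    cohort = meta,
    truth = list(effect_mask = effect_mask, effect_direction = effect_dir,
                 networks = lapply(networks, function(n)
                   n[c("voxels", "is_core", "sign", "magnitude")]),
                 spec = spec)
  )
}
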