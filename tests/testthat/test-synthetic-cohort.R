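test_that("cohort spec validates hub regions and sizes", {
  expect_error(cohort_spec(n_timepoints = 10), "at least 20")
  expect_error(
    cohort_spec(grid_shape = c(12, 12, 12),
                hub_regions = list(list(center = c(2, 6, 6), radius = 3,
                                        sign = 1, magnitude = 0.5))),
    "outside"
  )
  expect_error(
    cohort_spec(hub_regions = list(list(center = c(6, 6, 6), radius = 2,
                                        sign = 1, magnitude = -0.1))),
    "magnitude"
  )
})

test_that("generated cohorts are seed-deterministic", {
  spec <- cohort_spec(n_per_group = 3, grid_shape = c(12, 12, 12),
                      n_timepoints = 30, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(
    lapply(a$bold, function(s) s$data),
    lapply(b$bold, function(s) s$data)
  )
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$motion, b$motion)
})

test_that("default study-scale spec yields 142 series of 212 volumes", {
  spec <- cohort_spec()
  expect_equal(spec$n_per_group, 71L)
  expect_equal(spec$n_timepoints, 212L)
  expect_equal(spec$tr_seconds, 2)
  expect_equal(spec$voxel_size_mm, 3)
  ch <- generate_cohort(spec)
  expect_length(ch$bold, 142L)
  expect_true(all(vapply(ch$bold, function(b) dim(b$data)[4], numeric(1)) == 212))
  expect_equal(nrow(ch$cohort), 142L)
  rm(ch); gc(verbose = FALSE)
})

test_that("metadata matches the cohort eligibility and marginals", {
  spec <- cohort_spec(n_per_group = 60, grid_shape = c(12, 12, 12),
                      n_timepoints = 30, seed = 4)
  ch <- generate_cohort(spec)
  meta <- ch$cohort
  expect_false(any(duplicated(meta$subject_id)))
  pat <- meta[meta$group == "patient", ]
  ctl <- meta[meta$group == "control", ]
  expect_true(all(pat$hrsd17 >= 17))             # eligibility floor
  expect_true(all(ctl$hrsd17 >= 0))
  expect_true(mean(pat$hrsd17) > mean(ctl$hrsd17) + 5)
  expect_true(all(is.na(ctl$illness_duration_months)))
  expect_true(all(pat$illness_duration_months > 0 &
                  pat$illness_duration_months <= 12))
  expect_true(all(meta$age_years >= 14 & meta$age_years <= 18))
  # ~62% male with binomial slack at n = 120
  expect_gt(mean(meta$sex == "M"), 0.45)
  expect_lt(mean(meta$sex == "M"), 0.78)
})

test_that("null-effect groups are exchangeable voxel-wise", {
  spec <- cohort_spec(n_per_group = 20, grid_shape = c(12, 12, 12),
                      n_timepoints = 40, effect_magnitude = 0, seed = 77)
  ch <- generate_cohort(spec)
  expect_false(any(ch$truth$effect_mask))
  pat <- ch$cohort$group == "patient"
  vox <- sample(which(ch$mask$data), 50)
  # per-subject temporal SD at each probed voxel, compared across groups
  rej <- 0
  for (v in vox) {
    ijk <- arrayInd(v, dim(ch$mask$data))[1, ]
    vals <- vapply(ch$bold, function(b) {
      stats::sd(b$data[ijk[1], ijk[2], ijk[3], ])
    }, numeric(1))
    p <- suppressWarnings(stats::ks.test(vals[pat], vals[!pat])$p.value)
    rej <- rej + (p < 0.01)
  }
  expect_lte(rej, 4)  # ~nominal rejection rate at alpha = 0.01 over 50 voxels
})

test_that("same-network voxels correlate more than unrelated voxels", {
  ch <- small_planted_cohort(n_per_group = 4, n_timepoints = 80, seed = 11)
  b <- ch$bold[[1]]
  net <- ch$truth$networks[[1]]
  dm <- dim(ch$mask$data)
  Y <- matrix(b$data, prod(dm))
  members <- net$voxels[seq_len(min(25, length(net$voxels)))]
  # unrelated voxels: in mask, in no network, far enough apart to avoid
  # the local noise autocorrelation
  allnet <- unlist(lapply(ch$truth$networks, `[[`, "voxels"))
  free <- setdiff(which(ch$mask$data), allnet)
  free <- free[seq(1, length(free), by = 17)][1:25]
  cwithin <- stats::cor(t(Y[members, ]))
  cfree <- stats::cor(t(Y[free, ]))
  expect_gt(mean(cwithin[upper.tri(cwithin)]), mean(cfree[upper.tri(cfree)]))
})

test_that("planted effects shift brute-force degree in the planted direction", {
  ch <- small_planted_cohort(n_per_group = 8, n_timepoints = 100,
                             magnitude = 0.5, seed = 23)
  pat <- ch$cohort$group == "patient"
  dm <- dim(ch$mask$data)
  idx <- which(ch$mask$data)
  deg <- vapply(ch$bold, function(b) {
    X <- t(matrix(b$data, prod(dm))[idx, ])
    bf_degree(X)
  }, integer(length(idx)))
  pos <- which(ch$truth$effect_direction[idx] > 0)
  neg <- which(ch$truth$effect_direction[idx] < 0)
  expect_gt(mean(deg[pos, pat]), mean(deg[pos, !pat]))
  expect_lt(mean(deg[neg, pat]), mean(deg[neg, !pat]))
})

test_that("motion traces honor requested maxima and determinism", {
  zero <- generate_motion_trace(50, 0, 0, seed = 1)
  expect_true(all(zero == 0))
  tr <- generate_motion_trace(80, 2.5, 1.0, seed = 3)
  expect_equal(max(abs(tr[, 1:3])), 2.5)
  expect_equal(max(abs(tr[, 4:6])), 1.0)
  expect_identical(generate_motion_trace(40, 1, 1, seed = 5),
                   generate_motion_trace(40, 1, 1, seed = 5))
  expect_error(generate_motion_trace(40, -1, 0), "non-negative")
})
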