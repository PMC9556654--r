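# shared planted cohort for the heavier inference checks (built once)
.inference_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- small_planted_cohort(n_per_group = 15, n_timepoints = 100,
                                 seed = 42)
      maps <- cohort_dc_maps(ch)
      cache <<- list(cohort = ch, maps = maps)
    }
    cache
  }
})

test_that("group designs validate structure and rank", {
  expect_error(group_design(c("patient", "weird")), "patient")
  expect_error(group_design(c("patient", "control", "control")), "2 subjects")
  g <- rep(c("patient", "control"), each = 4)
  covs <- data.frame(age = stats::rnorm(8), dup = 1:8, dup2 = 2 * (1:8))
  expect_error(group_design(g, covs), "rank deficient")
  d <- group_design(g, data.frame(age = stats::rnorm(8),
                                  sex = rep(c("M", "F"), 4)))
  expect_equal(sum(d$contrast), 1)
  expect_equal(ncol(d$X), 4)
})

test_that("with no covariates the voxel t equals the pooled two-sample t", {
  # printed toy example, hand-derived: {1,2,3} vs {4,5,6} -> t = -3.674
  m <- lapply(c(1, 2, 3, 4, 5, 6), function(v) array(v, dim = c(1, 1, 1)))
  mask <- volume_mask(array(TRUE, dim = c(1, 1, 1)))
  d <- group_design(rep(c("patient", "control"), each = 3))
  stat <- fit_voxelwise_glm(m, d, mask)
  expect_equal(stat$tmap[1, 1, 1], -3.674, tolerance = 5e-4)
  expect_equal(stat$tmap[1, 1, 1], bf_pooled_t(1:3, 4:6), tolerance = 1e-12)
  expect_equal(stat$df, 4)

  # random maps, every voxel against the textbook formula
  set.seed(55)
  dims <- c(4, 3, 2)
  maps <- lapply(1:14, function(i) array(stats::rnorm(prod(dims)), dim = dims))
  maskr <- volume_mask(array(TRUE, dim = dims))
  dr <- group_design(rep(c("patient", "control"), c(6, 8)))
  statr <- fit_voxelwise_glm(maps, dr, maskr)
  for (v in sample(prod(dims), 8)) {
    a <- vapply(maps[1:6], function(m) m[v], numeric(1))
    b <- vapply(maps[7:14], function(m) m[v], numeric(1))
    expect_equal(statr$tmap[v], bf_pooled_t(a, b), tolerance = 1e-10)
  }
})

test_that("identical group map sets give a null t-map; label swap negates t", {
  set.seed(9)
  dims <- c(5, 5, 5)
  half <- lapply(1:6, function(i) array(stats::rnorm(125), dim = dims))
  mask <- volume_mask(array(TRUE, dim = dims))
  d <- group_design(rep(c("patient", "control"), each = 6))
  stat0 <- fit_voxelwise_glm(c(half, half), d, mask)
  expect_lt(max(abs(stat0$tmap)), 1e-8)

  maps <- lapply(1:12, function(i) array(stats::rnorm(125), dim = dims))
  covs <- data.frame(age = stats::rnorm(12))
  d1 <- group_design(rep(c("patient", "control"), each = 6), covs)
  d2 <- group_design(rep(c("control", "patient"), each = 6), covs)
  s1 <- fit_voxelwise_glm(maps, d1, mask)
  s2 <- fit_voxelwise_glm(maps, d2, mask)
  expect_equal(s1$tmap, -s2$tmap, tolerance = 1e-10)
})

test_that("smoothness estimation recovers a known kernel and is monotone", {
  set.seed(12)
  dims <- c(16, 16, 16)
  mask_arr <- array(FALSE, dim = dims)
  mask_arr[4:13, 4:13, 4:13] <- TRUE       # interior box avoids edge effects
  mask <- volume_mask(mask_arr)
  mk <- function(fwhm) {
    lapply(1:10, function(i) {
      smooth_volume(array(stats::rnorm(prod(dims)), dim = dims), fwhm,
                    voxel_size_mm = 3)
    })
  }
  sm6 <- estimate_smoothness(mk(6), mask, 3)
  expect_lt(max(abs(sm6$fwhm_mm - 6)) / 6, 0.15)
  sm0 <- estimate_smoothness(mk(0), mask, 3)
  expect_true(all(sm0$fwhm_mm < sm6$fwhm_mm))
  expect_lt(max(sm0$fwhm_mm), 4)           # white noise: about voxel scale
  sm12 <- estimate_smoothness(mk(12), mask, 3)
  expect_true(all(sm12$fwhm_mm > sm6$fwhm_mm))
  expect_gt(sm0$resel_count, sm6$resel_count)
})

test_that("a null t-map yields an empty cluster table", {
  set.seed(2)
  dims <- c(8, 8, 8)
  maps <- lapply(1:16, function(i) array(stats::rnorm(512, sd = 1e-3) +
                                           7, dim = dims))
  mask <- volume_mask(array(TRUE, dim = dims))
  d <- group_design(rep(c("patient", "control"), each = 8))
  stat <- fit_voxelwise_glm(maps, d, mask)
  ct <- grf_cluster_correct(stat, min_extent = 1, voxel_size_mm = 3)
  expect_s3_class(ct, "cluster_table")
  expect_equal(nrow(ct), 0)
})

test_that("cluster reports map voxels to world mm and sort by |t|", {
  tb <- data.frame(
    cluster_id = 1:2, sign = c("increase", "decrease"),
    peak_x_mm = 0, peak_y_mm = 0, peak_z_mm = 0,
    peak_i = c(11, 3), peak_j = c(11, 4), peak_k = c(11, 5),
    n_voxels = c(105, 199), peak_t = c(9.5, -11.4),
    corrected_p = c(0.001, 0.0005))
  class(tb) <- c("cluster_table", "data.frame")
  aff <- diag(c(3, 3, 3, 1))
  rep <- report_clusters(tb, aff)
  # 0-based voxel (10,10,10) at 3 mm -> 30 mm on each axis
  expect_equal(unlist(rep[rep$peak_t > 0, c("peak_x_mm", "peak_y_mm", "peak_z_mm")],
                      use.names = FALSE), c(30, 30, 30))
  expect_equal(rep$peak_t, c(-11.4, 9.5))  # larger |t| first, sign kept
  empty <- grf_cluster_correct(
    fit_voxelwise_glm(lapply(1:8, function(i) array(stats::rnorm(27), c(3, 3, 3))),
                      group_design(rep(c("patient", "control"), each = 4)),
                      volume_mask(array(TRUE, c(3, 3, 3)))),
    min_extent = 1e6, voxel_size_mm = 3)
  expect_equal(nrow(report_clusters(empty, aff)), 0)
  expect_true(all(c("sign", "n_voxels", "peak_t", "corrected_p") %in%
                  names(empty)))
})

test_that("planted effects survive GRF correction with matching signs", {
  fx <- .inference_fixture()
  d <- group_design(fx$cohort$cohort$group,
                    fx$cohort$cohort[, c("age_years", "sex")])
  stat <- fit_voxelwise_glm(fx$maps, d, fx$cohort$mask,
                            fx$cohort$bold[[1]]$affine)
  ct <- grf_cluster_correct(stat, min_extent = 10, voxel_size_mm = 3)
  expect_gte(nrow(ct), 2)
  expect_setequal(unique(ct$sign), c("increase", "decrease"))
  rec <- planted_recovery(ct, fx$cohort$truth, fx$cohort$mask)
  expect_true(all(rec$best_dice > 0.3))   # recovery; exact geometry tested at scale
})

test_that("permutation correction is seed-stable and agrees with GRF", {
  fx <- .inference_fixture()
  d <- group_design(fx$cohort$cohort$group,
                    fx$cohort$cohort[, c("age_years", "sex")])
  p1 <- permutation_cluster_correct(fx$maps, d, fx$cohort$mask,
                                    n_perm = 200, seed = 5, min_extent = 10)
  p2 <- permutation_cluster_correct(fx$maps, d, fx$cohort$mask,
                                    n_perm = 200, seed = 5, min_extent = 10)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  stat <- fit_voxelwise_glm(fx$maps, d, fx$cohort$mask)
  g <- grf_cluster_correct(stat, min_extent = 10, voxel_size_mm = 3)
  dice <- dice_coefficient(attr(g, "label_map") > 0,
                           attr(p1, "label_map") > 0)
  expect_gt(dice, 0.5)
})

test_that("GRF corrected p decreases with cluster extent", {
  q <- dcnet:::.rft_cluster_quantities(2.7, 40, c(1, 10, 40, 60), 2000)
  p <- vapply(c(5, 20, 60, 150), dcnet:::.rft_cluster_p, numeric(1),
              Em = q$Em, EN = q$EN)
  expect_true(all(diff(p) < 0))
})
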