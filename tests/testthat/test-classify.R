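test_that("confusion metrics reproduce printed worked examples exactly", {
  m <- confusion_metrics(tp = 70, fn = 6, tn = 66, fp = 1)
  expect_equal(round(m$accuracy_pct, 1), 95.1)
  expect_equal(round(m$sensitivity_pct, 1), 92.1)
  expect_equal(round(m$specificity_pct, 1), 98.5)
  expect_equal(m$correct, 136); expect_equal(m$total, 143)
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)
  worst <- confusion_metrics(0, 7, 0, 7)
  expect_equal(worst$accuracy_pct, 0)
  expect_error(confusion_metrics(0, 0, 3, 1), "positive")
  expect_error(confusion_metrics(-1, 2, 3, 1), "non-negative")
})

test_that("accuracy is the class-size weighted mix of sensitivity and specificity", {
  set.seed(3)
  for (i in 1:20) {
    tp <- sample(0:30, 1); fn <- sample(1:10, 1)
    tn <- sample(0:30, 1); fp <- sample(1:10, 1)
    m <- confusion_metrics(tp, fn, tn, fp)
    npos <- tp + fn; nneg <- tn + fp
    expect_equal(m$accuracy_pct * (npos + nneg),
                 m$sensitivity_pct * npos + m$specificity_pct * nneg,
                 tolerance = 1e-9)
    expect_gte(m$accuracy_pct, min(m$sensitivity_pct, m$specificity_pct))
    expect_lte(m$accuracy_pct, max(m$sensitivity_pct, m$specificity_pct))
  }
})

test_that("well-separated classes are classified near perfectly", {
  set.seed(11)
  x <- matrix(c(stats::rnorm(50, -5), stats::rnorm(50, 5)), ncol = 1)
  y <- rep(c("control", "patient"), each = 50)
  cfg <- svm_config(C_grid = 2^seq(-2, 6, 2), gamma_grid = 2^seq(-4, 2, 2))
  gs <- grid_search_svm(x, y, cfg)
  expect_gte(gs$cv_accuracy, 0.98)
})

test_that("grid search is deterministic and breaks ties toward smaller C, gamma", {
  set.seed(21)
  x <- matrix(stats::rnorm(40), ncol = 2)
  y <- rep(c("patient", "control"), 10)
  cfg <- svm_config(C_grid = c(1, 4), gamma_grid = c(0.25, 1),
                    cv_scheme = "k_fold", k = 5, seed = 7)
  a <- grid_search_svm(x, y, cfg)
  b <- grid_search_svm(x, y, cfg)
  expect_identical(a[c("best_C", "best_gamma", "cv_accuracy")],
                   b[c("best_C", "best_gamma", "cv_accuracy")])
  ties <- a$grid[a$grid$accuracy == max(a$grid$accuracy), ]
  expect_equal(a$best_C, min(ties$C))
  expect_equal(a$best_gamma, min(ties$gamma[ties$C == a$best_C]))
})

test_that("permuted labels score at chance under an unbiased protocol", {
  set.seed(31)
  x <- matrix(stats::rnorm(80), ncol = 2)   # pure noise features
  y <- sample(rep(c("patient", "control"), each = 20))
  # single-point grid: plain LOOCV accuracy, no selection optimism
  cfg <- svm_config(C_grid = 1, gamma_grid = 0.5)
  accs <- vapply(1:12, function(i) {
    grid_search_svm(x, sample(y), cfg)$cv_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.30)
  expect_lt(mean(accs), 0.70)
})

test_that("fold-wise scalers never use test-fold observations", {
  set.seed(41)
  x <- matrix(stats::rnorm(60), ncol = 2)
  y <- rep(c("patient", "control"), 15)
  folds <- list(1:10, 11:20, 21:30)
  cv <- svm_cv_predict(x, y, C = 1, gamma = 0.5, folds)
  for (f in seq_along(folds)) {
    train <- setdiff(1:30, folds[[f]])
    expect_equal(cv$scalers[[f]]$center, colMeans(x[train, ]))
  }
  # perturbing a test subject leaves its fold's training scaler unchanged
  x2 <- x; x2[folds[[2]], 1] <- x2[folds[[2]], 1] + 100
  cv2 <- svm_cv_predict(x2, y, C = 1, gamma = 0.5, folds)
  expect_identical(cv$scalers[[2]], cv2$scalers[[2]])
})

test_that("per-region evaluation ranks the informative region first", {
  set.seed(51)
  n <- 40
  tb <- data.frame(
    region_1 = c(stats::rnorm(n / 2, 2), stats::rnorm(n / 2, -2)),
    region_2 = stats::rnorm(n),
    region_3 = stats::rnorm(n),
    group = rep(c("patient", "control"), each = n / 2)
  )
  cfg <- svm_config(C_grid = 2^c(-2, 2), gamma_grid = 2^c(-2, 2))
  res <- evaluate_per_region(tb, cfg)
  expect_equal(res$top_region, "region_1")
  expect_gte(res$reports$region_1$cv_accuracy, 0.9)
  joint <- res$reports$all_regions$cv_accuracy
  expect_gte(joint, res$reports$region_1$cv_accuracy - 0.05)
  r <- res$reports$region_1
  expect_equal(r$tp + r$fn, n / 2)
  expect_equal(r$tn + r$fp, n / 2)
})

test_that("nested cross-validation removes grid-selection optimism", {
  set.seed(61)
  x <- matrix(stats::rnorm(40), ncol = 1)   # null feature
  y <- rep(c("patient", "control"), each = 20)
  cfg <- svm_config(C_grid = 2^c(-2, 2, 6), gamma_grid = 2^c(-4, 0, 4))
  paperish <- grid_search_svm(x, y, cfg)$cv_accuracy
  nested <- nested_cv_svm(x, y, cfg, inner_k = 5)$cv_accuracy
  expect_gte(paperish, nested)              # optimism is one-directional
  expect_lt(nested, 0.75)
})
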