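#' Extract mean regional DC features
#'
#' Computes, per subject and labeled region, the arithmetic mean of the
#' standardized DC map over the region's voxels, and joins the cohort
#' metadata by subject id. The regions are typically the surviving clusters
#' of the group analysis (the `label_map` attribute of a cluster table) or
#' ground-truth region masks.
#'
#' @param dc_maps list of [dc_map()]s or 3D arrays.
#' @param cluster_labels integer 3D array; 0 is background, positive values
#'   label regions.
#' @param cohort optional metadata data.frame with a `subject_id` column,
#'   one row per map in order.
#' @return A data.frame with one row per subject: `subject_id`, one
#'   `region_<k>` column per label, plus the cohort columns.
#' @export
extract_region_features <- function(dc_maps, cluster_labels, cohort = NULL) {
  labs <- sort(unique(cluster_labels[cluster_labels > 0]))
  if (length(labs) == 0L) stop("label map contains no regions")
  region_idx <- lapply(labs, function(l) which(cluster_labels == l))
  if (any(vapply(region_idx, length, integer(1)) == 0L)) {
    stop("empty region in label map")
  }
  feats <- t(vapply(dc_maps, function(m) {
    arr <- if (inherits(m, "dc_map")) m$standardized else m
    stopifnot(identical(dim(arr), dim(cluster_labels)))
    vapply(region_idx, function(ix) mean(arr[ix]), numeric(1))
  }, numeric(length(labs))))
  feats <- matrix(feats, ncol = length(labs))
  colnames(feats) <- sprintf("region_%d", labs)
  ids <- vapply(seq_along(dc_maps), function(i) {
    m <- dc_maps[[i]]
    if (inherits(m, "dc_map")) m$subject_id else sprintf("sub-%03d", i)
  }, character(1))
  out <- data.frame(subject_id = ids, feats, stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    stopifnot("subject_id" %in% names(cohort))
    out <- merge(out, cohort, by = "subject_id", sort = FALSE)
  }
  out
}

#' Correlate regional DC features with clinical variables
#'
#' For every region x clinical-variable pair, computes either the Pearson
#' correlation with its two-sided p-value, or (method
#' `"multiple_regression"`) regresses the region's DC on all clinical
#' variables jointly and reports each coefficient's t and p. P-values are
#' corrected across the whole region x variable family. Pairs involving a
#' zero-variance variable are reported with NA statistics rather than
#' propagating NaN. Variables observed only in patients (illness duration)
#' are automatically analyzed on the complete-case subset.
#'
#' @param table feature table from [extract_region_features()].
#' @param clinical_vars character vector of column names to test (default
#'   HRSD-17, illness duration, age).
#' @param method "pearson" or "multiple_regression".
#' @param correction "bonferroni" or "fdr_bh".
#' @return Long-format data.frame: region, variable, estimate (r or
#'   regression t), p, p_corrected, n.
#' @export
correlate_with_clinical <- function(table,
                                    clinical_vars = c("hrsd17",
                                                      "illness_duration_months",
                                                      "age_years"),
                                    method = c("pearson", "multiple_regression"),
                                    correction = c("bonferroni", "fdr_bh")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  regions <- grep("^region_", names(table), value = TRUE)
  stopifnot(length(regions) > 0, all(clinical_vars %in% names(table)))
  rows <- list()
  if (method == "pearson") {
    for (rg in regions) {
      for (cv in clinical_vars) {
        ok <- stats::complete.cases(table[[rg]], table[[cv]])
        x <- table[[rg]][ok]; y <- as.numeric(table[[cv]][ok])
        n <- sum(ok)
        if (n < 3 || stats::sd(y) == 0 || stats::sd(x) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, variable = cv, estimate = NA_real_, p = NA_real_,
            n = n, stringsAsFactors = FALSE)
          next
        }
        ct <- stats::cor.test(x, y, method = "pearson")
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, variable = cv, estimate = unname(ct$estimate),
          p = ct$p.value, n = n, stringsAsFactors = FALSE)
      }
    }
  } else {
    for (rg in regions) {
      dat <- table[, c(rg, clinical_vars)]
      dat <- dat[stats::complete.cases(dat), , drop = FALSE]
      dat[] <- lapply(dat, function(v) if (is.character(v)) factor(v) else v)
      keep <- vapply(clinical_vars, function(cv) {
        v <- dat[[cv]]
        length(unique(v)) > 1
      }, logical(1))
      fml <- stats::reformulate(clinical_vars[keep], response = rg)
      fit <- summary(stats::lm(fml, data = dat))$coefficients
      for (cv in clinical_vars) {
        hit <- grep(paste0("^", cv), rownames(fit))
        if (!keep[cv] || length(hit) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, variable = cv, estimate = NA_real_, p = NA_real_,
            n = nrow(dat), stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, variable = cv, estimate = fit[hit[1], "t value"],
            p = fit[hit[1], "Pr(>|t|)"], n = nrow(dat),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  meth <- if (correction == "bonferroni") "bonferroni" else "BH"
  out$p_corrected <- NA_real_
  ok <- !is.na(out$p)
  out$p_corrected[ok] <- stats::p.adjust(out$p[ok], method = meth)
  out
}
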