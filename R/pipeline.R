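#' Default end-to-end run configuration
#'
#' One flat namespace per stage; every analysis parameter defaults to the
#' protocol value of the study the pipeline emulates (discard 5 volumes,
#' 2 mm / 2 deg motion limits, 0.01-0.1 Hz band, 8 mm preprocessing and
#' 6 mm DC smoothing, r > 0.25 binarization, cluster-forming voxel
#' p = 0.01, alpha = 0.05). Simulation parameters default to a desk-scale
#' cohort so a full run finishes in seconds to minutes.
#'
#' @param ... named overrides of any default, e.g. `simulate.n_per_group`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    simulate = list(enabled = TRUE, n_per_group = 12L,
                    grid_shape = c(16L, 16L, 16L), voxel_size_mm = 3,
                    n_timepoints = 100L, tr_seconds = 2,
                    effect_magnitude = 0.5, n_latents = 5L, ar_coef = 0.3,
                    noise_sigma = 1, spatial_fwhm_mm = 6, seed = 1L),
    preprocess = list(n_discard = 5L, threshold_mm = 2, threshold_deg = 2,
                      low_hz = 0.01, high_hz = 0.1, smooth_fwhm_mm = 0),
    dc = list(threshold_r = 0.25, smooth_fwhm_mm = 6, method = "zscore",
              chunk_size = 256L),
    infer = list(voxel_p = 0.01, alpha = 0.05, method = "grf",
                 connectivity = 26L, min_extent = 5L, n_perm = 500L,
                 covariates = c("age_years", "sex"), seed = 1L),
    correlate = list(clinical_vars = c("hrsd17", "illness_duration_months",
                                       "age_years"),
                     method = "pearson", correction = "bonferroni"),
    classify = list(C_exp = seq(-6, 6, by = 2), gamma_exp = seq(-6, 6, by = 2),
                    cv_scheme = "leave_one_out", k = 10L, seed = 1L)
  )
  over <- list(...)
  for (nm in names(over)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]])) {
      stop(sprintf("unknown config field '%s'", nm))
    }
    cfg[[parts[1]]][[parts[2]]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' Round-trip faithful: `load_run_config(save_run_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (save) or the `run_config` (load).
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  for (stage in names(cfg)) {
    for (nm in names(cfg[[stage]])) {
      tmpl <- base[[stage]][[nm]]
      val <- cfg[[stage]][[nm]]
      if (is.integer(tmpl)) val <- as.integer(val)
      if (is.numeric(tmpl) && !is.integer(tmpl)) val <- as.numeric(val)
      base[[stage]][[nm]] <- if (length(val) > 1) unlist(val) else val
    }
  }
  base
}

# Stable md5 of a config (via its canonical YAML serialization).
.config_checksum <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Run the full degree-centrality analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> DC -> group inference ->
#' clinical correlation -> classification, writing every stage artifact
#' under `out_dir` and returning a manifest of configuration and output
#' checksums. Deterministic stages re-run with an identical config produce
#' identical checksums; when a manifest from a previous run with the same
#' config checksum is found, completed stage outputs are reused.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param cohort optionally, a pre-generated [generate_cohort()] result to
#'   analyze instead of simulating (set `config$simulate$enabled = FALSE`
#'   to require this).
#' @return The run manifest (list), invisibly writable as JSON; contains
#'   `config_checksum`, per-stage file checksums, counts, warnings and
#'   timestamps, plus the in-memory stage results in `results`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("dcnet_run_"),
                         cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_checksum = .config_checksum(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list(), warnings = character(0))
  note <- function(stage, msg) {
    manifest$warnings <<- c(manifest$warnings, sprintf("[%s] %s", stage, msg))
    message(sprintf("dcnet [%s] %s", stage, msg))
  }
  fail <- function(stage, e, id = NULL) {
    stop(sprintf("pipeline stage '%s' failed%s: %s", stage,
                 if (is.null(id)) "" else sprintf(" (subject %s)", id),
                 conditionMessage(e)), call. = FALSE)
  }

  # ---- simulate -------------------------------------------------------
  if (is.null(cohort)) {
    if (!isTRUE(config$simulate$enabled)) {
      stop("no cohort supplied and simulation is disabled in the config")
    }
    sc <- config$simulate
    spec <- cohort_spec(n_per_group = sc$n_per_group,
                        grid_shape = sc$grid_shape,
                        voxel_size_mm = sc$voxel_size_mm,
                        n_timepoints = sc$n_timepoints,
                        tr_seconds = sc$tr_seconds,
                        effect_magnitude = sc$effect_magnitude,
                        n_latents = sc$n_latents, ar_coef = sc$ar_coef,
                        noise_sigma = sc$noise_sigma,
                        spatial_fwhm_mm = sc$spatial_fwhm_mm, seed = sc$seed)
    cohort <- tryCatch(generate_cohort(spec), error = function(e)
      fail("simulate", e))
  }
  affine <- cohort$bold[[1]]$affine
  voxmm <- .voxel_sizes(affine)
  manifest$stages$simulate <- list(n_subjects = length(cohort$bold))

  # ---- preprocess -----------------------------------------------------
  pp <- config$preprocess
  kept <- list(); kept_rows <- integer(0); reports <- list()
  for (i in seq_along(cohort$bold)) {
    id <- cohort$bold[[i]]$subject_id
    res <- tryCatch(
      preprocess_bold(cohort$bold[[i]], cohort$motion[[i]],
                      n_discard = pp$n_discard,
                      threshold_mm = pp$threshold_mm,
                      threshold_deg = pp$threshold_deg,
                      low_hz = pp$low_hz, high_hz = pp$high_hz,
                      smooth_fwhm_mm = pp$smooth_fwhm_mm),
      error = function(e) fail("preprocess", e, id))
    reports[[i]] <- res$report
    if (is.null(res$series)) {
      note("preprocess", sprintf("subject %s excluded: %s", id,
                                 res$report$reason))
    } else {
      kept[[length(kept) + 1L]] <- res$series
      kept_rows <- c(kept_rows, i)
    }
  }
  qc_report <- do.call(rbind, reports)
  utils::write.csv(qc_report, file.path(out_dir, "preprocess_report.csv"),
                   row.names = FALSE)
  if (length(kept) < 4L) stop("pipeline stage 'preprocess' failed: fewer than 4 subjects retained")
  cohort_kept <- cohort$cohort[kept_rows, , drop = FALSE]
  manifest$stages$preprocess <- list(n_retained = length(kept),
                                     n_excluded = sum(qc_report$excluded))

  # ---- degree centrality ----------------------------------------------
  dcc <- config$dc
  maps <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    maps[[i]] <- tryCatch(withCallingHandlers(
      dc_pipeline(kept[[i]], cohort$mask, threshold_r = dcc$threshold_r,
                  smooth_fwhm_mm = dcc$smooth_fwhm_mm, method = dcc$method,
                  chunk_size = dcc$chunk_size),
      warning = function(w) {
        note("dc", sprintf("subject %s: %s", kept[[i]]$subject_id,
                           conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) fail("dc", e, kept[[i]]$subject_id))
  }
  dc_dir <- file.path(out_dir, "dc"); dir.create(dc_dir, showWarnings = FALSE)
  for (m in maps) {
    write_volume(m$standardized, affine,
                 file.path(dc_dir, paste0(m$subject_id, "_dcz.nii.gz")))
  }
  manifest$stages$dc <- list(n_maps = length(maps),
                             threshold_r = dcc$threshold_r)

  # ---- group inference ------------------------------------------------
  inf <- config$infer
  cov_df <- if (length(inf$covariates))
    cohort_kept[, inf$covariates, drop = FALSE] else NULL
  design <- tryCatch(group_design(cohort_kept$group, cov_df),
                     error = function(e) fail("infer", e))
  stat <- tryCatch(fit_voxelwise_glm(maps, design, cohort$mask, affine),
                   error = function(e) fail("infer", e))
  clusters <- tryCatch({
    if (identical(inf$method, "perm")) {
      permutation_cluster_correct(maps, design, cohort$mask,
                                  voxel_p = inf$voxel_p, n_perm = inf$n_perm,
                                  seed = inf$seed, alpha = inf$alpha,
                                  connectivity = inf$connectivity,
                                  min_extent = inf$min_extent,
                                  affine = affine)
    } else {
      grf_cluster_correct(stat, voxel_p = inf$voxel_p, alpha = inf$alpha,
                          connectivity = inf$connectivity,
                          min_extent = inf$min_extent,
                          voxel_size_mm = voxmm)
    }
  }, error = function(e) fail("infer", e))
  write_volume(stat$tmap, affine, file.path(out_dir, "tmap.nii.gz"))
  label_map <- attr(clusters, "label_map")
  write_volume(label_map, affine, file.path(out_dir, "cluster_labels.nii.gz"))
  write_cluster_table(clusters, file.path(out_dir, "clusters.csv"))
  manifest$stages$infer <- list(method = inf$method,
                                n_clusters = nrow(clusters),
                                threshold_t = attr(clusters, "threshold_t"))

  # ---- clinical correlation & classification --------------------------
  if (nrow(clusters) > 0L) {
    features <- tryCatch(
      extract_region_features(maps, label_map, cohort_kept),
      error = function(e) fail("correlate", e))
    # illness duration exists only for patients; Pearson runs on complete cases
    corr <- tryCatch(
      correlate_with_clinical(features,
                              clinical_vars = config$correlate$clinical_vars,
                              method = config$correlate$method,
                              correction = config$correlate$correction),
      error = function(e) fail("correlate", e))
    utils::write.csv(corr, file.path(out_dir, "clinical_correlation.csv"),
                     row.names = FALSE)
    cls <- config$classify
    cfg_svm <- svm_config(C_grid = 2^cls$C_exp, gamma_grid = 2^cls$gamma_exp,
                          cv_scheme = cls$cv_scheme, k = cls$k,
                          seed = cls$seed)
    class_res <- tryCatch(evaluate_per_region(features, cfg_svm),
                          error = function(e) fail("classify", e))
    summ <- do.call(rbind, lapply(names(class_res$reports), function(nm) {
      r <- class_res$reports[[nm]]
      data.frame(feature_set = nm, accuracy_pct = r$accuracy_pct,
                 sensitivity_pct = r$sensitivity_pct,
                 specificity_pct = r$specificity_pct,
                 best_C = r$best_C, best_gamma = r$best_gamma,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(summ, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(class_res$reports, function(r) r[setdiff(names(r), "predicted")]),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$stages$classify <- list(top_region = class_res$top_region)
  } else {
    note("infer", "no surviving clusters; correlation and classification skipped")
    features <- NULL; corr <- NULL; class_res <- NULL
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$output_checksums <- as.list(tools::md5sum(files))
  names(manifest$output_checksums) <-
    substring(files, nchar(out_dir) + 2L)
  json_manifest <- manifest
  jsonlite::write_json(json_manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- list(cohort = cohort, qc = qc_report, dc_maps = maps,
                           stat = stat, clusters = clusters,
                           features = features, correlation = corr,
                           classification = class_res)
  invisible(manifest)
}
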