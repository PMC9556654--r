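# dcnet — voxel-wise degree centrality analysis of resting-state fMRI

`dcnet` is an R package for case-control analysis of resting-state BOLD
fMRI via **binarized degree centrality (DC)**: a graph-theoretic hubness
measure in which every gray-matter voxel is a node and an edge exists
wherever the Pearson correlation between two voxels' time series exceeds
a threshold. It is aimed at neuroimaging researchers who want a tested,
scriptable, end-to-end DC pipeline — and a synthetic-cohort generator
with *known planted effects* against which every stage of that pipeline
is validated.

For voxel *i* with time series *x<sub>i</sub>*,

> DC(i) = #{ j ≠ i in mask : r(x<sub>i</sub>, x<sub>j</sub>) > r₀ },  r₀ = 0.25

Degree maps are z-scored within the mask, Z(i) = (DC(i) − μ)/σ, smoothed,
and compared voxel-by-voxel between groups with an ANCOVA-style GLM
(age and sex covariates by default). Suprathreshold clusters (two-tailed
voxel p = 0.01) are corrected at the cluster level by Gaussian
random-field theory or by a Freedman–Lane permutation test on maximal
cluster extent. Mean standardized DC over each surviving cluster then
feeds (a) Pearson / multiple-regression correlation with clinical scores
under multiple-comparison correction, and (b) an RBF-kernel SVM
classifier with grid-searched C and γ and cross-validated accuracy,
sensitivity, and specificity.

The pipeline stages are:

| stage | function | what it does |
|---|---|---|
| simulate | `generate_cohort()` | two-group synthetic BOLD cohort with planted hub effects, motion traces, Table-1-style metadata |
| preprocess | `preprocess_bold()` | discard initial volumes, motion QC (2 mm / 2°), detrend + nuisance regression, 0.01–0.1 Hz zero-phase bandpass, Gaussian smoothing |
| dc | `dc_pipeline()` | chunked voxel-wise degree (r > 0.25), z-standardization, smoothing |
| infer | `fit_voxelwise_glm()`, `grf_cluster_correct()`, `permutation_cluster_correct()` | voxel-wise group GLM and cluster-level correction |
| correlate | `extract_region_features()`, `correlate_with_clinical()` | regional DC vs clinical variables with correction |
| classify | `grid_search_svm()`, `nested_cv_svm()`, `evaluate_per_region()`, `confusion_metrics()` | per-region and joint RBF-SVM discrimination |

`run_pipeline()` ties all stages together under a YAML-serializable
configuration (every analysis parameter defaults to the conventional
protocol value), and `inst/cli/dcnet.R` is a thin command-line wrapper
for the `simulate` and `run` entry points.

## Worked example

Simulate a 30+30-subject cohort with three planted DC increases and
three decreases (magnitude 0.5, 212 volumes at TR = 2 s), preprocess,
map degree centrality, test the group difference, and classify from the
surviving clusters:

```r
library(dcnet)

dm  <- rep(20L, 3); ctr <- floor((dm + 1) / 2)
mk  <- function(center, sign) list(center = center, radius = 2.5,
                                   sign = sign, magnitude = 0.5)
hubs <- list(mk(ctr + c(-6, 0, 0), +1), mk(ctr + c(6, 0, 0), +1),
             mk(ctr + c(0, -6, 0), +1), mk(ctr + c(0, 6, 0), -1),
             mk(ctr + c(0, 0, -6), -1), mk(ctr + c(0, 0, 6), -1))
spec <- cohort_spec(n_per_group = 30, grid_shape = dm, n_timepoints = 212,
                    hub_regions = hubs, seed = 1)
cohort <- generate_cohort(spec)

pp   <- mapply(function(b, m) preprocess_bold(b, m, smooth_fwhm_mm = 0),
               cohort$bold, cohort$motion, SIMPLIFY = FALSE)
maps <- lapply(pp, function(x) dc_pipeline(x$series, cohort$mask,
                                           smooth_fwhm_mm = 0))

design   <- group_design(cohort$cohort$group,
                         cohort$cohort[, c("age_years", "sex")])
stat     <- fit_voxelwise_glm(maps, design, cohort$mask,
                              cohort$bold[[1]]$affine)
clusters <- grf_cluster_correct(stat, min_extent = 20, voxel_size_mm = 3)
as.data.frame(clusters)[, c("sign", "peak_x_mm", "peak_y_mm", "peak_z_mm",
                            "n_voxels", "peak_t", "corrected_p")]
#>       sign peak_x_mm peak_y_mm peak_z_mm n_voxels peak_t corrected_p
#> 1 decrease        21        48        30       81 -11.75    2.71e-13
#> 2 decrease        30        33        12       81 -11.00    2.71e-13
#> 3 decrease        24        24        51       80 -10.36    3.56e-13
#> 4 increase         6        21        24       81   7.75    2.71e-13
#> 5 increase        45        21        27       81   7.54    2.71e-13
#> 6 increase        30        15        27       76   5.84    1.07e-12

mean(planted_recovery(clusters, cohort$truth, cohort$mask)$best_dice)
#> [1] 0.987

features <- extract_region_features(maps, attr(clusters, "label_map"),
                                    cohort$cohort)
evaluate_per_region(features, svm_config(C_grid = 2^seq(-4, 8, 2),
                                         gamma_grid = 2^seq(-6, 4, 2)))
#> <classification_report_set>
#>   region_1     acc  80.0% (48/60)  sens  90.0%  spec  70.0%  C=1 g=0.015625
#>   region_2     acc  88.3% (53/60)  sens  93.3%  spec  83.3%  C=0.0625 g=0.25
#>   region_3     acc  93.3% (56/60)  sens  96.7%  spec  90.0%  C=0.25 g=4
#>   region_4     acc  96.7% (58/60)  sens  96.7%  spec  96.7%  C=1 g=1
#>   region_5     acc  98.3% (59/60)  sens 100.0%  spec  96.7%  C=0.25 g=4
#>   region_6     acc  98.3% (59/60)  sens 100.0%  spec  96.7%  C=0.0625 g=0.25
#>   all_regions  acc 100.0% (60/60)  sens 100.0%  spec 100.0%  C=0.0625 g=0.0625
#>   top region: region_5
```

The cluster table is the package's analogue of a published
significant-cluster report: each row is a suprathreshold cluster with
its peak world coordinate (mm, from the image affine), extent in voxels,
peak t value (negative for DC decreases in patients), and
family-wise-corrected p. All six planted regions are recovered — three
increases and three decreases, with Dice overlap 0.987 against the
planted spheres. The classification report shows, per region and for
all regions jointly, the cross-validated accuracy (with its integer
counts), sensitivity (patients correctly identified), specificity
(controls correctly identified), and the selected SVM hyperparameters;
this is the maximal-grid-accuracy protocol, so read the percentages
with its optimism in mind (see `nested_cv_svm()` for the unbiased
estimator).

On real data, replace the simulated inputs with `read_bold()` /
`read_motion_trace()` / `read_volume()` on your own NIfTI volumes and
realignment-parameter files.

## The methods vignette

`vignettes/degree-centrality-workflow.Rmd` documents the models and
assumptions stage by stage: the degree/standardization conventions, the
zero-phase filter design, the smoothness/resel estimation behind the
random-field correction, the permutation scheme, the biased-vs-nested
classification protocols, what the synthetic generator does and does not
emulate, and the calibration reasoning behind its defaults.
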