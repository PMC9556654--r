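---
title: "Voxel-wise degree centrality analysis: models, parameters, and validation"
author: "dcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise degree centrality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`dcnet` implements a complete resting-state fMRI degree-centrality (DC)
workflow for two-group case-control studies: per-subject voxel-wise
binarized DC maps, voxel-wise group inference with cluster-level
correction, DC-clinical correlation analysis, and RBF-SVM classification
of patients versus controls from regional DC features. Because raw
clinical fMRI data of this kind are not publicly distributable, the
package also ships a synthetic-cohort generator that emulates the
acquisition and produces data with *known* planted group differences, so
every stage of the pipeline can be validated quantitatively.

Degree centrality treats every in-mask voxel as a node of a functional
graph. For voxel $i$ with BOLD time series $x_i$, the binarized degree is

$$ DC(i) = \#\{\, j \ne i : r(x_i, x_j) > r_0 \,\} $$

with Pearson correlation $r$ and threshold $r_0 = 0.25$ by default. The
strict inequality follows the conventional protocol; negative
correlations are discarded, not folded in by absolute value. Degree maps
are z-scored within the gray-matter mask,
$Z(i) = (DC(i) - \mu_{mask})/\sigma_{mask}$, and optionally smoothed
(6 mm FWHM default). A weighted variant replaces the unit edge weight by
the Fisher transform $\operatorname{atanh}(r)$ of each suprathreshold
correlation (`method = "fisher_weighted"`); the binarized count with
z-scoring is the default because the two operations — an edge-weight
transform and a map standardization — are distinct steps that protocols
often conflate, and the map metadata records which was used.

# Preprocessing model

`preprocess_bold()` applies, in a fixed and logged order: discarding of
initial volumes (default 5, leaving the magnetization to equilibrate),
motion quality control, joint detrending + nuisance regression, bandpass
filtering, and optional Gaussian smoothing.

* **Motion QC** excludes a subject when any single translation column
  exceeds 2 mm or any rotation column exceeds 2 degrees in absolute
  value (strict inequality, per direction — not framewise displacement,
  matching the per-direction wording of the protocol this emulates).
* **Nuisance regression** removes an intercept, a linear trend, and any
  supplied confounds (six motion parameters; mean white-matter and
  ventricular signals when masks are provided) in one least-squares
  projection. Folding the detrend into the same regression is
  mathematically equivalent to detrending first and avoids two passes.
  Residuals are orthogonal to the confounds to near machine precision.
* **Bandpass** (0.01–0.1 Hz default) is a zero-phase frequency-domain
  filter: the FFT spectrum is multiplied by a real response that is 1 in
  the pass band with raised-cosine roll-offs of half-width 0.005 Hz.
  A real, symmetric response introduces no phase shift, so inter-voxel
  correlations — the quantity DC is built from — are not distorted by
  filter delays. The DC (zero-frequency) component is removed whenever
  the low edge is positive. Filtering after regression can re-introduce
  small correlations with the unfiltered confounds; this is inherent to
  every filter-after-regression ordering and is bounded in the tests.
* **Smoothing** is separable 3-D Gaussian convolution with per-axis
  sigma $\mathrm{FWHM}/(2\sqrt{2\ln 2})$ in voxel units (anisotropic
  voxels get per-axis sigmas), kernel truncated at $4\sigma$ and
  renormalized, reflection padding at the boundaries. No within-mask
  renormalization is applied at this stage; masked operations happen at
  DC standardization. The protocol emulated here smooths at 8 mm before
  DC computation and again at 6 mm after standardization; both switches
  are independent because the double-smoothing is a property of that
  protocol, not a recommendation.

The pipeline order (discard, QC, regression, filter, smooth) is fixed by
configuration and recorded; whether filtering preceded smoothing in the
original toolchain is not documented there, so the order is an explicit
configuration of this package rather than a claim about that toolchain.

# Degree computation at scale

A whole-brain gray-matter mask at 3 mm has tens of thousands of voxels,
so the $V \times V$ correlation matrix is never materialized. Time series
are demeaned and normalized to unit Euclidean norm once; correlations are
then inner products, computed in row blocks of `chunk_size` voxels and
immediately reduced to suprathreshold counts. The result is exactly
independent of the chunk size, and the test suite verifies integer
equality against a dense brute-force correlation matrix on instances up
to 2,000 voxels for chunk sizes 1, 7 and 64. Correlations are clamped to
$[-1, 1]$ before thresholding or `atanh` so floating-point drift can
never produce an infinite Fisher weight. Zero-variance voxels are
removed from the mask with a warning rather than propagating NaN.

# Group inference

`fit_voxelwise_glm()` fits, per voxel, standardized DC on
`[intercept, group, covariates]` by ordinary least squares and forms the
t statistic of the patient-minus-control contrast. With no covariates
this reduces *exactly* to the pooled two-sample t-test (verified to
1e-10 voxel-wise). The default covariates are age and sex — the matching
variables of the emulated study design; the protocol source does not
name its covariate set, so the choice is configurable and recorded.

Cluster-level correction comes in two flavors:

* **Random-field theory** (`grf_cluster_correct`): the t-map is
  thresholded at the two-tailed quantile for the cluster-forming
  `voxel_p` (default 0.01); connected components (26-connectivity, the
  convention of the common DC toolchains; 6/18 configurable) are formed
  separately in the positive and negative tails. Residual smoothness is
  estimated with the standard normalized-gradient variance estimator —
  squared forward differences of unit-variance residual fields, averaged
  over in-mask pairs, mapped from the discrete lattice to the continuous
  Gaussian autocorrelation scale by
  $\lambda = -2\log(1 - \lambda_{disc}/2)$ and clamped so unsmoothed
  white fields resolve to a sub-voxel FWHM rather than zero (a zero
  FWHM would make resel counts infinite). Resel counts $R_0..R_3$ use
  the lattice point/edge/face/cube counting of the mask, and the
  expected number of clusters is the full expected-Euler-characteristic
  sum over the four t-field EC densities. Cluster extent p-values use
  the standard expected-cluster-extent approximation
  $P(n \ge k) = \exp(-\beta k^{2/3})$, and the reported corrected p is
  two-tailed (the expected cluster count is doubled because both tails
  are searched).
* **Permutation** (`permutation_cluster_correct`): covariate effects are
  removed by Freedman–Lane residualization of both the maps and the
  group regressor, subject order is permuted, and the null distribution
  of the maximal suprathreshold cluster extent over both tails gives
  rank-based corrected p-values with +1 smoothing. This route makes no
  smoothness assumptions and is the calibration reference for the RFT
  route: the test suite checks on 200 null cohorts that the permutation
  family-wise error rate lies inside the binomial 99% interval around
  0.05 and that the RFT rate stays at or below 0.10.

The cluster-forming rule "correction at the voxel level (p < 0.01)" in
the emulated protocol is ambiguous between voxel-level FWE at 0.01 and
cluster-level correction with a 0.01 forming threshold; this package
implements cluster-level correction with `voxel_p = 0.01` as the default
reading and does not claim to resolve the ambiguity. The minimum
reportable cluster extent defaults to 50 voxels — the scale of
whole-brain analyses, where reported clusters start around 64 voxels —
and is lowered explicitly in desk-scale analyses where whole regions are
smaller than that.

# Clinical correlation and classification

`extract_region_features()` averages standardized DC over each surviving
cluster (or over ground-truth regions) per subject.
`correlate_with_clinical()` computes Pearson correlations (or a joint
multiple regression per region) between regional DC and clinical
variables, with Bonferroni (default) or Benjamini–Hochberg correction
across the whole region-by-variable family. Illness duration exists only
for patients, so pairs involving it are computed on the patient subset;
the variable list of the emulated "multiple factors regression" is not
documented, so the default set is symptom severity, illness duration and
age.

`grid_search_svm()` reproduces the LIBSVM grid-tool protocol: an
RBF-kernel SVM evaluated by cross-validated accuracy over an exhaustive
grid of $C$ and $\gamma$ (default powers of two, $2^{-10}..2^{10}$),
ties broken toward smaller $C$ then smaller $\gamma$, leave-one-out
folds by default. Feature standardization is computed from training
folds only and applied to held-out subjects, so no test-fold statistics
leak into the scalers (asserted in the tests). Reporting the *maximal*
cross-validated accuracy over a grid is optimistically biased on small
samples; `nested_cv_svm()` provides the unbiased alternative in which
the grid search runs inside each outer training set. `evaluate_per_region()`
exposes both as `protocol = "paper"` (the emulated protocol, biased as
published) and `protocol = "nested"`; neither is silently substituted
for the other. The same distinction applies to feature selection: the
emulated protocol selects regions from a group contrast over all
subjects and then cross-validates on the same subjects, which this
package reproduces when asked, while ground-truth regions or
fold-internal selection give the honest estimate on synthetic data.

`confusion_metrics()` is deliberately trivial arithmetic — accuracy,
sensitivity and specificity as integer-count ratios — because published
classification results are printed in exactly that form and must be
reproducible from their printed counts.

# The synthetic cohort generator

`generate_cohort()` emulates a two-group adolescent depression study:
71 subjects per group by default, 212 volumes at TR = 2 s, 3 mm
isotropic voxels, an ellipsoidal "brain" mask, demographics drawn from
truncated normals matching the published sample table (patient HRSD-17
$\sim \mathcal{N}(22.9, 4.3^2)$ truncated at the eligibility floor of
17, control $\sim \mathcal{N}(8.7, 5.8^2)$ truncated at 0, ages 14–18,
about 62% male, patient illness duration under 12 months), and
per-subject motion traces as random walks rescaled to exact requested
maxima so QC thresholds can be exercised deterministically.

The BOLD model is a sum of $K$ latent network signals plus spatially
autocorrelated noise. Each latent course is AR(1) (coefficient 0.3,
unit marginal variance) and is broadcast to a spherical voxel set with
fixed per-voxel loadings drawn from `loading_range`; noise is white
Gaussian smoothed with a 6 mm FWHM kernel — matching the smoothness
assumptions of the random-field inference downstream — and rescaled so
the post-smoothing voxel SD equals `noise_sigma` exactly (interior
voxels). All randomness flows from one seeded generator stream — subject data are
drawn sequentially from it, and per-subject motion seeds are themselves
drawn from the stream rather than derived arithmetically from the cohort
seed, because the early draws of consecutively seeded Mersenne–Twister
streams are correlated and would plant spurious group structure in null
cohorts. Identical seeds give bit-identical cohorts.

Planted effects multiply the loadings of hub-region voxels by
$1 \pm \text{magnitude}$ in the patient group. Three generator design
points matter and were calibrated once, on first principles plus pilot
simulation, before the validation thresholds were frozen:

* **Hub radius versus noise correlation length.** The smoothed noise
  correlates neighboring voxels strongly (its autocorrelation is about
  0.25 at two voxels, negligible at three). Within-sphere voxel pairs
  closer than that are connected at the binarization threshold in *both*
  groups regardless of loadings, so a hub sphere must have radius of at
  least about 2.5 voxels for most member pairs to sit at noise-free
  distances where loading changes can move edges across the threshold.
  The default six-region layout solves for the largest feasible such
  radius on the requested grid; grids of at least 16 voxels per axis are
  needed for planted-effect studies, and recovery analyses here use
  20-22 voxel grids.
* **Loading spread.** Loadings are uniform on `loading_range` (default
  0.35–0.8 relative to the unit-variance latent), which puts
  within-network pair correlations on both sides of $r_0$ so edges
  respond to the group scaling in either direction.
* **Balanced planting.** Per-subject z-standardization couples every
  voxel to the mask-wide degree distribution. If planted decreases
  remove more total degree than planted increases add, the patient mask
  mean drops and every background voxel acquires a spurious positive
  shift — a real artifact of the z-scoring protocol that is negligible
  at whole-brain scale (clusters are about 1% of the mask) but material
  at desk scale, where six planted spheres occupy about 10% of it. The
  generator therefore draws loadings of decrease-regions from the upper
  part of `loading_range` (hubs with room to fall below threshold) and
  of increase-regions from the lower part (room to rise across it),
  which roughly balances the total planted degree change. A small
  residual background bias remains at desk scale and is visible as
  occasional small extra clusters; recovery analyses therefore use a
  minimum cluster extent well below the planted-region size but above
  that speckle.

What the generator does **not** emulate: hemodynamic response dynamics,
cardiac/respiratory physiological noise, scanner drift beyond a linear
trend, multi-site effects, spatial normalization residuals, or any
coupling between DC and the simulated clinical scores (which is what
makes the null-correlation validation meaningful). Passing tests on this
synthetic family therefore demonstrate the correctness and calibration
of the *algorithms*, not the effect sizes to be expected on real
adolescent-depression data.

# Validation scale and numerical choices

The shipped validation suite runs at desk scale, chosen so the full
suite completes on a single CPU in well under half an hour: null
calibration uses 200 cohorts of 20+20 subjects on 12-voxel grids with 60
timepoints; planted-region recovery uses 30+30 subjects on 20-voxel
grids with 150 timepoints and six planted regions at magnitude 0.5;
classifier validation uses 50 single-effect-region cohorts (ranking,
grid-search protocol) and 15 null cohorts (nested protocol, mean
cross-validated accuracy within 0.40–0.60). The null calibration uses a
stratified 10-fold outer scheme rather than leave-one-out: on balanced
two-class data, leaving one subject out always leaves the training fold
imbalanced by one, and a near-degenerate (heavily regularized)
classifier then predicts the training majority — the held-out subject's
opposite class — so LOOCV accuracy under the null is bimodal near 0 or
1 depending on tie-breaking, not 0.5. Chance-level calibration is a
property of balance-preserving folds; leave-one-out remains the default
for the effect-detection protocol it emulates. Recovery geometry is evaluated
on unsmoothed standardized maps because a 6 mm kernel at 3 mm voxels
inflates a radius-2.5-voxel cluster several-fold — the smoothing
operator itself is validated separately against its closed form. SVM
grids in the validation runs span $2^{-4}..2^{8}$ rather than the full
default grid purely to keep the grid evaluation count proportionate to
these small cohorts.

Other numerical choices: double-precision accumulation throughout;
correlation clamping before `atanh`; rank-deficient confound matrices
residualized through an SVD pseudo-inverse with a warning;
rank-deficient design matrices rejected with the offending columns
named; empty cluster tables are ordinary results, not errors; and the
permutation corrected p uses $(1 + r)/(n_{perm} + 1)$, which is valid
(never anti-conservative in expectation) for any number of permutations.

# Known limitations

* RFT cluster p-values on coarse grids with modest smoothness are an
  approximation; the permutation route is the reference when the two
  disagree.
* The generator's latent networks are spherical (optionally with a
  dispersed periphery via `n_periphery`); real functional networks are
  anatomically structured and long-tailed in their degree distributions.
* Classification metrics under `protocol = "paper"` inherit the
  optimism of maximal-grid-accuracy reporting; they reproduce the
  emulated protocol faithfully and should be read accordingly.
* The emulated study's anatomical cluster labels (cerebellum, insula,
  lingual and parietal cortex) require real MNI-registered data and an
  atlas; this package reports coordinates and planted-region recovery
  instead.
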