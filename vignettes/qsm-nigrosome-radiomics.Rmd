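---
title: "Radiomic analysis of the nigrosome-1 region on quantitative susceptibility maps"
author: "qsmRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic analysis of the nigrosome-1 region on quantitative susceptibility maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmRadiomics)
```

## The scientific problem

Idiopathic Parkinson's disease (IPD) is accompanied by early iron
accumulation and dopaminergic neuron loss in nigrosome-1, the largest
calbindin-poor subregion of the substantia nigra pars compacta. On
iron-sensitive MRI a preserved nigrosome-1 produces the "swallow-tail
sign" (STS) — a thin hyperintense (low-susceptibility) pocket inside the
otherwise iron-rich nigral territory — and the loss of that sign is an
established visual biomarker of IPD. Visual reading, however, is
reader- and protocol-dependent. This package implements a quantitative
alternative: a radiomic characterisation of a manually segmented,
nigrosome-1-containing volume of interest (VOI) on quantitative
susceptibility mapping (QSM) data, followed by machine-learning
classification and conventional group statistics.

The pipeline has five stages, each an exported module:

1. **Synthetic cohort generation** (`cohortSpec()`, `generateCohort()`,
   `generateFeatureTable()`) — the study cohort was not deposited, so a
   generator emulates its published class-conditional statistics and makes
   every downstream stage testable.
2. **Feature extraction** (`extractAll()`, `extractCohort()`) — 105
   radiomic features: 18 first-order, 13 shape, and 74 texture features
   from the GLCM, GLRLM, GLSZM, GLDM and NGTDM gray-level matrices.
3. **Ensemble feature selection** (`ensembleSelect()`) — average rank of
   ANOVA-F, random-forest importance and linear-SVM recursive feature
   elimination; top 40 kept.
4. **Classification** (`crossValidate()`) — standardize, PCA-rotate and
   classify with an RBF-kernel SVM (C = 30, gamma = 0.001) under
   stratified 3-fold cross-validation with 10 repetitions.
5. **Group statistics** (`featureTtests()`, `featureAuc()`,
   `motorCorrelation()`, `contingencyMetrics()`) — Bonferroni-corrected
   unpaired t-tests (threshold 0.05/40 = 0.00125), per-feature ROC AUC,
   Pearson correlation with a UPDRS-III-like motor score, and the
   contingency arithmetic of the radiologist's STS reading.

## The feature engine

### Discretization

All texture matrices operate on gray levels, not raw ppm values.
The binning policy is deliberately explicit because it is the single
most consequential free parameter of any radiomic texture analysis:

* **fixed bin count** (default, 32 bins over the VOI's own `[min, max]`):
  `level = 1 + floor((x - min)/(max - min) * N)`, clamped so the maximum
  falls in the top bin. Relative binning is robust to the between-subject
  susceptibility scale and makes texture features invariant to a global
  intensity shift.
* **fixed bin width** in ppm: `level = 1 + floor((x - min)/w)`, for
  sensitivity analyses where an absolute susceptibility resolution is
  wanted.

A constant VOI discretizes to the single level 1 — a logged, non-error
degenerate case.

### Direction sampling

Directional matrices (GLCM, GLRLM) are computed along the 13 unique axes
of the 26-neighbourhood at one voxel step (`directionSet()`): the 3
lattice axes, 6 face diagonals and 4 body diagonals, one sign
representative each; per-direction features are averaged, and a direction
with no valid voxel pair is dropped from the average rather than
poisoning it with NaN. Distances are counted in voxel steps — texture is
a lattice property here — while millimetre spacing enters only the shape
features and TotalEnergy.

### Matrix families

* **GLCM** — symmetrized co-occurrence counts of level pairs at a fixed
  offset; 23 features (entropies, moments, information measures of
  correlation, inverse-difference family).
* **GLRLM** — maximal same-level runs per direction; 16 features.
* **GLSZM** — connected same-level zones under 26-connectivity
  (direction-free); 16 features. Zone labelling delegates to igraph
  connected components.
* **GLDM** — per-voxel count of level-identical 26-neighbours
  (dependence, tolerance alpha = 0); column j + 1 of the matrix holds
  "j dependent neighbours", and every VOI voxel contributes exactly once;
  14 features.
* **NGTDM** — per-level summed deviation from the mean level of each
  voxel's in-VOI neighbours; 5 features.

Every engine is verified in the test suite against an independent
brute-force transliteration of its definition (per-voxel loops, flood
fill, line scans) over hundreds of random VOIs, plus the structural
invariants: normalised matrices sum to one, GLCM symmetry, GLSZM/GLRLM
voxel conservation, translation invariance of all 105 features, and
intensity-shift invariance of the texture block under bin-count
discretization.

### Shape conventions

Shape features use the physical coordinates of voxel centres. The
surface mesh is the triangulated set of exposed voxel faces (two
congruent triangles per face): surface area is exact for the voxelized
boundary, and the diameter features are the largest vertex-pair
distances (in 3D, and in the three axis-aligned plane families). This
convention is coarser than a smoothed marching-cubes isosurface but has
no free parameters, is exactly reproducible, and is pinned by tests
(e.g. a single 1 mm voxel has area 6 mm^2 and 3D diameter sqrt(3) mm).
`Volume` is reported as the voxel count — the scale on which the group
difference of nigral volume is conventionally reported — while
sphericity and the surface-to-volume ratio use the physical volume in
mm^3. Axis lengths are `4*sqrt(lambda)` for the eigenvalues of the
coordinate covariance (sample covariance, n - 1); a degenerate (planar
or single-voxel) VOI yields Flatness 0, logged.

### Degenerate-input conventions

Constant or single-voxel VOIs are legal inputs with pinned conventions:
first-order Skewness/Kurtosis 0; Entropy/Variance 0; GLCM Correlation 1
when a marginal sd is 0; Imc1 = 0 when `max(HX, HY) = 0`; Imc2 clipped
at 0; NGTDM Coarseness capped at 1e6 when its denominator vanishes;
`0 * log 0 = 0` throughout. All are logged through the package's quiet
log channel (`options(qsmRadiomics.verbose = TRUE)` to see them).

## The synthetic cohort generator

No imaging data accompany the study, so the generator is a first-class,
tested module, not a fixture. It emulates what the published group
statistics say about the measured cohort — 87 IPD and 77 retained
healthy controls — at the level of a per-subject image:

* **VOI geometry.** Four consecutive 1 mm axial slices of elliptical
  cross-section on a 28 x 28 x 8 grid at 0.86 x 0.86 x 1.0 mm spacing,
  rasterized so the voxel count tracks a per-class Gaussian draw
  (IPD 519.5 +/- 128.7 voxels, HC 629.1 +/- 129.6 — the published volume
  distributions).
* **Susceptibility field.** A Gaussian random field smoothed with a small
  separable kernel (sigma 0.6 voxels, both classes) for short-range
  spatial correlation, re-standardized inside the VOI and scaled to a
  within-VOI sd of 0.041 (IPD) / 0.038 (HC) ppm around a subject-level
  mean drawn from the class median (0.076 / 0.066 ppm, between-subject
  sd 0.012 ppm). The within-VOI sd values place the subject's 10th
  percentile near its published group mean (0.023 ppm in IPD).
* **Nigrosome pocket.** With probability 0.675 in HC and 0.092 in IPD —
  the published rates at which a radiologist saw the STS — an ellipsoidal
  sub-region covering 15% of the VOI is set to the subject level
  - 0.055 ppm with its internal field variance damped by a factor 0.35.
  The damping matters: a coherent low-susceptibility structure occupies a
  tight, spatially contiguous band of low gray levels, which is what
  drives the published texture contrasts (higher long-run low-gray-level
  emphasis and higher GLSZM gray-level non-uniformity in controls). A
  constant-offset pocket with undamped variance reproduces the intensity
  statistics but not the run-length direction.
* **Motor score.** For patients only,
  `score = 13.5 + 500 * p10 + N(0, 16.1)` with `p10` the subject's
  10th-percentile susceptibility; the noise sd is set so the population
  correlation is approximately 0.35, the published UPDRS-III association.
  The score scale is arbitrary (correlation is scale-free); controls get
  NA.

`generateFeatureTable()` bypasses image synthesis entirely: it draws the
five representative features (10th percentile, median, volume, GLRLM
long-run low-gray-level emphasis, GLSZM gray-level non-uniformity)
directly from per-class Gaussians at the published means and sds
(`referenceEffectSizes()`), with the remaining 100 columns as
class-independent standard-normal nuisance. This analytic table is what
the closed-form recovery checks use: its per-feature AUC has a known
binormal value `pnorm(dmu / sqrt(s1^2 + s0^2))`, and the five planted
features are recoverable among the top 40 ensemble-selected features
because the competition is pure noise.

**What passing tests do and do not show.** The image generator matches
the *directions* of all five published group differences and the
*magnitudes* of the intensity and volume features; the magnitudes of the
two texture features depend on the (unpublished) binning of the original
analysis and are not matched. Real QSM data additionally contain
reconstruction artifacts, bilateral VOIs, segmentation variability and
anatomical covariation that the generator does not model, so a pipeline
that passes here is verified as *software* and as a *statistical
procedure*, not validated as a clinical classifier. Because the planted
image-level signal is clean, the cross-validated AUC on synthetic
cohorts (typically > 0.95) exceeds what heterogeneous clinical data
would give; the corresponding test asserts only a 0.8 sanity floor.

## Selection and classification choices

* Ranking uses the full sample, mirroring the original protocol in which
  feature importance was computed on all 164 subjects; this is
  deliberately outside the CV loop (the published generalization
  estimate shares this optimism). `crossValidate()` itself is leakage-safe
  by default: standardization and PCA are refit inside every training
  fold; `paperMode = TRUE` fits them once on the full table to mirror the
  original description.
* RFE eliminates exactly one feature per round with a linear SVM at
  C = 1 (the estimator's regularization is unstated in the source;
  pinned). Its training-accuracy curve over 105 -> 1 retained features is
  returned for inspection; the package does not auto-pick N from it.
* The random forest uses 10 trees (as specified) with impurity (Gini)
  importance; remaining hyperparameters are the randomForest defaults
  (unlimited depth, sqrt(p) candidates per split), pinned by tests.
* Rank ties break by best single-method rank, then canonical feature
  order — deterministic and documented rather than arbitrary.
* Folds are stratified by class (unstated in the source; stratification
  is the default because it guarantees both classes in every test fold
  at these class sizes, reproducing the printed 109/55 split);
  `stratified = FALSE` is available.
* IPD is the positive class everywhere; SVM margins are oriented so
  positive scores mean IPD, hard labels cut at 0, and AUC uses the
  rank/Mann-Whitney formulation with half credit for ties.

## Problem sizes used by the tests and the acceptance script

The matrix-engine property suites run on random VOIs up to 6 x 6 x 4
voxels (where brute-force oracles are exact and fast), 100+ VOIs per
suite. Cohort-level checks run the full 164-subject design: the
closed-form AUC recovery averages 200 Gaussian-table seeds, the
five-feature selection recovery uses 10 seeds, and the image-level
classification check runs one full pipeline (simulate, extract, select,
3-fold x 10 repetitions). These sizes were chosen so that every check is
a real end-to-end computation at the study's sample size while the whole
suite stays in the minutes range on one CPU.

## Known limitations

* One VOI per subject: the source extracted features "of bilateral VOIs"
  but analyses 164 samples (one per subject); whether sides were merged
  or averaged is unstated. The package treats the supplied mask as the
  per-subject VOI.
* The binning of the original analysis is unknown; absolute texture
  magnitudes are therefore not comparable to the published table, only
  directions and rank behaviour.
* The voxel-face surface mesh gives systematically larger areas (hence
  smaller sphericities) than smoothed isosurface meshes; comparisons
  across packages must hold the mesher fixed.
* QSM reconstruction (background-field removal, dipole inversion) and
  DICOM handling are out of scope; the pipeline starts from a
  reconstructed NIfTI volume plus mask.
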