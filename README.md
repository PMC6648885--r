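# qsmRadiomics

Radiomic analysis of the nigrosome-1-containing substantia nigra on
quantitative susceptibility mapping (QSM) volumes, for separating
idiopathic Parkinson's disease (IPD) from healthy controls (HC).

Parkinson's disease begins with iron accumulation and dopaminergic
neuron loss in nigrosome-1; on iron-sensitive MRI a preserved
nigrosome-1 appears as the "swallow-tail sign", and its loss is a
visual biomarker of IPD that is hard to read consistently. This package
quantifies the same territory instead: from a 3D susceptibility volume
(NIfTI, ppm) and a co-registered binary VOI mask it computes **105
radiomic features** — 18 first-order intensity statistics, 13 shape
features, and 74 texture features from the five gray-level matrix
families

- GLCM (co-occurrence), GLRLM (run length) — computed along the 13
  unique lattice directions of the 26-neighbourhood and averaged,
- GLSZM (size zone), GLDM (dependence), NGTDM (neighbouring gray-tone
  difference),

then ranks features by an **ensemble of ANOVA F, random-forest (10-tree,
Gini) importance and linear-SVM recursive feature elimination** (average
rank, top N = 40 kept), classifies with an **RBF-kernel SVM**
(K(x_i, x_j) = exp(-γ‖x_i − x_j‖²), C = 30, γ = 0.001) after per-fold
standardization and PCA under **stratified 3-fold cross-validation with
10 repetitions**, and reports the group statistics: two-tailed unpaired
t-tests at the Bonferroni threshold 0.05/40 = 0.00125, per-feature ROC
AUC, Pearson correlation with a UPDRS-III-like motor score, and the
contingency metrics of the radiologist's sign reading.

Because the clinical cohort is not public, the package ships a tested
synthetic cohort generator (`generateCohort()`, 87 IPD + 77 HC, 4-slice
VOIs of ~500–650 voxels) whose class-conditional intensity, texture and
volume statistics emulate the published effect sizes, plus an analytic
Gaussian feature simulator (`generateFeatureTable()`) for closed-form
recovery checks. It is aimed at methodologists who want a transparent,
fully testable reference implementation of a QSM radiomics pipeline.

## Worked example

```r
library(qsmRadiomics)

spec   <- cohortSpec(seed = 11)                 # study-sized synthetic cohort
cohort <- generateCohort(spec)                  # 164 volumes + VOI masks
table  <- extractCohort(cohort)                 # 164 x 105 feature table
sel    <- ensembleSelect(table, nSelect = 40, seed = 11)
cv     <- crossValidate(sel$reduced, studyConfig(seed = 11),
                        labels = subjectLabels(table))
cv
#> CvReport: 30 fold records (10 reps x 3 folds), seed 11
#>   AUC 0.999 +/- 0.001 | accuracy 0.988 +/- 0.014 | sensitivity 0.999 +/- 0.006 | specificity 0.977 +/- 0.026
```

The pooled AUC is near 1 because the planted synthetic signal is clean;
on heterogeneous clinical data this pipeline design reports AUC around
0.96. Group statistics of the five representative features:

```r
st <- groupStatistics(table)
st$tests[, c("feature", "meanIpd", "meanHc", "p", "significant", "auc")]
#>                             feature  meanIpd   meanHc        p significant   auc
#> 1           firstorder_10Percentile   0.0217   0.0092 3.41e-08        TRUE 0.750
#> 2                 firstorder_Median   0.0744   0.0593 3.04e-11        TRUE 0.800
#> 3                      shape_Volume 524.0920 595.0130 3.48e-04        TRUE 0.656
#> 4 glrlm_LongRunLowGrayLevelEmphasis   0.0118   0.0120 8.82e-01       FALSE 0.533
#> 5      glszm_GrayLevelNonUniformity  13.1321  14.4653 3.79e-03       FALSE 0.616
```

Patients show the higher 10th-percentile and median susceptibility and
the smaller, texturally more uniform VOI — the published directions.
The 10th percentile also tracks motor severity in patients
(`r = 0.38, p = 3e-4` on this seed; coupling calibrated to r ≈ 0.35),
and the sign-reading arithmetic reproduces the reported rates exactly:

```r
contingencyMetrics(hcPresent = 52, hcTotal = 77, ipdPresent = 8, ipdTotal = 87)
#> accuracy 79.88%, sensitivity 67.53%, specificity 90.80% (sign present in 9.20% of IPD)
```

A thin CLI over the same functions lives in `inst/cli/qsmradiomics.R`
(subcommands `simulate`, `extract`, `select`, `classify`, `stats`,
`run-all`). The methods vignette
(`vignettes/qsm-nigrosome-radiomics.Rmd`) documents every model,
convention and default.

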