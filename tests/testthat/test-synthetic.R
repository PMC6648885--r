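# Synthetic cohort generator: determinism, VOI geometry, calibration.

smallSpec <- function(...) cohortSpec(nIpd = 8L, nHc = 8L, ...)

test_that("cohort has the configured composition and 4-slice VOIs", {
  coh <- generateCohort(cohortSpec(seed = 7))
  expect_length(coh, 164L)
  expect_equal(sum(vapply(coh, `[[`, character(1), "label") == "IPD"), 87L)
  s <- coh[[1]]
  z <- unique(which(s$mask@mask, arr.ind = TRUE)[, 3])
  expect_length(z, 4L)
  expect_true(all(diff(sort(z)) == 1))
  expect_identical(dim(s$volume@values), dim(s$mask@mask))
})

test_that("fixed seed reproduces the cohort bit-identically", {
  c1 <- generateCohort(smallSpec(seed = 5))
  c2 <- generateCohort(smallSpec(seed = 5))
  expect_identical(lapply(c1, function(s) s$volume@values),
                   lapply(c2, function(s) s$volume@values))
  expect_identical(lapply(c1, function(s) s$mask@mask),
                   lapply(c2, function(s) s$mask@mask))
  expect_identical(vapply(c1, `[[`, numeric(1), "score"),
                   vapply(c2, `[[`, numeric(1), "score"))
})

test_that("VOI voxel counts track the class means within 3 SE", {
  coh <- generateCohort(cohortSpec(seed = 3))
  lab <- vapply(coh, `[[`, character(1), "label")
  nv <- vapply(coh, function(s) voiSize(s$mask), numeric(1))
  spec <- cohortSpec()
  for (cls in c("IPD", "HC")) {
    se3 <- 3 * spec$volumeSd[cls] / sqrt(sum(lab == cls))
    expect_lt(abs(mean(nv[lab == cls]) - spec$volumeMean[cls]),
              se3 + 15)    # rasterization granularity allowance
  }
})

test_that("deepening the pocket widens the HC-IPD 10th-percentile gap", {
  gap <- vapply(c(-0.02, -0.055, -0.09), function(off) {
    coh <- generateCohort(cohortSpec(nIpd = 12L, nHc = 12L, seed = 21,
                                     pocketOffset = off))
    p10 <- vapply(coh, function(s)
      quantile(voiValues(s$volume, s$mask), 0.1, names = FALSE), numeric(1))
    lab <- vapply(coh, `[[`, character(1), "label")
    mean(p10[lab == "IPD"]) - mean(p10[lab == "HC"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))   # more negative offset, larger gap
})

test_that("null generator (no pocket, equal intensities) shows no p10 effect", {
  pvals <- vapply(1:20, function(s) {
    spec <- cohortSpec(nIpd = 10L, nHc = 10L, seed = s,
                       pocketProb = c(IPD = 0, HC = 0),
                       fieldMean = c(IPD = 0.07, HC = 0.07),
                       fieldSd = c(IPD = 0.04, HC = 0.04),
                       volumeMean = c(IPD = 570, HC = 570),
                       volumeSd = c(IPD = 129, HC = 129))
    coh <- generateCohort(spec)
    p10 <- vapply(coh, function(s)
      quantile(voiValues(s$volume, s$mask), 0.1, names = FALSE), numeric(1))
    lab <- vapply(coh, `[[`, character(1), "label")
    t.test(p10[lab == "IPD"], p10[lab == "HC"], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("invalid specs are rejected", {
  expect_error(cohortSpec(nIpd = 0), "spec error")
  expect_error(cohortSpec(pocketFraction = 1.2), "spec error")
  expect_error(cohortSpec(volumeMean = c(IPD = -5, HC = 600)), "spec error")
})

test_that("Gaussian table has the planted moments and cohort layout", {
  se <- generateFeatureTable(cohortSpec(seed = 2))
  expect_equal(ncol(se), 164L)
  m <- featureMatrix(se); lab <- subjectLabels(se)
  eff <- referenceEffectSizes()
  for (r in seq_len(nrow(eff))) {
    f <- eff$feature[r]
    expect_lt(abs(mean(m[lab == "IPD", f]) - eff$ipdMean[r]),
              4 * eff$ipdSd[r] / sqrt(87))
    expect_lt(abs(mean(m[lab == "HC", f]) - eff$hcMean[r]),
              4 * eff$hcSd[r] / sqrt(77))
  }
  # degenerate separation: zero sds and distinct means give AUC 1
  eff0 <- eff
  eff0$ipdSd <- eff0$hcSd <- rep(0, 5)
  se0 <- generateFeatureTable(cohortSpec(seed = 3), effects = eff0)
  a <- featureAuc(featureMatrix(se0)[, eff$feature[1]], subjectLabels(se0))
  expect_equal(as.numeric(a), 1)
})

test_that("empirical AUC of the planted 10th percentile matches the binormal form", {
  # average over seeds of the rank AUC vs closed-form Phi(dmu / sqrt(s1^2+s0^2))
  aucs <- vapply(1:60, function(s) {
    se <- generateFeatureTable(cohortSpec(seed = s))
    as.numeric(featureAuc(featureMatrix(se)[, "firstorder_10Percentile"],
                          subjectLabels(se), orient = FALSE))
  }, numeric(1))
  expect_equal(mean(aucs), binormalAuc(0.023, 0.007, 0.015, 0.009),
               tolerance = 0.02)
})
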