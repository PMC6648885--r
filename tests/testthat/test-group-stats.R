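# Group statistics: t-tests, per-feature AUC identities, correlation,
# contingency arithmetic.

test_that("t-test flags and threshold follow the Bonferroni contract", {
  set.seed(20)
  x <- cbind(sig = c(rnorm(30, 2, 0.5), rnorm(30, 0, 0.5)),
             null = rnorm(60))
  labs <- rep(c("IPD", "HC"), each = 30)
  res <- featureTtests(x, familyN = 40, labels = labs)
  expect_equal(attr(res, "threshold"), 0.00125)
  expect_true(res$significant[res$feature == "sig"])
  expect_false(res$significant[res$feature == "null"])
  expect_equal(res$significant, res$p < 0.00125)
  # identical groups: p = 1 under the zero-variance convention
  xc <- cbind(flat = rep(1, 20))
  resc <- featureTtests(xc, familyN = 40,
                        labels = rep(c("IPD", "HC"), each = 10))
  expect_equal(resc$p, 1)
  expect_false(resc$significant)
})

test_that("t-test p-values agree with an independent implementation", {
  set.seed(21)
  x <- cbind(a = rnorm(40, 0.3), b = rnorm(40))
  labs <- rep(c("IPD", "HC"), 20)
  res <- featureTtests(x, familyN = 5, labels = labs)
  for (f in c("a", "b")) {
    ref <- t.test(x[labs == "IPD", f], x[labs == "HC", f], var.equal = TRUE)
    expect_equal(res$p[res$feature == f], ref$p.value)
    expect_equal(res$t[res$feature == f], unname(ref$statistic))
  }
  # Welch flag switches the variant
  resw <- featureTtests(x, familyN = 5, labels = labs, welch = TRUE)
  refw <- t.test(x[labs == "IPD", "a"], x[labs == "HC", "a"])
  expect_equal(resw$p[resw$feature == "a"], refw$p.value)
})

test_that("power at the published 10th-percentile parameters is near 1", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    a <- rnorm(87, 0.023, 0.007); b <- rnorm(77, 0.015, 0.009)
    t.test(a, b, var.equal = TRUE)$p.value < 0.00125
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("feature AUC obeys the label-swap and Mann-Whitney identities", {
  set.seed(22)
  v <- rnorm(50)
  labs <- rep(c("IPD", "HC"), 25)
  a <- featureAuc(v, labs, orient = FALSE)
  swapped <- ifelse(labs == "IPD", "HC", "IPD")
  expect_equal(as.numeric(featureAuc(v, swapped, orient = FALSE)),
               1 - as.numeric(a))
  # U / (n1 n0) identity
  u <- wilcox.test(v[labs == "IPD"], v[labs == "HC"])$statistic
  expect_equal(as.numeric(a), unname(u) / (25 * 25))
  # oriented report is always >= 0.5 with a direction flag
  ao <- featureAuc(v, labs)
  expect_gte(as.numeric(ao), 0.5)
  expect_true(attr(ao, "direction") %in% c(-1, 1))
  expect_error(featureAuc(v, rep("IPD", 50)), "both classes")
})

test_that("feature AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  v <- c(rnorm(40, 1), rnorm(35, 0))
  labs <- rep(c("IPD", "HC"), c(40, 35))
  ref <- as.numeric(pROC::auc(pROC::roc(labs, v, levels = c("HC", "IPD"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(as.numeric(featureAuc(v, labs, orient = FALSE)), ref)
})

test_that("motor correlation matches the exact linear case and the null", {
  x <- rnorm(30)
  mc <- motorCorrelation(x, 2 * x + 1)
  expect_equal(mc$r, 1)
  expect_lt(mc$p, 1e-10)
  set.seed(24)
  rs <- vapply(1:50, function(s) {
    set.seed(s + 300)
    motorCorrelation(rnorm(87), rnorm(87))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(50 * 85))
  expect_error(motorCorrelation(rep(1, 10), rnorm(10)), "zero variance")
  # agreement with cor.test
  set.seed(25)
  a <- rnorm(40); b <- 0.4 * a + rnorm(40)
  mc2 <- motorCorrelation(a, b)
  ref <- cor.test(a, b)
  expect_equal(mc2$r, unname(ref$estimate))
  expect_equal(mc2$p, ref$p.value)
})

test_that("synthetic IPD cohort recovers the calibrated motor correlation", {
  rs <- vapply(1:60, function(s) {
    se <- generateFeatureTable(cohortSpec(seed = s + 500))
    ipd <- subjectLabels(se) == "IPD"
    motorCorrelation(featureMatrix(se)[ipd, "firstorder_10Percentile"],
                     motorScores(se)[ipd])$r
  }, numeric(1))
  # population r calibrated to 0.35; the mean sample r over seeds must sit
  # within 3 standard errors of that target
  expect_lt(abs(mean(rs) - 0.35), 3 * sd(rs) / sqrt(length(rs)) + 0.01)
})

test_that("contingency metrics reproduce the printed reading rates", {
  cm <- contingencyMetrics(52, 77, 8, 87)
  expect_equal(round(cm$accuracy, 2), 79.88)
  expect_equal(round(cm$sensitivity, 2), 67.53)
  expect_equal(round(cm$specificity, 2), 90.80)
  expect_equal(round(cm$ipdPresentRate, 2), 9.20)
  # prevalence-weighted identity: acc = (nHC * sens + nIPD * spec) / n
  expect_equal(cm$accuracy,
               (77 * cm$sensitivity + 87 * cm$specificity) / 164)
  # perfect and degenerate tables
  expect_equal(contingencyMetrics(77, 77, 0, 87)$accuracy, 100)
  allAbsent <- contingencyMetrics(0, 77, 0, 87)
  expect_equal(allAbsent$accuracy, 100 * 87 / 164)
  expect_error(contingencyMetrics(5, 0, 0, 10))
})

test_that("t-test p matches a permutation test within Monte-Carlo error", {
  set.seed(26)
  a <- rnorm(12, 0.8); b <- rnorm(12)
  x <- cbind(f = c(a, b))
  labs <- rep(c("IPD", "HC"), each = 12)
  p_t <- featureTtests(x, familyN = 1, labels = labs)$p
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(4000, {
    g <- sample(labs)
    abs(mean(x[g == "IPD", 1]) - mean(x[g == "HC", 1]))
  })
  p_perm <- mean(perm >= obs)
  expect_equal(p_t, p_perm, tolerance = 0.04)
})
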