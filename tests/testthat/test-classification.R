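# Standardization, PCA, SVM and repeated cross-validation.

gaussTable <- function(seed, n1 = 30, n0 = 30, sep = 2, p = 10) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p, sep), n1), matrix(rnorm(n0 * p, 0), n0))
  list(x = x, y = factor(rep(c("IPD", "HC"), c(n1, n0)),
                         levels = c("HC", "IPD")))
}

test_that("standardization uses training statistics only", {
  train <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2)
  test <- matrix(c(4, 5, 6, 7, 8, 9), ncol = 2)
  st <- standardizeFeatures(train, test)
  # population? no: sd() convention (n-1); pinned here
  expect_equal(st$train[, 1], (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  # constant training column maps to zero everywhere
  expect_equal(st$train[, 2], c(0, 0, 0))
  expect_equal(st$test[, 2], c(0, 0, 0))
  # test columns standardized with train mu/sigma, not their own
  expect_false(isTRUE(all.equal(mean(st$test[, 1]), 0)))
  expect_equal(st$test[, 1], (c(4, 5, 6) - 2) / 1)
})

test_that("PCA on the training fold is orthogonal and variance-preserving", {
  set.seed(10)
  x <- matrix(rnorm(200), 40, 5) %*% matrix(rnorm(25), 5, 5)
  st <- standardizeFeatures(x)
  pc <- pcaTransform(st$train)
  gram <- crossprod(scale(pc$train, scale = FALSE))
  expect_equal(gram, diag(diag(gram)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(apply(pc$train, 2, var)), sum(apply(st$train, 2, var)))
  # 2D correlated Gaussian: first-component variance = top eigenvalue
  set.seed(11)
  z <- matrix(rnorm(4000), 2000)
  z[, 2] <- 0.8 * z[, 1] + 0.6 * z[, 2]
  pc2 <- pcaTransform(z)
  expect_equal(var(pc2$train[, 1]), max(eigen(cov(z))$values),
               tolerance = 1e-8)
})

test_that("RBF kernel and SVM behave at the limits", {
  g <- gaussTable(1, sep = 6)
  fit <- trainSvm(g$x, g$y, C = 1000, gamma = 0.1)
  pred <- fit$predict(g$x)
  expect_equal(mean(pred$label == g$y), 1)        # separable case
  # kernel at zero distance is exactly 1
  expect_equal(exp(-0.1 * sum((g$x[1, ] - g$x[1, ])^2)), 1)
  expect_error(trainSvm(g$x, factor(rep("IPD", nrow(g$x)),
                                    levels = c("HC", "IPD"))),
               "single-class")
})

test_that("metrics follow the rank formulation with tie credit", {
  m <- computeMetrics(c(0.9, 0.8, 0.2, 0.1), c("IPD", "IPD", "HC", "HC"))
  expect_equal(m$auc, 1)
  # hard labels come from the margin sign
  mm <- computeMetrics(c(0.9, 0.8, -0.2, -0.1), c("IPD", "IPD", "HC", "HC"))
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$sensitivity, 1)
  expect_equal(mm$specificity, 1)
  m2 <- computeMetrics(rep(0.5, 10), rep(c("IPD", "HC"), 5))
  expect_equal(m2$auc, 0.5)                       # all-tied convention
  # random scores: AUC equals brute-force concordant-pair count
  set.seed(13)
  sc <- rnorm(100); tr <- rep(c("IPD", "HC"), 50)
  m3 <- computeMetrics(sc, tr)
  pos <- sc[tr == "IPD"]; neg <- sc[tr == "HC"]
  brute <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(m3$auc, brute)
  expect_error(computeMetrics(1:3, rep("IPD", 3)), "one-class")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(14)
  sc <- rnorm(60); tr <- rep(c("IPD", "HC"), 30)
  a1 <- computeMetrics(sc, tr)$auc
  expect_equal(computeMetrics(exp(sc), tr)$auc, a1)
  expect_equal(computeMetrics(5 * sc + 2, tr)$auc, a1)
})

test_that("cross-validation produces the printed fold layout on n = 164", {
  se <- generateFeatureTable(cohortSpec(seed = 4))
  cfg <- studyConfig(cvRepeats = 2L, seed = 4)
  cv <- crossValidate(se, cfg)
  expect_equal(nrow(cv@folds), 6L)               # 2 reps x 3 folds
  expect_setequal(unique(cv@folds$nTest), c(54L, 55L))
  expect_true(all(cv@folds$nTrain %in% c(109L, 110L)))
  expect_true(all(cv@folds$nTrain + cv@folds$nTest == 164L))
  # stratification keeps both classes in every fold
  expect_true(all(is.finite(cv@folds$auc)))
})

test_that("fixed seed reproduces fold assignments and metrics", {
  se <- generateFeatureTable(cohortSpec(nIpd = 20L, nHc = 20L, seed = 2))
  cfg <- studyConfig(cvRepeats = 3L, seed = 9)
  cv1 <- crossValidate(se, cfg)
  cv2 <- crossValidate(se, cfg)
  expect_identical(cv1@assignments, cv2@assignments)
  expect_identical(cv1@folds, cv2@folds)
})

test_that("pooled summary is recomputable from the fold records", {
  se <- generateFeatureTable(cohortSpec(nIpd = 20L, nHc = 20L, seed = 3))
  cv <- crossValidate(se, studyConfig(cvRepeats = 4L, seed = 3))
  s <- cvSummary(cv)
  expect_equal(s["auc", "mean"], mean(cv@folds$auc))
  expect_equal(s["accuracy", "sd"], sd(cv@folds$accuracy))
  perRep <- attr(s, "perRepetition")
  expect_equal(nrow(perRep), 4L)
})

test_that("permuted labels drive pooled AUC to chance", {
  set.seed(15)
  se <- generateFeatureTable(cohortSpec(seed = 5))
  labs <- sample(as.character(subjectLabels(se)))   # break the association
  cv <- crossValidate(featureMatrix(se), studyConfig(cvRepeats = 3L, seed = 5),
                      labels = labs)
  pooled <- mean(cv@folds$auc)
  se3 <- 3 * sd(cv@folds$auc) / sqrt(nrow(cv@folds))
  expect_lt(abs(pooled - 0.5), max(se3, 0.12))
})

test_that("perfectly separated features give accuracy 1 in every fold", {
  set.seed(16)
  n <- 60
  x <- matrix(rnorm(n * 5), n)
  y <- rep(c("IPD", "HC"), n / 2)
  x[, 1] <- ifelse(y == "IPD", 10, -10)
  cv <- crossValidate(x, studyConfig(cvRepeats = 2L, svmGamma = 0.1, seed = 6),
                      labels = y)
  expect_true(all(cv@folds$accuracy == 1))
  expect_true(all(cv@folds$auc == 1))
})
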