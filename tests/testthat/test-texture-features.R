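# Texture feature formulas by direct substitution into the definitions.

test_that("constant line VOI gives the hand-computed GLRLM features", {
  lev <- array(1L, c(1, 1, 4))
  gm <- glrlmMatrix(asDisc(lev), c(0L, 0L, 1L))
  f <- qsmRadiomics:::.glrlmFeatures(gm)
  # single run of level 1, length 4: LRLGLE = (1 * 16 / 1) / 1
  expect_equal(unname(f["LongRunLowGrayLevelEmphasis"]), 16)
  expect_equal(unname(f["LongRunEmphasis"]), 16)
  expect_equal(unname(f["ShortRunEmphasis"]), 1 / 16)
  expect_equal(unname(f["RunPercentage"]), 1 / 4)
  expect_equal(unname(f["RunEntropy"]), 0)
})

test_that("GLSZM gray-level non-uniformity by direct substitution", {
  # zones {(level 1, size 2): 1, (level 2, size 1): 1}, Nz = 2
  lev <- array(NA_integer_, c(4, 1, 1))
  lev[1:2, 1, 1] <- 1L; lev[4, 1, 1] <- 2L
  gm <- glszmMatrix(asDisc(lev))
  expect_equal(gm$nz, 2)
  f <- qsmRadiomics:::.glszmFeatures(gm)
  expect_equal(unname(f["GrayLevelNonUniformity"]), (1 + 1) / 2)
  expect_equal(unname(f["SizeZoneNonUniformity"]), 1)
  expect_equal(unname(f["ZonePercentage"]), 2 / 3)
})

test_that("constant VOI: GLCM joint entropy 0, max probability 1", {
  lev <- array(1L, c(2, 2, 2))
  gm <- glcmMatrix(asDisc(lev), c(1L, 0L, 0L))
  f <- qsmRadiomics:::.glcmFeatures(gm)
  expect_equal(unname(f["JointEntropy"]), 0)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Imc1"]), 0)     # HX = HY = 0 convention
  expect_equal(unname(f["Correlation"]), 1)
})

test_that("GLDM dependence entropy matches its histogram by hand", {
  lev <- array(1L, c(1, 1, 3))           # dependence counts 1, 2, 1
  gm <- gldmMatrix(asDisc(lev))
  f <- qsmRadiomics:::.gldmFeatures(gm)
  p <- c(2, 1) / 3                       # two voxels with 1 dep, one with 2
  expect_equal(unname(f["DependenceEntropy"]), -sum(p * log2(p)))
  # column index j = count + 1: mean dependence column
  mu <- (2 * 2 + 1 * 3) / 3
  expect_equal(unname(f["DependenceVariance"]),
               (2 * (2 - mu)^2 + 1 * (3 - mu)^2) / 3)
})

test_that("GLCM marginal-based features agree with definition sums", {
  set.seed(31)
  lev <- randomVoiFixture(c(5, 5, 3), ng = 4, holeProb = 0.1)
  gm <- glcmMatrix(asDisc(lev), c(1L, 1L, 0L))
  f <- qsmRadiomics:::.glcmFeatures(gm)
  p <- gm$p; ng <- nrow(p)
  i <- row(p); j <- col(p)
  expect_equal(unname(f["Autocorrelation"]), sum(p * i * j))
  expect_equal(unname(f["Contrast"]), sum(p * (i - j)^2))
  expect_equal(unname(f["Id"]), sum(p / (1 + abs(i - j))))
  expect_equal(unname(f["Idm"]), sum(p / (1 + (i - j)^2)))
  expect_equal(unname(f["InverseVariance"]),
               sum(p[abs(i - j) > 0] / (i - j)[abs(i - j) > 0]^2))
  mux <- sum(rowSums(p) * 1:ng)
  expect_equal(unname(f["JointAverage"]), mux)
  expect_equal(unname(f["SumSquares"]), sum(p * (i - mux)^2))
  expect_equal(unname(f["SumAverage"]), sum(p * (i + j)))
  expect_equal(unname(f["DifferenceAverage"]), sum(p * abs(i - j)))
  # correlation via covariance identity
  sx <- sqrt(sum(rowSums(p) * (1:ng - mux)^2))
  expect_equal(unname(f["Correlation"]),
               (sum(p * i * j) - mux^2) / sx^2)
})

test_that("NGTDM features by direct substitution on a tiny VOI", {
  lev <- array(c(1L, 2L, 1L), c(1, 1, 3))
  gm <- ngtdmMatrix(asDisc(lev))
  f <- qsmRadiomics:::.ngtdmFeatures(gm)
  # n = (2, 1), p = (2/3, 1/3), s = (2, 1)
  sumPS <- 2 / 3 * 2 + 1 / 3 * 1
  expect_equal(unname(f["Coarseness"]), 1 / sumPS)
  # contrast: (1/(2*1)) * sum_{i,j} p_i p_j (i-j)^2 * (1/3) * sum(s)
  expect_equal(unname(f["Contrast"]),
               (2 * (2 / 3) * (1 / 3) * 1) / 2 * (3 / 3))
})

test_that("direction averaging is a fixed point for identical matrices", {
  lev <- array(1L, c(3, 3, 3))           # constant: all directions identical
  disc <- asDisc(lev)
  dirs <- directionSet()
  glcms <- lapply(seq_len(13), function(k) glcmMatrix(disc, dirs[k, ]))
  one <- qsmRadiomics:::.glcmFeatures(glcms[[1]])
  avg <- textureFeatures(glcms,
                         lapply(seq_len(13),
                                function(k) glrlmMatrix(disc, dirs[k, ])),
                         glszmMatrix(disc), gldmMatrix(disc),
                         ngtdmMatrix(disc))
  expect_equal(unname(avg[paste0("glcm_", names(one))]), unname(one))
})
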