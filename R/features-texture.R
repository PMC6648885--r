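# Texture feature formulas per matrix family. Each .xxxFeatures() takes one
# grayLevelMatrix and returns the family's named feature vector; undefined
# terms follow the 0*log0 = 0 convention and sums restricted to non-empty
# cells; fully degenerate matrices fall back to the documented conventions.

.glcmFeatures <- function(gm) {
  p <- gm$p
  ng <- nrow(p)
  if (gm$nz == 0) {
    logNote("GLCM degenerate: empty matrix")
    return(setNames(rep(NA_real_, 23L), .glcmNames))
  }
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)           # equal by symmetry
  mux <- sum(1:ng * px); muy <- sum(1:ng * py)
  sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
  # diagonal / cross-diagonal marginals
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  k_dif <- 0:(ng - 1)
  pxy_dif <- vapply(k_dif, function(k) sum(p[abs(i - j) == k]), numeric(1))
  HX <- -sum(xlog2(px)); HY <- -sum(xlog2(py))
  HXY <- -sum(xlog2(p))
  pq <- px[i] * py[j]
  HXY1 <- -sum(p[pq > 0] * log2(pq[pq > 0]))
  HXY2 <- -sum(xlog2(pq))
  corr <- if (sx > 0 && sy > 0)
    (sum(p * i * j) - mux * muy) / (sx * sy)
  else { logNote("GLCM Correlation degenerate: sigma = 0, set to 1"); 1 }
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  da <- sum(k_dif * pxy_dif)
  vals <- c(
    Autocorrelation = sum(p * i * j),
    ClusterProminence = sum(p * (i + j - mux - muy)^4),
    ClusterShade = sum(p * (i + j - mux - muy)^3),
    ClusterTendency = sum(p * (i + j - mux - muy)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(pxy_dif)),
    DifferenceVariance = sum((k_dif - da)^2 * pxy_dif),
    Id = sum(pxy_dif / (1 + k_dif)),
    Idm = sum(pxy_dif / (1 + k_dif^2)),
    Idmn = sum(pxy_dif / (1 + (k_dif / ng)^2)),
    Idn = sum(pxy_dif / (1 + k_dif / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(pxy_dif[k_dif > 0] / k_dif[k_dif > 0]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = -sum(xlog2(pxy_sum)),
    SumSquares = sum(p * (i - mux)^2))
  setNames(as.numeric(vals), .glcmNames)
}

.glrlmFeatures <- function(gm) {
  P <- gm$counts
  nr <- gm$nz                       # number of runs
  np <- gm$np                       # voxels along this direction
  if (nr == 0) {
    logNote("GLRLM degenerate: no runs")
    return(setNames(rep(NA_real_, 16L), .glrlmNames))
  }
  p <- P / nr
  i <- row(P); j <- col(P)
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  vals <- c(
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    RunEntropy = -sum(xlog2(p)),
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum(p * (j - mu_j)^2),
    ShortRunEmphasis = sum(P / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr)
  setNames(as.numeric(vals), .glrlmNames)
}

.glszmFeatures <- function(gm) {
  P <- gm$counts
  nz <- gm$nz                       # number of zones
  np <- gm$np                       # VOI voxels
  p <- P / nz
  i <- row(P); j <- col(P)
  gi <- rowSums(P); sj <- colSums(P)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  vals <- c(
    GrayLevelNonUniformity = sum(gi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    LargeAreaEmphasis = sum(P * j^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    SizeZoneNonUniformity = sum(sj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sj^2) / nz^2,
    SmallAreaEmphasis = sum(P / j^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    ZoneEntropy = -sum(xlog2(p)),
    ZonePercentage = nz / np,
    ZoneVariance = sum(p * (j - mu_j)^2))
  setNames(as.numeric(vals), .glszmNames)
}

.gldmFeatures <- function(gm) {
  P <- gm$counts
  nz <- gm$nz                       # VOI voxels
  p <- P / nz
  i <- row(P); j <- col(P)          # column j holds (j-1) dependent nbrs
  gi <- rowSums(P); dj <- colSums(P)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  vals <- c(
    DependenceEntropy = -sum(xlog2(p)),
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    DependenceVariance = sum(p * (j - mu_j)^2),
    GrayLevelNonUniformity = sum(gi^2) / nz,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz)
  setNames(as.numeric(vals), .gldmNames)
}

.ngtdmFeatures <- function(gm) {
  s <- gm$s; pl <- gm$pLevel; nvp <- gm$nvp
  ng <- length(s)
  lv <- seq_len(ng)
  act <- pl > 0
  ngp <- sum(act)
  sumPS <- sum(pl * s)
  # pairwise tables over active levels
  ii <- lv[act]; pi_ <- pl[act]; si <- s[act]
  contrast <- 0; busyDen <- 0; complexity <- 0; strengthNum <- 0
  if (ngp >= 1) {
    D2 <- outer(ii, ii, function(a, b) (a - b)^2)
    PP <- outer(pi_, pi_)
    contrast <- if (ngp > 1)
      sum(PP * D2) / (ngp * (ngp - 1)) * sum(si) / nvp else 0
    busyDen <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
    PSi <- pi_ * si
    complexity <- sum(abs(outer(ii, ii, `-`)) *
                        (outer(PSi, PSi, `+`)) / outer(pi_, pi_, `+`)) / nvp
    strengthNum <- sum(outer(pi_, pi_, `+`) * D2)
  }
  coarse <- if (sumPS > 0) 1 / sumPS else {
    logNote("NGTDM Coarseness degenerate: capped at 1e6"); 1e6 }
  vals <- c(
    Busyness = if (busyDen > 0) sumPS / busyDen else 0,
    Coarseness = coarse,
    Complexity = complexity,
    Contrast = contrast,
    Strength = if (sum(si) > 0) strengthNum / sum(si) else 0)
  setNames(as.numeric(vals), .ngtdmNames)
}

#' Texture features from per-family gray-level matrices
#'
#' Evaluates the 74 texture features. GLCM and GLRLM are directional: one
#' matrix per offset in [directionSet()] is expected, the per-direction
#' feature values are averaged, and directions whose matrix holds no valid
#' pair/run are dropped from the average. GLSZM, GLDM and NGTDM are
#' direction-free single matrices.
#'
#' @param glcms list of 13 GLCM `grayLevelMatrix` objects.
#' @param glrlms list of 13 GLRLM `grayLevelMatrix` objects.
#' @param glszm,gldm,ngtdm single matrices of the remaining families.
#' @return named numeric(74) in canonical order (glcm 23, glrlm 16,
#'   glszm 16, gldm 14, ngtdm 5).
#' @export
textureFeatures <- function(glcms, glrlms, glszm, gldm, ngtdm) {
  avgDir <- function(mats, fun, nms) {
    vals <- vapply(mats, function(m) fun(m), numeric(length(nms)))
    ok <- !apply(is.na(vals), 2, any)
    if (!all(ok)) logNote("dropping %d direction(s) from average", sum(!ok))
    rowMeans(vals[, ok, drop = FALSE])
  }
  out <- c(avgDir(glcms, .glcmFeatures, .glcmNames),
           avgDir(glrlms, .glrlmFeatures, .glrlmNames),
           .glszmFeatures(glszm),
           .gldmFeatures(gldm),
           .ngtdmFeatures(ngtdm))
  setNames(as.numeric(out),
           c(featureNames105("glcm"), featureNames105("glrlm"),
             featureNames105("glszm"), featureNames105("gldm"),
             featureNames105("ngtdm")))
}

#' Extract all 105 radiomic features from one volume + VOI
#'
#' Runs the full feature engine: first-order statistics on the raw and
#' discretized intensities, shape features of the mask geometry, and the
#' 74 texture features from the five gray-level matrix families (GLCM and
#' GLRLM averaged over the 13 lattice directions).
#'
#' @param volume a [QsmVolume-class].
#' @param mask a [VoiMask-class] on the same grid.
#' @param config a [StudyConfig-class]; governs the binning policy.
#' @return named numeric(105) in the canonical [featureNames105()] order.
#' @export
extractAll <- function(volume, mask, config = studyConfig()) {
  disc <- discretizeVoi(volume, mask, config)
  dirs <- directionSet()
  # the co-occurrence distance delta scales the offsets; run/dependence
  # definitions are pinned at unit steps (the study's delta = 1)
  glcms <- lapply(seq_len(13),
                  function(k) glcmMatrix(disc, dirs[k, ] * config@delta))
  glrlms <- lapply(seq_len(13), function(k) glrlmMatrix(disc, dirs[k, ]))
  out <- c(firstOrderFeatures(volume, mask, disc),
           shapeFeatures(mask, volume@spacing),
           textureFeatures(glcms, glrlms, glszmMatrix(disc),
                           gldmMatrix(disc), ngtdmMatrix(disc)))
  stopifnot(identical(names(out), featureNames105()))
  out
}
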