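# Synthetic cohort generator. The generator emulates the measured
# class-conditional statistics of the nigrosome-1 VOI: per-class VOI size,
# a spatially smoothed susceptibility field whose subject-level median and
# 10th percentile land at the published group means, and a low-susceptibility
# "nigrosome pocket" present in most controls but few patients (mirroring
# the swallow-tail sign visualization rates). See the methods vignette for
# the derivation of every default.

#' Reference class-conditional effect sizes
#'
#' Group means and standard deviations of the five representative features
#' (10th percentile and median susceptibility in ppm, VOI volume in voxels,
#' GLRLM long-run low-gray-level emphasis, GLSZM gray-level non-uniformity)
#' for IPD patients and healthy controls, together with the published
#' per-feature AUCs. These parameterise both the image-level generator and
#' the direct Gaussian feature simulator.
#'
#' @return data.frame with columns feature, ipdMean, ipdSd, hcMean, hcSd,
#'   auc.
#' @export
referenceEffectSizes <- function() {
  data.frame(
    feature = c("firstorder_10Percentile", "firstorder_Median",
                "shape_Volume", "glrlm_LongRunLowGrayLevelEmphasis",
                "glszm_GrayLevelNonUniformity"),
    ipdMean = c(0.023, 0.076, 519.514, 0.420, 5.769),
    ipdSd   = c(0.007, 0.016, 128.743, 0.133, 2.442),
    hcMean  = c(0.015, 0.066, 629.073, 0.546, 7.583),
    hcSd    = c(0.009, 0.015, 129.558, 0.312, 2.707),
    auc     = c(0.75, 0.68, 0.73, 0.64, 0.71),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the study conditions: 87 IPD patients and 77
#' retained controls; VOI voxel counts drawn per class from the published
#' volume distributions; within-VOI field levels set so the subject
#' median and (through the field sd and the pocket) the 10th percentile
#' match the published group means; pocket prevalence equal to the
#' published swallow-tail visualization rates (67.5% of HC, 9.2% of IPD);
#' motor-score coupling calibrated for a population correlation of about
#' 0.35 with the subject's low-quantile susceptibility.
#'
#' @param nIpd,nHc class sizes.
#' @param volumeMean,volumeSd named numeric(2) (`IPD`, `HC`): VOI voxel
#'   count distribution per class.
#' @param fieldMean named numeric(2): median susceptibility of the VOI
#'   field per class (ppm).
#' @param fieldSd named numeric(2): within-VOI susceptibility sd (ppm).
#' @param smoothSigma named numeric(2): Gaussian smoothing width (voxels)
#'   of the random field per class, controlling the field's spatial
#'   correlation length; symmetric by default (the class texture contrast
#'   comes from the pocket, not the base field).
#' @param subjectSd between-subject sd of the field mean (ppm).
#' @param pocketFraction fraction of VOI voxels in the nigrosome pocket,
#'   in (0, 1).
#' @param pocketOffset susceptibility offset of the pocket centre relative
#'   to the subject's field level (ppm, negative = low-susceptibility
#'   pocket).
#' @param pocketTightness factor in (0, 1] damping the field variance
#'   inside the pocket; small values make the pocket a coherent band of
#'   low gray levels.
#' @param pocketProb named numeric(2): probability that a subject of each
#'   class carries the pocket.
#' @param motorCoupling,motorNoiseSd,motorIntercept linear coupling of the
#'   IPD motor score to the subject's 10th-percentile susceptibility:
#'   `score = intercept + coupling * p10 + N(0, noiseSd)`.
#' @param gridDim integer(3) grid dimensions; `slices` the axial slices
#'   spanned by every VOI (four, as segmented in the study).
#' @param spacing voxel spacing in mm.
#' @param seed integer random seed.
#' @return object of class `CohortSpec` (a validated list).
#' @export
cohortSpec <- function(nIpd = 87L, nHc = 77L,
                       volumeMean = c(IPD = 519.514, HC = 629.073),
                       volumeSd = c(IPD = 128.743, HC = 129.558),
                       fieldMean = c(IPD = 0.076, HC = 0.066),
                       fieldSd = c(IPD = 0.041, HC = 0.038),
                       smoothSigma = c(IPD = 0.6, HC = 0.6),
                       subjectSd = 0.012,
                       pocketFraction = 0.15,
                       pocketOffset = -0.055,
                       pocketTightness = 0.35,
                       pocketProb = c(IPD = 0.092, HC = 0.675),
                       motorCoupling = 500,
                       motorNoiseSd = 16.1,
                       motorIntercept = 13.5,
                       gridDim = c(28L, 28L, 8L),
                       spacing = c(0.86, 0.86, 1.0),
                       slices = 3:6,
                       seed = 1L) {
  spec <- list(nIpd = as.integer(nIpd), nHc = as.integer(nHc),
               volumeMean = volumeMean, volumeSd = volumeSd,
               fieldMean = fieldMean, fieldSd = fieldSd,
               smoothSigma = smoothSigma, subjectSd = subjectSd, pocketFraction = pocketFraction,
               pocketOffset = pocketOffset,
               pocketTightness = pocketTightness, pocketProb = pocketProb,
               motorCoupling = motorCoupling, motorNoiseSd = motorNoiseSd,
               motorIntercept = motorIntercept,
               gridDim = as.integer(gridDim), spacing = spacing,
               slices = as.integer(slices), seed = as.integer(seed))
  if (spec$nIpd < 1L || spec$nHc < 1L)
    stop("spec error: class sizes must be >= 1")
  if (any(spec$volumeMean <= 0))
    stop("spec error: voxel-count means must be positive")
  if (spec$pocketFraction <= 0 || spec$pocketFraction >= 1)
    stop("spec error: pocket fraction must lie in (0, 1)")
  if (length(spec$slices) != 4L)
    stop("spec error: the VOI spans exactly four slices")
  class(spec) <- "CohortSpec"
  spec
}

#' @export
print.CohortSpec <- function(x, ...) {
  cat(sprintf("CohortSpec: %d IPD + %d HC, grid %s, 4-slice VOI, seed %d\n",
              x$nIpd, x$nHc, paste(x$gridDim, collapse = "x"), x$seed))
  invisible(x)
}

# Separable 3x3x3 Gaussian smoothing (sigma in voxels) to give the field
# short-range spatial correlation.
.smooth3 <- function(a, sigma = 0.7) {
  w1 <- exp(-1 / (2 * sigma^2))
  w <- c(w1, 1, w1); w <- w / sum(w)
  for (ax in 1:3) {
    up <- shiftArray(a, (1:3 == ax) * 1L, fill = NA)
    dn <- shiftArray(a, (1:3 == ax) * -1L, fill = NA)
    up[is.na(up)] <- a[is.na(up)]
    dn[is.na(dn)] <- a[is.na(dn)]
    a <- w[1] * dn + w[2] * a + w[3] * up
  }
  a
}

# Rasterize one subject's 4-slice elliptical VOI with ~nTarget voxels.
.makeVoiMask <- function(nTarget, gridDim, slices) {
  mask <- array(FALSE, dim = gridDim)
  cx <- gridDim[1] / 2 + runif(1, -0.5, 0.5)
  cy <- gridDim[2] / 2 + runif(1, -0.5, 0.5)
  perSlice <- nTarget / length(slices)
  prof <- c(0.92, 1.08, 1.08, 0.92)      # slight mid-slice bulge
  for (k in seq_along(slices)) {
    area <- perSlice * prof[k]
    a <- sqrt(area / (pi * 0.72))
    b <- 0.72 * a
    ix <- seq_len(gridDim[1]); iy <- seq_len(gridDim[2])
    ell <- outer(((ix - cx) / a)^2, ((iy - cy) / b)^2, `+`) <= 1
    mask[, , slices[k]] <- ell
  }
  mask
}

.generateSubject <- function(id, label, spec) {
  cls <- label
  nTarget <- max(80, round(rnorm(1, spec$volumeMean[cls],
                                 spec$volumeSd[cls])))
  mask <- .makeVoiMask(nTarget, spec$gridDim, spec$slices)
  nvox <- sum(mask)
  # smoothed Gaussian random field, re-standardized inside the VOI so the
  # within-VOI sd is exact, then shifted to the subject's mean level
  muS <- rnorm(1, spec$fieldMean[cls], spec$subjectSd)
  field <- .smooth3(array(rnorm(prod(spec$gridDim)), dim = spec$gridDim),
                    sigma = spec$smoothSigma[cls])
  inVoi <- field[mask]
  inVoi <- (inVoi - mean(inVoi)) / stats::sd(inVoi)
  vals <- array(rnorm(prod(spec$gridDim), 0.02, 0.01), dim = spec$gridDim)
  vals[mask] <- muS + spec$fieldSd[cls] * inVoi
  # nigrosome pocket: contiguous low-susceptibility sub-region
  hasPocket <- runif(1) < spec$pocketProb[cls]
  if (hasPocket) {
    idx <- which(mask, arr.ind = TRUE)
    ctr <- colMeans(idx)
    ctr[1] <- ctr[1] + 0.25 * diff(range(idx[, 1]))   # lateral pocket
    d2 <- ((idx[, 1] - ctr[1]) / 1.0)^2 +
          ((idx[, 2] - ctr[2]) / 0.8)^2 +
          ((idx[, 3] - ctr[3]) / 0.5)^2
    nPocket <- max(1L, round(spec$pocketFraction * nvox))
    sel <- idx[order(d2)[seq_len(nPocket)], , drop = FALSE]
    # the pocket is a coherent structure: damped internal variance puts its
    # voxels in a tight, contiguous band of low susceptibility
    vals[sel] <- muS + spec$pocketOffset +
      spec$pocketTightness * (vals[sel] - muS)
  }
  score <- if (cls == "IPD") {
    p10 <- quantile(vals[mask], 0.10, names = FALSE, type = 7)
    spec$motorIntercept + spec$motorCoupling * p10 +
      rnorm(1, 0, spec$motorNoiseSd)
  } else NA_real_
  list(id = id, label = cls,
       volume = QsmVolume(vals, spec$spacing), mask = VoiMask(mask),
       score = score, pocket = hasPocket)
}

#' Generate a labeled synthetic cohort of volumes + VOI masks
#'
#' Draws `nIpd + nHc` subjects. Each healthy control carries, with the
#' configured probability, a low-susceptibility nigrosome pocket inside
#' its VOI (emulating a preserved swallow-tail sign) while patient VOIs
#' are spatially more uniform with a higher low-quantile susceptibility;
#' VOI voxel counts follow the per-class volume distributions, and patient
#' motor scores are positively coupled to the subject's 10th-percentile
#' susceptibility. Fixed seed gives a bit-identical cohort.
#'
#' @param spec a [cohortSpec()].
#' @return list of subjects; each a list with `id`, `label` ("IPD"/"HC"),
#'   `volume` ([QsmVolume-class]), `mask` ([VoiMask-class]), `score`
#'   (NA for HC) and `pocket` (logical).
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  labels <- c(rep("IPD", spec$nIpd), rep("HC", spec$nHc))
  ids <- sprintf("S%03d", seq_along(labels))
  mapply(.generateSubject, ids, labels, MoreArgs = list(spec = spec),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Simulate the feature table directly from class-conditional Gaussians
#'
#' Bypasses image synthesis: the five representative features are drawn
#' from per-class Gaussians at the reference effect sizes (see
#' [referenceEffectSizes()]), the remaining 100 features are standard
#' normal nuisance noise identical in distribution across classes, and
#' the IPD motor score is linearly coupled to the subject's
#' 10th-percentile draw. Used by the analytic recovery checks.
#'
#' @param spec a [cohortSpec()] (class sizes, coupling and seed are used).
#' @param effects data.frame as from [referenceEffectSizes()].
#' @return a `SummarizedExperiment` feature table.
#' @export
generateFeatureTable <- function(spec = cohortSpec(),
                                 effects = referenceEffectSizes()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- spec$nIpd + spec$nHc
  labels <- c(rep("IPD", spec$nIpd), rep("HC", spec$nHc))
  mat <- matrix(rnorm(n * 105L), nrow = n,
                dimnames = list(sprintf("S%03d", 1:n), featureNames105()))
  for (r in seq_len(nrow(effects))) {
    f <- effects$feature[r]
    mat[labels == "IPD", f] <- rnorm(spec$nIpd, effects$ipdMean[r],
                                     effects$ipdSd[r])
    mat[labels == "HC", f] <- rnorm(spec$nHc, effects$hcMean[r],
                                    effects$hcSd[r])
  }
  p10 <- mat[, "firstorder_10Percentile"]
  row10 <- match("firstorder_10Percentile", effects$feature)
  # noise sd set from the p10 spread so the population correlation with the
  # motor score is the calibrated target
  score <- ifelse(
    labels == "IPD",
    spec$motorIntercept + spec$motorCoupling * p10 +
      rnorm(n, 0, spec$motorCoupling * effects$ipdSd[row10] *
              sqrt(1 / 0.35^2 - 1)),
    NA_real_)
  featureExperiment(mat, labels = labels, motorScores = score)
}
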