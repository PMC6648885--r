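#' Construct a QsmVolume
#'
#' @param values 3D numeric array of susceptibility values (ppm).
#' @param spacing numeric(3) voxel spacing in mm; defaults to the study's
#'   acquisition grid 0.86 x 0.86 x 1.0 mm.
#' @return A [QsmVolume-class] object.
#' @export
QsmVolume <- function(values, spacing = c(0.86, 0.86, 1.0)) {
  new("QsmVolume", values = values, spacing = as.numeric(spacing))
}

#' Construct a VoiMask
#'
#' @param mask logical or 0/1 numeric 3D array.
#' @return A [VoiMask-class] object.
#' @export
VoiMask <- function(mask) {
  if (!is.logical(mask)) {
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1)))
      stop("mask values must be 0/1")
    mask <- array(mask != 0, dim = dim(mask))
  }
  new("VoiMask", mask = mask)
}

#' @rdname QsmVolume
#' @param x a `QsmVolume`.
#' @export
voxelValues <- function(x) x@values

#' @rdname QsmVolume
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname VoiMask
#' @param x a `VoiMask`.
#' @export
maskArray <- function(x) x@mask

#' @rdname VoiMask
#' @export
voiSize <- function(x) sum(x@mask)

#' Susceptibility values inside the VOI
#'
#' @param volume a [QsmVolume-class].
#' @param mask a [VoiMask-class] on the same grid.
#' @return numeric vector of in-VOI voxel values (ppm).
#' @export
voiValues <- function(volume, mask) {
  stopifnot(identical(dim(volume@values), dim(mask@mask)))
  volume@values[mask@mask]
}

#' Construct a StudyConfig
#'
#' Defaults follow the published protocol: one-voxel texture neighbourhood
#' (delta = 1), RBF-SVM with C = 30 and gamma = 0.001, 3-fold
#' cross-validation with 10 repetitions, 40 ensemble-selected features and
#' a Bonferroni family of 40 comparisons. The intensity binning policy is
#' a package choice (fixed count of 32 levels over the VOI's own range);
#' pass `binWidth` (ppm) instead to switch policy.
#'
#' @param binCount integer; number of gray-level bins (default 32).
#' @param binWidth numeric; fixed bin width in ppm (mutually exclusive
#'   with `binCount`).
#' @param delta neighbourhood distance in voxel steps.
#' @param svmCost,svmGamma RBF-SVM hyperparameters C and gamma.
#' @param cvFolds,cvRepeats cross-validation folds k and repetitions R.
#' @param nSelect number of features kept by ensemble selection.
#' @param bonferroniN family size n for the 0.05/n significance threshold.
#' @param seed master random seed.
#' @return A [StudyConfig-class] object.
#' @export
studyConfig <- function(binCount = 32L, binWidth = NULL, delta = 1L,
                        svmCost = 30, svmGamma = 0.001,
                        cvFolds = 3L, cvRepeats = 10L,
                        nSelect = 40L, bonferroniN = 40L, seed = 1L) {
  if (!is.null(binWidth)) binCount <- NA_integer_
  new("StudyConfig",
      binCount = as.integer(binCount),
      binWidth = if (is.null(binWidth)) NA_real_ else as.numeric(binWidth),
      delta = as.integer(delta), svmCost = as.numeric(svmCost),
      svmGamma = as.numeric(svmGamma), cvFolds = as.integer(cvFolds),
      cvRepeats = as.integer(cvRepeats), nSelect = as.integer(nSelect),
      bonferroniN = as.integer(bonferroniN), seed = as.integer(seed))
}
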