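#' @import methods
#' @importFrom stats sd var quantile rnorm runif cor cor.test t.test
#'   prcomp pt pf pnorm setNames aggregate
#' @importFrom utils head read.csv write.csv
NULL

#' QsmVolume: a 3D scalar susceptibility field
#'
#' Container for a reconstructed quantitative susceptibility map (QSM):
#' a 3D numeric array of susceptibility values (ppm) together with the
#' anisotropic voxel spacing in mm. The third array axis is the slice
#' (axial) direction.
#'
#' @slot values 3D numeric array, susceptibility in ppm.
#' @slot spacing numeric(3), voxel spacing (dx, dy, dz) in mm, all > 0.
#' @export
setClass("QsmVolume",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive finite numbers (mm)")
    if (length(msg)) msg else TRUE
  })

#' VoiMask: a binary volume of interest
#'
#' Binary 3D mask selecting the nigrosome-1-containing volume of interest
#' (VOI) on a co-registered [QsmVolume]. Stored as a logical array with the
#' same dimensions as its grid.
#'
#' @slot mask logical 3D array.
#' @export
setClass("VoiMask",
  representation(mask = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "'mask' must be a 3D array")
    if (!is.logical(object@mask))
      msg <- c(msg, "'mask' must be logical")
    if (length(msg)) msg else TRUE
  })

#' DiscretizedVoi: gray-level discretized VOI
#'
#' Result of intensity discretization of the VOI voxels into integer gray
#' levels 1..Ng. Voxels outside the VOI carry NA and are excluded from every
#' texture matrix.
#'
#' @slot levels integer 3D array; NA outside the VOI.
#' @slot ng integer(1), number of gray levels (maximum level in use).
#' @export
setClass("DiscretizedVoi",
  representation(levels = "array", ng = "integer"),
  validity = function(object) {
    msg <- character()
    lv <- object@levels[!is.na(object@levels)]
    if (length(lv) == 0L)
      msg <- c(msg, "discretized VOI is empty")
    else if (any(lv < 1L) || any(lv > object@ng))
      msg <- c(msg, "levels must lie in [1, ng]")
    if (length(object@ng) != 1L || object@ng < 1L)
      msg <- c(msg, "'ng' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  })

#' StudyConfig: pipeline parameters
#'
#' Bundles every tunable of the analysis: the intensity binning policy
#' (fixed bin count or fixed bin width in ppm — exactly one active), the
#' texture neighbourhood distance delta (voxel steps), SVM hyperparameters
#' C and gamma, the cross-validation layout (k folds, R repetitions), the
#' number of ensemble-selected features, the Bonferroni family size and the
#' master random seed.
#'
#' @slot binCount integer(1) or NA; number of gray-level bins.
#' @slot binWidth numeric(1) or NA; bin width in ppm.
#' @slot delta integer(1), neighbourhood distance in voxel steps (>= 1).
#' @slot svmCost numeric(1), SVM penalty C (> 0).
#' @slot svmGamma numeric(1), RBF kernel width gamma (> 0).
#' @slot cvFolds integer(1), folds k (>= 2).
#' @slot cvRepeats integer(1), repetitions R (>= 1).
#' @slot nSelect integer(1), number of features kept by ensemble selection.
#' @slot bonferroniN integer(1), family size for the 0.05/n threshold.
#' @slot seed integer(1), master random seed.
#' @export
setClass("StudyConfig",
  representation(binCount = "integer", binWidth = "numeric",
                 delta = "integer", svmCost = "numeric",
                 svmGamma = "numeric", cvFolds = "integer",
                 cvRepeats = "integer", nSelect = "integer",
                 bonferroniN = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    hasCount <- !is.na(object@binCount)
    hasWidth <- !is.na(object@binWidth)
    if (hasCount == hasWidth)
      msg <- c(msg, "exactly one of binCount / binWidth must be set")
    if (hasCount && object@binCount < 1L)
      msg <- c(msg, "binCount must be >= 1")
    if (hasWidth && object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (object@delta < 1L) msg <- c(msg, "delta must be an integer >= 1")
    if (object@svmCost <= 0) msg <- c(msg, "svmCost must be > 0")
    if (object@svmGamma <= 0) msg <- c(msg, "svmGamma must be > 0")
    if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
    if (object@cvRepeats < 1L) msg <- c(msg, "cvRepeats must be >= 1")
    if (object@nSelect < 1L) msg <- c(msg, "nSelect must be >= 1")
    if (object@bonferroniN < 1L) msg <- c(msg, "bonferroniN must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' CvReport: repeated cross-validation results
#'
#' Per-repetition, per-fold classification metrics of the SVM pipeline,
#' together with the fold assignments, pooled summaries and ROC curves.
#'
#' @slot folds data.frame with one row per (repetition, fold): columns
#'   repetition, fold, nTrain, nTest, auc, accuracy, sensitivity,
#'   specificity.
#' @slot assignments integer matrix (subjects x repetitions) of fold labels.
#' @slot roc list of per-(repetition,fold) ROC data.frames (fpr, tpr).
#' @slot seed integer(1), the seed that produced the fold assignments.
#' @export
setClass("CvReport",
  representation(folds = "data.frame", assignments = "matrix",
                 roc = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("repetition", "fold", "nTrain", "nTest", "auc",
              "accuracy", "sensitivity", "specificity")
    if (!all(need %in% names(object@folds)))
      msg <- c(msg, "folds must contain the standard metric columns")
    met <- unlist(object@folds[c("accuracy", "sensitivity", "specificity")])
    if (length(met) && any(met < -1e-9 | met > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "metrics must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "QsmVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("QsmVolume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g] ppm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], min(object@values), max(object@values)))
})

setMethod("show", "VoiMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VoiMask %dx%dx%d, %d voxels in VOI across %d slice(s)\n",
              d[1], d[2], d[3], sum(object@mask),
              length(unique(which(object@mask, arr.ind = TRUE)[, 3]))))
})

setMethod("show", "DiscretizedVoi", function(object) {
  cat(sprintf("DiscretizedVoi: %d voxels, Ng = %d\n",
              sum(!is.na(object@levels)), object@ng))
})

setMethod("show", "StudyConfig", function(object) {
  pol <- if (!is.na(object@binCount))
    sprintf("bin count %d", object@binCount)
  else sprintf("bin width %g ppm", object@binWidth)
  cat(sprintf(paste0("StudyConfig: %s, delta=%d, SVM(C=%g, gamma=%g), ",
                     "%d-fold x %d reps, nSelect=%d, Bonferroni n=%d, seed=%d\n"),
              pol, object@delta, object@svmCost, object@svmGamma,
              object@cvFolds, object@cvRepeats, object@nSelect,
              object@bonferroniN, object@seed))
})

setMethod("show", "CvReport", function(object) {
  s <- cvSummary(object)
  cat(sprintf("CvReport: %d fold records (%d reps x %d folds), seed %d\n",
              nrow(object@folds), max(object@folds$repetition),
              max(object@folds$fold), object@seed))
  cat(sprintf("  AUC %.3f +/- %.3f | accuracy %.3f +/- %.3f | sensitivity %.3f +/- %.3f | specificity %.3f +/- %.3f\n",
              s["auc", "mean"], s["auc", "sd"],
              s["accuracy", "mean"], s["accuracy", "sd"],
              s["sensitivity", "mean"], s["sensitivity", "sd"],
              s["specificity", "mean"], s["specificity", "sd"]))
})
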