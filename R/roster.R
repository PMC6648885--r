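# Canonical roster of the 105 radiomic features: 18 first-order, 13 shape,
# 74 texture (GLCM 23, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5). Column order
# of every feature table is fixed to this list.

.firstOrderNames <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

.shapeNames <- c(
  "Volume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
  "Maximum3DDiameter", "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
  "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness")

.glcmNames <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

.glrlmNames <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

.glszmNames <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

.gldmNames <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

.ngtdmNames <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                 "Strength")

#' Canonical radiomic feature names
#'
#' Returns the fixed roster of the 105 feature names, prefixed by family
#' (`firstorder_`, `shape_`, `glcm_`, `glrlm_`, `glszm_`, `gldm_`,
#' `ngtdm_`). Every feature vector and feature table produced by the
#' package uses exactly this set, in this order.
#'
#' @param family optional; one of "firstorder", "shape", "glcm", "glrlm",
#'   "glszm", "gldm", "ngtdm" to return a single family's names.
#' @return character vector of feature names.
#' @examples
#' length(featureNames105())       # 105
#' head(featureNames105("shape"))
#' @export
featureNames105 <- function(family = NULL) {
  fams <- list(firstorder = .firstOrderNames, shape = .shapeNames,
               glcm = .glcmNames, glrlm = .glrlmNames,
               glszm = .glszmNames, gldm = .gldmNames,
               ngtdm = .ngtdmNames)
  if (!is.null(family)) {
    family <- match.arg(family, names(fams))
    return(paste0(family, "_", fams[[family]]))
  }
  unlist(lapply(names(fams), function(f) paste0(f, "_", fams[[f]])),
         use.names = FALSE)
}

#' Feature family of each canonical feature
#'
#' @return named character vector mapping each of the 105 names to its
#'   family.
#' @export
featureFamilies <- function() {
  nm <- featureNames105()
  setNames(sub("_.*$", "", nm), nm)
}
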