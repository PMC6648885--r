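#' First-order (intensity histogram) features
#'
#' The 18 first-order features describing the distribution of in-VOI
#' susceptibility values X (ppm). Entropy and Uniformity are computed on
#' the discretized gray-level histogram; percentiles use linear
#' interpolation between order statistics; TotalEnergy scales Energy by
#' the physical voxel volume (mm^3); Variance, Skewness and Kurtosis use
#' the population (denominator n) moments, with Skewness and Kurtosis
#' defined as 0 for a constant (or single-voxel) VOI.
#'
#' @param volume a [QsmVolume-class].
#' @param mask a [VoiMask-class] on the same grid (non-empty).
#' @param disc the [DiscretizedVoi-class] of the same VOI (for the
#'   histogram-based Entropy/Uniformity).
#' @return named numeric(18), names `firstorder_*` in canonical order.
#' @export
firstOrderFeatures <- function(volume, mask, disc) {
  x <- voiValues(volume, mask)
  n <- length(x)
  vv <- prod(volume@spacing)
  lev <- disc@levels[!is.na(disc@levels)]
  p <- tabulate(lev, nbins = disc@ng) / length(lev)
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  m2 <- popMoment(x, 2)
  if (m2 > 0) {
    skew <- popMoment(x, 3) / m2^1.5
    kurt <- popMoment(x, 4) / m2^2
  } else {
    skew <- kurt <- 0
    logNote("constant VOI: Skewness/Kurtosis set to 0")
  }
  inBand <- x >= q[1] & x <= q[5]
  vals <- c(
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(xlog2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mean(x),
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mean(x))),
    RobustMeanAbsoluteDeviation =
      mean(abs(x[inBand] - mean(x[inBand]))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
  setNames(as.numeric(vals), featureNames105("firstorder"))
}
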