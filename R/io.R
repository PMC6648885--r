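#' Read a susceptibility volume and its VOI mask
#'
#' Reads a NIfTI-1 QSM volume and its co-registered binary VOI mask,
#' checking that the two files share grid dimensions, that voxel spacing
#' is positive and that the mask is a non-empty 0/1 volume.
#'
#' @param volumePath path to the NIfTI susceptibility volume (ppm).
#' @param maskPath path to the NIfTI 0/1 mask.
#' @return list with elements `volume` ([QsmVolume-class]) and `mask`
#'   ([VoiMask-class]).
#' @export
readVolumeAndMask <- function(volumePath, maskPath) {
  stopifnot(file.exists(volumePath), file.exists(maskPath))
  vimg <- RNifti::readNifti(volumePath)
  mimg <- RNifti::readNifti(maskPath)
  if (!identical(dim(vimg), dim(mimg)))
    stop(sprintf("shape error: volume %s vs mask %s",
                 paste(dim(vimg), collapse = "x"),
                 paste(dim(mimg), collapse = "x")))
  spacing <- RNifti::pixdim(vimg)[1:3]
  mspacing <- RNifti::pixdim(mimg)[1:3]
  if (any(abs(spacing - mspacing) > 1e-4 * max(spacing)))
    stop("shape error: volume and mask voxel spacing differ")
  mvals <- unique(as.vector(mimg))
  if (!all(mvals %in% c(0, 1)))
    stop("mask values must be 0/1")
  if (!any(mimg != 0))
    stop("degenerate VOI: mask is empty")
  list(volume = QsmVolume(array(as.numeric(vimg), dim = dim(vimg)), spacing),
       mask = VoiMask(array(as.vector(mimg) != 0, dim = dim(mimg))))
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are written as float32 with the spacing in the header; masks as
#' integer 0/1.
#'
#' @param x a [QsmVolume-class] or [VoiMask-class].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param spacing for masks, the voxel spacing in mm to record.
#' @return the path, invisibly.
#' @export
writeNiftiVolume <- function(x, path, spacing = c(0.86, 0.86, 1.0)) {
  withPixdim <- function(arr, datatype, sp) {
    hdr <- RNifti::niftiHeader(RNifti::asNifti(arr, datatype = datatype))
    hdr$pixdim[2:4] <- sp
    RNifti::asNifti(arr, reference = hdr, datatype = datatype)
  }
  img <- if (is(x, "QsmVolume"))
    withPixdim(x@values, "float", x@spacing)
  else if (is(x, "VoiMask"))
    withPixdim(array(as.integer(x@mask), dim = dim(x@mask)), "int16",
               spacing)
  else stop("x must be a QsmVolume or VoiMask")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Writes the cohort feature table with stable column order: `subject_id`,
#' `label`, `motor_score` (if present), then the 105 canonical feature
#' columns. Round-trips losslessly through [readFeatureTable()] at full
#' double precision.
#'
#' @param table a `SummarizedExperiment` from [featureExperiment()] /
#'   [extractCohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  mat <- featureMatrix(table)
  if (!identical(colnames(mat), featureNames105()))
    stop(sprintf("incomplete row: expected the %d canonical features, got %d",
                 length(featureNames105()), ncol(mat)))
  if (any(!is.finite(mat)))
    stop("incomplete row: missing feature values")
  cd <- SummarizedExperiment::colData(table)
  df <- data.frame(subject_id = rownames(mat),
                   label = as.character(cd$label),
                   check.names = FALSE)
  if ("motor_score" %in% names(cd))
    df$motor_score <- cd$motor_score
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  # full precision (17 significant digits) so write -> read is exact
  cols <- lapply(df, function(col)
    if (is.numeric(col)) trimws(formatC(col, digits = 17, format = "g"))
    else as.character(col))
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), body), path)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return a `SummarizedExperiment` with the canonical feature roster.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- featureNames105()
  if (!all(need %in% names(df)))
    stop("incomplete row: CSV lacks canonical feature columns")
  mat <- as.matrix(df[, need])
  rownames(mat) <- df$subject_id
  featureExperiment(mat, labels = df$label,
                    motorScores = if ("motor_score" %in% names(df))
                      df$motor_score else NULL,
                    subjectIds = df$subject_id)
}

#' Write a run report as JSON
#'
#' Serialises ranks, selected features, per-fold CV metrics or group
#' statistics to pretty-printed JSON.
#'
#' @param report a list (or coercible object) to serialise.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  if (is(report, "CvReport"))
    report <- list(seed = report@seed, folds = report@folds,
                   summary = as.data.frame(cvSummary(report)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
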