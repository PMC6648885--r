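#' Build the cohort feature table as a SummarizedExperiment
#'
#' The cohort container is a `SummarizedExperiment` whose assay
#' `"features"` holds the 105 canonical features (rows) by subjects
#' (columns), with `colData` carrying the subject id, the class label
#' (factor HC/IPD, IPD = positive class) and, when available, the
#' UPDRS-III-like motor score.
#'
#' @param mat numeric matrix, subjects x 105 features, columns named by
#'   [featureNames105()].
#' @param labels character/factor of class labels ("IPD"/"HC"), one per
#'   subject.
#' @param motorScores optional numeric motor scores (NA allowed for HC).
#' @param subjectIds optional subject identifiers.
#' @return a `SummarizedExperiment`.
#' @export
featureExperiment <- function(mat, labels, motorScores = NULL,
                              subjectIds = NULL) {
  stopifnot(is.matrix(mat))
  if (!identical(colnames(mat), featureNames105()))
    stop("feature matrix must have the 105 canonical columns in order")
  if (nrow(mat) != length(labels))
    stop("one label per subject required")
  if (is.null(subjectIds))
    subjectIds <- if (!is.null(rownames(mat))) rownames(mat)
                  else sprintf("S%03d", seq_len(nrow(mat)))
  labels <- factor(as.character(labels), levels = c("HC", "IPD"))
  if (any(is.na(labels))) stop("labels must be 'HC' or 'IPD'")
  cd <- S4Vectors::DataFrame(subject_id = subjectIds, label = labels)
  if (!is.null(motorScores)) cd$motor_score <- motorScores
  fams <- featureFamilies()
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat)),
    rowData = S4Vectors::DataFrame(family = unname(fams),
                                   row.names = names(fams)),
    colData = cd)
}

#' Subjects-by-features matrix of a feature table
#'
#' @param se a `SummarizedExperiment` from [featureExperiment()].
#' @return numeric matrix, subjects x features.
#' @export
featureMatrix <- function(se) {
  m <- t(SummarizedExperiment::assay(se, "features"))
  rownames(m) <- SummarizedExperiment::colData(se)$subject_id
  m
}

#' Class labels of a feature table
#'
#' @param se a `SummarizedExperiment` from [featureExperiment()].
#' @return factor with levels HC, IPD.
#' @export
subjectLabels <- function(se) SummarizedExperiment::colData(se)$label

#' Motor scores of a feature table
#'
#' @param se a `SummarizedExperiment` from [featureExperiment()].
#' @return numeric vector (NA where unavailable), or NULL if absent.
#' @export
motorScores <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if ("motor_score" %in% names(cd)) cd$motor_score else NULL
}

#' Extract features for a whole cohort
#'
#' Runs [extractAll()] on each subject of a synthetic (or loaded) cohort
#' and stacks the results into the cohort feature table.
#'
#' @param cohort list of subjects as produced by [generateCohort()]: each
#'   element has `id`, `label`, `volume`, `mask` and optional `score`.
#' @param config a [StudyConfig-class].
#' @return a `SummarizedExperiment` (see [featureExperiment()]).
#' @export
extractCohort <- function(cohort, config = studyConfig()) {
  mat <- t(vapply(cohort, function(s)
    extractAll(s$volume, s$mask, config), numeric(105L)))
  rownames(mat) <- vapply(cohort, `[[`, character(1), "id")
  featureExperiment(
    mat,
    labels = vapply(cohort, `[[`, character(1), "label"),
    motorScores = vapply(cohort, function(s)
      if (is.null(s$score)) NA_real_ else s$score, numeric(1)),
    subjectIds = rownames(mat))
}
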