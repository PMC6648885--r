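#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> extract -> select -> classify -> stats in one deterministic
#' call: generates the cohort, extracts the 105 features, performs
#' ensemble selection, cross-validates the RBF-SVM on the selected
#' features and computes the group statistics of the five reference
#' features. All randomness flows from `spec$seed` / `config@seed`.
#'
#' @param spec a [cohortSpec()].
#' @param config a [StudyConfig-class].
#' @param paperMode passed to [crossValidate()].
#' @return list with `table` (feature `SummarizedExperiment`), `selection`
#'   (see [ensembleSelect()]), `cv` ([CvReport-class]), `stats` (see
#'   [groupStatistics()]).
#' @export
runPipeline <- function(spec = cohortSpec(), config = studyConfig(),
                        paperMode = FALSE) {
  logNote("simulate: %d subjects, seed %d", spec$nIpd + spec$nHc, spec$seed)
  cohort <- generateCohort(spec)
  logNote("extract: %d features", length(featureNames105()))
  se <- extractCohort(cohort, config)
  logNote("select: top %d by ensemble rank", config@nSelect)
  sel <- ensembleSelect(se, nSelect = config@nSelect, seed = config@seed)
  logNote("classify: %d-fold x %d reps", config@cvFolds, config@cvRepeats)
  cv <- crossValidate(sel$reduced, config, labels = subjectLabels(se),
                      paperMode = paperMode)
  st <- groupStatistics(se, familyN = config@bonferroniN)
  list(table = se, selection = sel, cv = cv, stats = st)
}

#' Read a StudyConfig from a YAML or JSON file
#'
#' Recognised keys mirror the [studyConfig()] arguments (`binCount`,
#' `binWidth`, `delta`, `svmCost`, `svmGamma`, `cvFolds`, `cvRepeats`,
#' `nSelect`, `bonferroniN`, `seed`); missing keys keep their defaults.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a [StudyConfig-class].
#' @export
readStudyConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(studyConfig))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(studyConfig, vals)
}
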