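# RBF-SVM classification under repeated stratified k-fold cross-validation.
# Per-fold pipeline: standardize -> PCA (all components) -> SVM, each step
# fitted on the training folds only (leakage-safe); paperMode = TRUE fits
# the standardizer and PCA on the full table before splitting, mirroring
# the original description.

#' Standardize features with training-set statistics
#'
#' Per-feature (x - mu_train) / sigma_train applied to both tables;
#' a zero-variance training feature maps to 0 everywhere.
#'
#' @param train,test numeric matrices (subjects x features); `test` may be
#'   NULL.
#' @return list `train`, `test`, `center`, `scale`.
#' @export
standardizeFeatures <- function(train, test = NULL) {
  mu <- colMeans(train)
  sg <- apply(train, 2, stats::sd)
  zero <- sg == 0
  if (any(zero)) {
    logNote("%d constant training feature(s) mapped to 0", sum(zero))
    sg[zero] <- 1
  }
  tr <- sweep(sweep(train, 2, mu), 2, sg, `/`)
  te <- if (!is.null(test)) sweep(sweep(test, 2, mu), 2, sg, `/`)
  if (any(zero)) {                      # sigma = 0 contract: feature -> 0
    tr[, zero] <- 0
    if (!is.null(te)) te[, zero] <- 0
  }
  list(train = tr, test = te, center = mu, scale = sg)
}

#' PCA rotation fitted on the training set
#'
#' Projects both tables onto the principal components of the training
#' set. All components are retained (no truncation); a rank-deficient
#' training set yields as many components as its rank.
#'
#' @param train,test standardized matrices; `test` may be NULL.
#' @return list `train`, `test`, `rotation`, `center`.
#' @export
pcaTransform <- function(train, test = NULL) {
  fit <- prcomp(train, center = FALSE, scale. = FALSE)
  keep <- fit$sdev > max(fit$sdev) * 1e-10
  if (!all(keep)) logNote("rank-deficient train: %d components", sum(keep))
  rot <- fit$rotation[, keep, drop = FALSE]
  list(train = train %*% rot,
       test = if (!is.null(test)) test %*% rot,
       rotation = rot)
}

#' Train an RBF-kernel SVM
#'
#' Fits the soft-margin SVM with Gaussian kernel
#' `K(xi, xj) = exp(-gamma * ||xi - xj||^2)` at penalty `C`; the returned
#' object predicts a continuous margin score (positive = IPD) and a hard
#' label at threshold 0.
#'
#' @param train numeric matrix (subjects x features).
#' @param labels factor with levels HC/IPD, both present.
#' @param C penalty parameter (default 30).
#' @param gamma kernel width (default 0.001).
#' @return list with `model` and `predict(newdata)` returning a
#'   data.frame (score, label).
#' @export
trainSvm <- function(train, labels, C = 30, gamma = 0.001) {
  labels <- droplevels(factor(labels, levels = c("HC", "IPD")))
  if (nlevels(labels) < 2) stop("single-class training set")
  fit <- e1071::svm(train, labels, kernel = "radial", cost = C,
                    gamma = gamma, scale = FALSE)
  # orient the margin so that positive = IPD regardless of internal order
  sgn <- if (fit$labels[1] == which(levels(labels) == "IPD")) 1 else -1
  dv <- attr(stats::predict(fit, train, decision.values = TRUE),
             "decision.values")[, 1] * sgn
  flip <- if (mean(dv[labels == "IPD"]) < mean(dv[labels == "HC"])) -1 else 1
  predictFun <- function(newdata) {
    pr <- stats::predict(fit, newdata, decision.values = TRUE)
    score <- attr(pr, "decision.values")[, 1] * sgn * flip
    data.frame(score = score,
               label = factor(ifelse(score > 0, "IPD", "HC"),
                              levels = c("HC", "IPD")))
  }
  list(model = fit, predict = predictFun)
}

#' Classification metrics from continuous scores
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for score
#' ties; accuracy, sensitivity (`TP/(TP+FN)` on the positive IPD class)
#' and specificity from the hard labels at decision threshold 0; plus the
#' empirical ROC curve.
#'
#' @param scores numeric margin scores (higher = more IPD-like).
#' @param truth factor/character of true labels (HC/IPD).
#' @param positive positive class (default "IPD").
#' @return list `auc`, `accuracy`, `sensitivity`, `specificity`, `roc`
#'   (data.frame fpr, tpr).
#' @export
computeMetrics <- function(scores, truth, positive = "IPD") {
  truth <- as.character(truth)
  pos <- truth == positive
  if (!any(pos) || all(pos)) stop("AUC undefined: one-class truth")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- scores > 0
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  list(auc = auc,
       accuracy = mean(pred == pos),
       sensitivity = sum(pred & pos) / n1,
       specificity = sum(!pred & !pos) / n0,
       roc = roc)
}

# stratified fold assignment: permute within class, deal folds round-robin
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the SVM pipeline
#'
#' Shuffles the cohort into k stratified folds, R times; per fold fits
#' standardize -> PCA -> RBF-SVM on the training folds and evaluates on
#' the held-out fold. IPD is the positive class throughout. Pooled
#' mean +/- sd are recomputable from the `R x k` stored fold records. A
#' test fold that ends up single-class gets NA AUC (recorded, logged).
#'
#' @param se feature table (`SummarizedExperiment`), or a plain subjects x
#'   features matrix together with `labels`.
#' @param config a [StudyConfig-class] (folds, repetitions, C, gamma,
#'   seed).
#' @param labels required when `se` is a matrix.
#' @param paperMode logical; TRUE fits standardization and PCA on the
#'   full table before splitting (mirroring the original description)
#'   instead of within each training fold.
#' @param stratified logical; stratify folds by class (default TRUE).
#' @return a [CvReport-class].
#' @export
crossValidate <- function(se, config = studyConfig(), labels = NULL,
                          paperMode = FALSE, stratified = TRUE) {
  if (is.matrix(se)) {
    x <- se
    stopifnot(!is.null(labels))
    labels <- factor(as.character(labels), levels = c("HC", "IPD"))
  } else {
    x <- featureMatrix(se)
    labels <- subjectLabels(se)
  }
  if (nlevels(droplevels(labels)) < 2) stop("cohort must contain both classes")
  n <- nrow(x); k <- config@cvFolds; R <- config@cvRepeats
  set.seed(config@seed)
  if (paperMode) {
    st <- standardizeFeatures(x)
    x <- pcaTransform(st$train)$train
  }
  assignments <- matrix(NA_integer_, n, R)
  rows <- list(); rocs <- list()
  for (r in seq_len(R)) {
    fold <- if (stratified) .stratifiedFolds(labels, k)
            else sample(rep_len(seq_len(k), n))
    assignments[, r] <- fold
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
      if (!paperMode) {
        st <- standardizeFeatures(xtr, xte)
        pc <- pcaTransform(st$train, st$test)
        xtr <- pc$train; xte <- pc$test
      }
      svmFit <- trainSvm(xtr, labels[tr], C = config@svmCost,
                         gamma = config@svmGamma)
      pred <- svmFit$predict(xte)
      truthTe <- labels[te]
      if (nlevels(droplevels(truthTe)) < 2) {
        logNote("rep %d fold %d: one-class test fold, AUC missing", r, f)
        met <- list(auc = NA_real_,
                    accuracy = mean(pred$label == truthTe),
                    sensitivity = NA_real_, specificity = NA_real_,
                    roc = data.frame(fpr = numeric(0), tpr = numeric(0)))
      } else met <- computeMetrics(pred$score, truthTe)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = r, fold = f, nTrain = sum(tr), nTest = sum(te),
        auc = met$auc, accuracy = met$accuracy,
        sensitivity = met$sensitivity, specificity = met$specificity)
      rocs[[sprintf("r%02df%d", r, f)]] <- met$roc
    }
  }
  new("CvReport", folds = do.call(rbind, rows), assignments = assignments,
      roc = rocs, seed = config@seed)
}

#' Pooled cross-validation summary
#'
#' Mean and sd of each metric over all fold records, plus per-repetition
#' means.
#'
#' @param report a [CvReport-class].
#' @return numeric matrix (metrics x c(mean, sd)) with attribute
#'   `perRepetition` (data.frame of per-repetition means).
#' @export
cvSummary <- function(report) {
  fd <- report@folds
  mets <- c("auc", "accuracy", "sensitivity", "specificity")
  out <- t(vapply(mets, function(m)
    c(mean = mean(fd[[m]], na.rm = TRUE), sd = stats::sd(fd[[m]], na.rm = TRUE)),
    numeric(2)))
  perRep <- aggregate(fd[mets], by = list(repetition = fd$repetition),
                      FUN = mean, na.rm = TRUE)
  attr(out, "perRepetition") <- perRep
  out
}
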