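# Ensemble feature selection: ANOVA-F, random-forest importance and
# SVM-based recursive feature elimination, combined by average rank.
# Ranking deliberately uses the full sample (as in the original protocol,
# where importance ranking was computed on all 164 subjects); a
# leakage-safe per-fold mode is available through crossValidate().

# rank so that 1 = most important; ties by canonical column order
.rankDesc <- function(score) {
  ord <- order(-score, seq_along(score))
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

#' ANOVA F ranking of features
#'
#' Ranks features by the one-way (two-group) ANOVA F statistic: higher F,
#' more important. For two groups F equals the squared unpaired
#' equal-variance t statistic. A feature with zero between- and
#' within-group variance gets F = 0 (worst rank).
#'
#' @param se feature table (`SummarizedExperiment`).
#' @return integer vector of ranks (1 = most important), named by feature.
#' @export
anovaRank <- function(se) {
  x <- featureMatrix(se)
  g <- subjectLabels(se)
  stopifnot(all(table(g) >= 2))
  n1 <- sum(g == "IPD"); n2 <- sum(g == "HC")
  f <- vapply(seq_len(ncol(x)), function(k) {
    v <- x[, k]
    m1 <- mean(v[g == "IPD"]); m2 <- mean(v[g == "HC"])
    ssb <- n1 * (m1 - mean(v))^2 + n2 * (m2 - mean(v))^2
    ssw <- sum((v[g == "IPD"] - m1)^2) + sum((v[g == "HC"] - m2)^2)
    if (ssw == 0) {
      if (ssb == 0) { logNote("constant feature %s: F = 0", colnames(x)[k]); 0 }
      else Inf
    } else (ssb / 1) / (ssw / (n1 + n2 - 2))
  }, numeric(1))
  setNames(.rankDesc(f), colnames(x))
}

#' Random-forest importance ranking of features
#'
#' Ranks by the mean impurity-decrease (Gini) importance of a
#' 10-tree random forest, the forest size used in the original protocol;
#' remaining hyperparameters are the package defaults for classification
#' (unlimited depth, sqrt(p) candidate features per split). Fully seeded.
#'
#' @param se feature table.
#' @param nTrees number of trees (default 10).
#' @param seed integer seed.
#' @return integer ranks (1 = most important), named by feature.
#' @export
rfRank <- function(se, nTrees = 10L, seed = 1L) {
  x <- featureMatrix(se)
  g <- subjectLabels(se)
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = g, ntree = nTrees,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  if (all(imp == 0)) logNote("all RF importances zero: canonical order")
  setNames(.rankDesc(imp), colnames(x))
}

#' Recursive feature elimination with a linear SVM
#'
#' Standardizes the features, then repeatedly fits a linear SVM (C = 1)
#' and removes the feature with the smallest squared weight, one per
#' round, until one remains. The rank of a feature is the reverse of its
#' elimination order (the survivor of the last round has rank 1), and the
#' estimator's training accuracy at each retained-set size is recorded —
#' the accuracy-vs-feature-number curve used to choose how many features
#' to keep.
#'
#' @param se feature table.
#' @param cost linear-SVM penalty (default 1).
#' @return list with `ranks` (integer, 1 = eliminated last) and `curve`
#'   (data.frame nFeatures, accuracy; one row per elimination round,
#'   largest retained set first).
#' @export
rfeRank <- function(se, cost = 1) {
  x <- featureMatrix(se)
  g <- subjectLabels(se)
  p <- ncol(x)
  mu <- colMeans(x); sg <- apply(x, 2, stats::sd)
  sg[sg == 0] <- 1
  xs <- scale(x, center = mu, scale = sg)
  active <- seq_len(p)
  ranks <- integer(p)
  curve <- data.frame(nFeatures = integer(0), accuracy = numeric(0))
  for (round in seq_len(p)) {
    fit <- e1071::svm(xs[, active, drop = FALSE], g, kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, xs[, active, drop = FALSE])
    curve <- rbind(curve, data.frame(nFeatures = length(active),
                                     accuracy = mean(pred == g)))
    # primal weights from the dual representation
    w <- crossprod(fit$coefs, fit$SV)
    score <- colSums(w^2)
    drop_ <- active[which.min(score)]
    ranks[drop_] <- length(active)
    active <- setdiff(active, drop_)
    if (!length(active)) break
  }
  list(ranks = setNames(ranks, colnames(x)), curve = curve)
}

#' Ensemble feature selection by average rank
#'
#' Combines the three rankers (ANOVA F, random-forest importance, RFE)
#' by the arithmetic mean of their ranks and keeps the top `nSelect`
#' features. Average-rank ties break by the best single-method rank, then
#' canonical feature order.
#'
#' @param se feature table.
#' @param nSelect number of features to keep (default 40).
#' @param seed seed for the random-forest ranker.
#' @param rfeCost linear-SVM penalty of the RFE estimator.
#' @return list with `rankTable` (data.frame: feature, anova, rf, rfe,
#'   ensemble, selected), `selected` (character, in ensemble order),
#'   `reduced` (the feature table subset to the selected features, a
#'   subjects x nSelect matrix) and `curve` (the RFE accuracy curve).
#' @export
ensembleSelect <- function(se, nSelect = 40L, seed = 1L, rfeCost = 1) {
  p <- length(featureNames105())
  stopifnot(nSelect >= 1L, nSelect <= p)
  ra <- anovaRank(se)
  rf <- rfRank(se, seed = seed)
  rfe <- rfeRank(se, cost = rfeCost)
  avg <- (ra + rf + rfe$ranks) / 3
  best <- pmin(ra, rf, rfe$ranks)
  ord <- order(avg, best, seq_along(avg))
  sel <- names(avg)[ord][seq_len(nSelect)]
  rankTable <- data.frame(
    feature = names(avg), anova = unname(ra), rf = unname(rf),
    rfe = unname(rfe$ranks), ensemble = unname(avg),
    selected = names(avg) %in% sel,
    stringsAsFactors = FALSE)
  list(rankTable = rankTable, selected = sel,
       reduced = featureMatrix(se)[, sel, drop = FALSE],
       curve = rfe$curve)
}
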