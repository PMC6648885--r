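# Group-level statistics: Bonferroni-corrected unpaired t-tests,
# per-feature ROC AUC, Pearson correlation with the motor score, and the
# contingency arithmetic for the radiologist's swallow-tail readings.

#' Per-feature unpaired t-tests with Bonferroni correction
#'
#' Two-tailed unpaired t-test (classical equal-variance by default, the
#' reporting convention assumed here; set `welch = TRUE` for the unequal
#' variance form) of IPD vs HC for every feature, flagged significant at
#' the Bonferroni-adjusted threshold 0.05 / `familyN`.
#'
#' @param se feature table (`SummarizedExperiment`), or subjects x
#'   features matrix with `labels`.
#' @param familyN Bonferroni family size n (threshold 0.05/n).
#' @param labels required when `se` is a matrix.
#' @param welch use the Welch (unequal-variance) t-test.
#' @return data.frame: feature, meanIpd, sdIpd, meanHc, sdHc, t, p,
#'   significant, auc (per-feature AUC, reported as the >= 0.5 side) and
#'   aucDirection (+1 when higher values indicate IPD). The Bonferroni
#'   threshold is attached as attribute `threshold`.
#' @export
featureTtests <- function(se, familyN = 40L, labels = NULL, welch = FALSE) {
  if (is.matrix(se)) { x <- se }
  else { x <- featureMatrix(se); labels <- subjectLabels(se) }
  g <- as.character(labels)
  stopifnot(sum(g == "IPD") >= 2, sum(g == "HC") >= 2)
  thr <- 0.05 / familyN
  rows <- lapply(colnames(x), function(f) {
    a <- x[g == "IPD", f]; b <- x[g == "HC", f]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      logNote("feature %s: zero pooled variance", f)
      p <- if (mean(a) == mean(b)) 1 else 0
      tt <- list(statistic = c(t = if (p == 1) 0 else Inf), p.value = p)
    } else {
      tt <- t.test(a, b, var.equal = !welch)
    }
    av <- featureAuc(x[, f], g)
    data.frame(feature = f,
               meanIpd = mean(a), sdIpd = stats::sd(a),
               meanHc = mean(b), sdHc = stats::sd(b),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < thr,
               auc = av, aucDirection = attr(av, "direction"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Per-feature ROC AUC
#'
#' Rank-based (Mann-Whitney) AUC of a single feature for separating IPD
#' from HC, with half credit for ties. By convention the reported value
#' is the >= 0.5 orientation, `max(AUC, 1 - AUC)`, with the direction
#' returned as an attribute (+1: higher values indicate IPD); set
#' `orient = FALSE` for the raw IPD-positive AUC.
#'
#' @param values numeric feature values, one per subject.
#' @param labels class labels (HC/IPD), both classes present.
#' @param orient report the >= 0.5 side (default TRUE).
#' @return numeric AUC with attribute `direction`.
#' @export
featureAuc <- function(values, labels, orient = TRUE) {
  g <- as.character(labels)
  pos <- g == "IPD"
  if (!any(pos) || all(pos)) stop("AUC undefined: both classes required")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  dir <- 1
  if (orient && auc < 0.5) { auc <- 1 - auc; dir <- -1 }
  structure(auc, direction = dir)
}

#' Pearson correlation of a feature with the motor score
#'
#' Two-tailed Pearson linear correlation (p-value via the t transform on
#' n - 2 degrees of freedom), as used to relate the selected features to
#' the UPDRS-III motor score.
#'
#' @param values numeric feature values.
#' @param scores numeric motor scores (pairs with NA dropped).
#' @return list `r`, `p`, `n`.
#' @export
motorCorrelation <- function(values, scores) {
  ok <- is.finite(values) & is.finite(scores)
  x <- values[ok]; y <- scores[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Diagnostic metrics of the swallow-tail sign reading
#'
#' Pure contingency arithmetic on the radiologist's sign counts. With the
#' sign-present healthy control as the positive call (the orientation
#' used when reporting the visual reading): sensitivity = HC correctly
#' showing the sign / all HC; specificity = IPD lacking the sign / all
#' IPD; accuracy = all correct / total. Percentages.
#'
#' @param hcPresent,hcTotal sign-present count and class size for HC.
#' @param ipdPresent,ipdTotal sign-present count and class size for IPD.
#' @return list `accuracy`, `sensitivity`, `specificity`,
#'   `ipdPresentRate` (percent of IPD showing the sign), `table` (2x2
#'   counts).
#' @export
contingencyMetrics <- function(hcPresent = 52L, hcTotal = 77L,
                               ipdPresent = 8L, ipdTotal = 87L) {
  stopifnot(hcPresent >= 0, ipdPresent >= 0,
            hcPresent <= hcTotal, ipdPresent <= ipdTotal)
  if (hcTotal == 0 || ipdTotal == 0)
    stop("undefined metric: zero row total")
  tab <- matrix(c(hcPresent, hcTotal - hcPresent,
                  ipdPresent, ipdTotal - ipdPresent),
                nrow = 2, byrow = TRUE,
                dimnames = list(class = c("HC", "IPD"),
                                sign = c("present", "absent")))
  sens <- hcPresent / hcTotal
  spec <- (ipdTotal - ipdPresent) / ipdTotal
  acc <- (hcPresent + ipdTotal - ipdPresent) / (hcTotal + ipdTotal)
  list(accuracy = 100 * acc, sensitivity = 100 * sens,
       specificity = 100 * spec,
       ipdPresentRate = 100 * ipdPresent / ipdTotal,
       table = tab)
}

#' Group statistics of the selected features
#'
#' Convenience wrapper running [featureTtests()] on the selected columns
#' and [motorCorrelation()] of each against the IPD motor scores.
#'
#' @param se feature table with motor scores.
#' @param selected character vector of feature names (default: the five
#'   reference features).
#' @param familyN Bonferroni family size.
#' @return list `tests` (data.frame), `correlations` (data.frame feature,
#'   r, p, n over IPD subjects).
#' @export
groupStatistics <- function(se, selected = referenceEffectSizes()$feature,
                            familyN = 40L) {
  x <- featureMatrix(se)[, selected, drop = FALSE]
  tests <- featureTtests(x, familyN = familyN, labels = subjectLabels(se))
  sc <- motorScores(se)
  corr <- NULL
  if (!is.null(sc)) {
    ipd <- subjectLabels(se) == "IPD"
    corr <- do.call(rbind, lapply(selected, function(f) {
      mc <- motorCorrelation(x[ipd, f], sc[ipd])
      data.frame(feature = f, r = mc$r, p = mc$p, n = mc$n)
    }))
  }
  list(tests = tests, correlations = corr)
}
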