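## Predictive metrics: error rate, baseline error rate, relative error
## reduction, rank-based AUC, and step-interpolated AUPRC.

#' Misclassification error rate
#' @param yhat predicted labels.
#' @param y observed labels.
#' @return mean of I(yhat != y).
#' @export
errorRate <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  if (length(y) == 0) stop("empty label vector")
  mean(as.character(yhat) != as.character(y))
}

#' Baseline (majority-class) error rate
#'
#' \eqn{ER^{(0)} = 1 - \max_k f_k}: the error of always predicting the most
#' frequent class.
#'
#' @param y observed labels.
#' @return baseline error rate.
#' @export
baselineErrorRate <- function(y) {
  stopifnot(length(y) > 0)
  1 - max(table(y) / length(y))
}

#' Relative error-rate reduction
#'
#' \eqn{R^2_{ER} = (ER^{(0)} - ER) / ER^{(0)}}; can be negative when the
#' model does worse than the majority rule.
#'
#' @param er model error rate.
#' @param er0 baseline error rate (> 0).
#' @return the relative reduction.
#' @export
rer2 <- function(er, er0) {
  if (er0 <= 0) stop("baseline error rate must be positive")
  (er0 - er) / er0
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' ties counted one half; equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores scores for the positive class (higher = more positive).
#' @param y binary labels.
#' @param positive the positive level (default: second sorted level).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, y, positive = NULL) {
  y <- as.factor(y)
  if (is.null(positive)) positive <- sort(levels(droplevels(y)))[2]
  pos <- y == positive
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (right-continuous) interpolation: the PR curve is traversed at
#' each distinct score threshold and the area accumulated as
#' \eqn{\sum (R_i - R_{i-1}) P_i}; linear interpolation is avoided because
#' it is optimistically biased for precision.
#'
#' @param scores scores for the positive class.
#' @param y binary labels.
#' @param positive the positive level (default: second sorted level).
#' @return AUPRC in (0, 1].
#' @export
auprcScore <- function(scores, y, positive = NULL) {
  y <- as.factor(y)
  if (is.null(positive)) positive <- sort(levels(droplevels(y)))[2]
  pos <- as.numeric(y == positive)
  if (sum(pos) == 0) stop("no positive cases")
  o <- order(scores, decreasing = TRUE)
  pos <- pos[o]; s <- scores[o]
  ## collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos); fp <- cumsum(1 - pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(pos)
  dr <- diff(c(0, rec))
  sum(dr * prec)
}

#' Full metrics report for a binary prediction
#'
#' @param proba n x K matrix of class probabilities (columns named by
#'   class).
#' @param y observed labels.
#' @param positive positive class (default: second sorted level).
#' @param trainMajority optional label used to break argmax ties (the
#'   majority training class); default: overall majority of \code{y}.
#' @return list with er, er0, rer2, auc, auprc, class_frequencies, n,
#'   sensitivity, specificity, precision, recall (at the argmax rule).
#' @export
metricsReport <- function(proba, y, positive = NULL, trainMajority = NULL) {
  y <- as.factor(y)
  if (is.null(positive)) positive <- sort(levels(droplevels(y)))[2]
  yhat <- argmaxPredict(proba, trainMajority = trainMajority)
  er <- errorRate(yhat, y)
  er0 <- baselineErrorRate(y)
  scores <- proba[, positive]
  tp <- sum(yhat == positive & y == positive)
  fp <- sum(yhat == positive & y != positive)
  fn <- sum(yhat != positive & y == positive)
  tn <- sum(yhat != positive & y != positive)
  list(er = er, er0 = er0, rer2 = rer2(er, er0),
       auc = aucScore(scores, y, positive),
       auprc = auprcScore(scores, y, positive),
       class_frequencies = table(y) / length(y), n = length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

## Point prediction by argmax; ties broken toward the majority training
## class when supplied.
argmaxPredict <- function(proba, trainMajority = NULL) {
  cls <- colnames(proba)
  idx <- apply(proba, 1, function(p) {
    w <- which(p == max(p))
    if (length(w) > 1 && !is.null(trainMajority) && trainMajority %in% cls[w])
      w <- which(cls == trainMajority)
    w[1]
  })
  cls[idx]
}
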