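# Confusion-matrix accuracies, ROC points, trapezoid AUC and the Gini
# rescaling. The trapezoid rule over the empirical ROC is the package's own
# primitive (tested against an exhaustive pair-counting oracle).

#' Accuracies from a confusion matrix
#'
#' Overall accuracy is the trace over the total count; per-class accuracy is
#' the diagonal entry over its row (actual-class) sum.
#'
#' @param m square non-negative integer matrix, actual classes in rows,
#'   predicted in columns.
#' @return list with `overall` and named `per_class` fractions.
#' @examples
#' m <- rbind(c(234, 59, 2), c(74, 191, 0), c(2, 0, 31))
#' accuracyFromConfusion(m)$per_class[1]  # 0.7932
#' @export
accuracyFromConfusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9))
    stop("confusion matrix entries must be non-negative integers")
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix")
  rs <- rowSums(m)
  per <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  names(per) <- rownames(m) %||% paste0("class", seq_len(nrow(m)))
  list(overall = sum(diag(m)) / tot, per_class = per)
}

#' Empirical ROC points
#'
#' One (false-positive rate, true-positive rate) point per distinct score
#' threshold, plus the (0,0) and (1,1) anchors. Ties in scores are grouped.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels logical (or two-level) vector, `TRUE`/second level =
#'   positive.
#' @return data.frame with columns `fpr`, `tpr`, ordered by increasing fpr.
#' @export
rocCurve <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0) stop("both classes required for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  keep <- c(s[-length(s)] != s[-1], TRUE)   # last index of each tied block
  data.frame(fpr = c(0, fp[keep] / nNeg), tpr = c(0, tp[keep] / nPos))
}

#' Trapezoid area under the ROC curve
#'
#' @inheritParams rocCurve
#' @return AUC in `[0, 1]`.
#' @export
aucTrapezoid <- function(scores, labels) {
  roc <- rocCurve(scores, labels)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Gini coefficient from an AUC
#'
#' The linear rescaling `2 * AUC - 1` of the area under the ROC curve.
#'
#' @param auc area under the ROC curve.
#' @return Gini coefficient.
#' @examples
#' giniFromAuc(0.667)  # 0.334
#' @export
giniFromAuc <- function(auc) 2 * auc - 1
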