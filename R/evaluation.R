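# Evaluation: confusion-matrix metrics at a threshold, precision-recall
# curves with step-wise AUC, and per-class score histograms.

#' Recall, precision and accuracy at a confidence threshold
#'
#' The prediction rule is closed at the threshold: score >= t predicts
#' positive (so t = 0 always yields recall 1).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels binary labels (\code{"positive"}/\code{"negative"},
#'   logical, or 0/1); positives must be present.
#' @param threshold confidence threshold (default 0.5, the package-wide
#'   evaluation default).
#' @return One-row data.frame: \code{threshold}, \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{recall}, \code{precision},
#'   \code{accuracy}. Precision is \code{NaN} when nothing is predicted
#'   positive.
#' @export
metricsAtThreshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  pos <- .asPositive(labels)
  if (!any(pos))
    stop("no positive examples: recall is undefined", call. = FALSE)
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos)
  fn <- sum(!pred & pos)
  data.frame(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    recall = tp / (tp + fn),
    precision = if (tp + fp == 0) NaN else tp / (tp + fp),
    accuracy = (tp + tn) / length(scores)
  )
}

#' Precision-recall curve and area under it
#'
#' One curve point per distinct score, taken as thresholds in descending
#' order, so tied scores flip together. The AUC is the step-wise
#' (rectangular) integral of precision over recall — no interpolation,
#' which in PR space would be optimistic. Monotone transformations of the
#' scores leave the curve unchanged.
#'
#' @inheritParams metricsAtThreshold
#' @return A \linkS4class{PRCurve}.
#' @examples
#' pc <- prCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' prAuc(pc)  # 1: perfectly separated
#' @export
prCurve <- function(scores, labels) {
  pos <- .asPositive(labels)
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(pos)
  ord <- order(-scores)
  s <- scores[ord]
  p <- pos[ord]
  cumTp <- cumsum(p)
  cumN <- seq_along(s)
  # index of the last example included at each distinct threshold
  last <- which(!duplicated(s, fromLast = TRUE))
  recall <- cumTp[last] / nPos
  precision <- cumTp[last] / cumN[last]
  auc <- sum(diff(c(0, recall)) * precision)
  new("PRCurve",
      points = data.frame(threshold = thr, recall = recall,
                          precision = precision),
      auc = auc)
}

#' Per-class score histograms
#'
#' Normalized histograms (masses sum to 1 per class) of the scores of
#' positive and negative examples over \[0, 1\] — the data behind the
#' customary density plot of prediction scores by class.
#'
#' @inheritParams metricsAtThreshold
#' @param bins number of equal-width bins over \[0, 1\] (>= 2).
#' @return List with elements \code{positive} and \code{negative}, each a
#'   data.frame (\code{bin_lo}, \code{bin_hi}, \code{mass}) or \code{NULL}
#'   (flagged via the \code{"empty_class"} attribute) when a class is
#'   absent.
#' @export
scoreDensity <- function(scores, labels, bins = 20L) {
  stopifnot(bins >= 2)
  pos <- .asPositive(labels)
  breaks <- seq(0, 1, length.out = bins + 1L)
  oneClass <- function(x) {
    if (length(x) == 0) return(NULL)
    counts <- graphics::hist(x, breaks = breaks, plot = FALSE,
                             include.lowest = TRUE, right = TRUE)$counts
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               mass = counts / sum(counts))
  }
  out <- list(positive = oneClass(scores[pos]),
              negative = oneClass(scores[!pos]))
  attr(out, "empty_class") <- names(out)[vapply(out, is.null, logical(1))]
  out
}
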