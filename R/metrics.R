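# Confusion-matrix metric suite and ROC/AUC.

#' Confusion counts for binary labels (positive class = 1)
#'
#' @param truth,predicted Equal-length vectors over \{0, 1\}.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(
    TP = sum(truth == 1L & predicted == 1L),
    FP = sum(truth == 0L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FN = sum(truth == 1L & predicted == 0L)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, sensitivity (recall/TPR), specificity,
#' false-positive rate and F1. A metric whose denominator is zero is reported
#' as `NA` (undefined, not zero) and named in the `undefined` attribute.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector (`Acc`, `Pre`, `Sen`, `Spe`, `FPR`, `F1`),
#'   values in \[0, 1\].
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  if (n == 0) stop("no samples", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(
    Acc = ratio(TP + TN, n),
    Pre = ratio(TP, TP + FP),
    Sen = ratio(TP, TP + FN),
    Spe = ratio(TN, TN + FP),
    FPR = ratio(FP, FP + TN)
  )
  f1 <- if (is.na(out["Pre"]) || is.na(out["Sen"]) ||
            (out["Pre"] + out["Sen"]) == 0) NA_real_ else {
    2 * out["Pre"] * out["Sen"] / (out["Pre"] + out["Sen"])
  }
  out <- c(out, F1 = unname(f1))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the classification threshold over the distinct scores, accumulating
#' (FPR, TPR) points, and integrates by the trapezoid rule. Tied scores are
#' grouped into a single threshold step, which makes the trapezoid area equal
#' the concordance probability P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param truth Binary labels over \{0, 1\}; both classes must be present.
#' @param scores Numeric association scores (higher = more positive).
#' @return List with `auc`, and the curve as `fpr`, `tpr`, `thresholds`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores)) {
    stop("truth and scores must have equal length", call. = FALSE)
  }
  P <- sum(truth == 1L)
  N <- sum(truth == 0L)
  if (P == 0 || N == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(t == 1L, grp, sum)
  fp_steps <- tapply(t == 0L, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / P)
  fpr <- c(0, cumsum(fp_steps) / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = unname(auc), fpr = unname(fpr), tpr = unname(tpr),
       thresholds = c(Inf, unique(s)))
}
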