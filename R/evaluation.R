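# Binary-classification metrics: sensitivity, specificity, accuracy,
# precision, F1, Matthews correlation coefficient and ROC AUC. Undefined
# metrics (zero denominators) are reported as NA with an explicit flag,
# never silently as 0.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; total must be positive.
#' @return A `cpp_confusion` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(counts < 0) || sum(counts) == 0) {
    cpp_stop("counts must be non-negative with positive total", "config")
  }
  structure(as.list(counts), class = "cpp_confusion")
}

#' Confusion counts from hard predictions
#'
#' @param predicted,truth 0/1 vectors of equal length.
#' @return A `cpp_confusion` list.
#' @export
confusion_from_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    cpp_stop("`predicted` and `truth` lengths differ", "length_mismatch")
  }
  confusion_counts(
    tp = sum(predicted == 1L & truth == 1L),
    fp = sum(predicted == 1L & truth == 0L),
    tn = sum(predicted == 0L & truth == 0L),
    fn = sum(predicted == 0L & truth == 1L)
  )
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold metrics from confusion counts
#'
#' SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/total, PR = TP/(TP+FP),
#' F1 = 2*PR*SN/(PR+SN), MCC = (TP*TN - FP*FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any zero denominator yields `NA`
#' and the metric name is listed in the `undefined` attribute.
#'
#' @param c A `cpp_confusion` from [confusion_counts()].
#' @return A `cpp_metrics` list with entries SN, SP, ACC, PR, F1, MCC
#'   (AUC is `NA` here; see [auc()] / [metrics_from_scores()]).
#' @export
metrics_from_counts <- function(c) {
  tp <- c$TP; fp <- c$FP; tn <- c$TN; fn <- c$FN
  sn <- safe_ratio(tp, tp + fn)
  sp <- safe_ratio(tn, tn + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  pr <- safe_ratio(tp, tp + fp)
  f1 <- if (is.na(pr) || is.na(sn) || pr + sn == 0) NA_real_ else 2 * pr * sn / (pr + sn)
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else {
    (tp * tn - fp * fn) / sqrt(mcc_den)
  }
  out <- list(SN = sn, SP = sp, ACC = acc, PR = pr, F1 = f1, MCC = mcc,
              AUC = NA_real_)
  undefined <- names(out)[vapply(out, is.na, logical(1L))]
  structure(out, undefined = setdiff(undefined, "AUC"),
            class = "cpp_metrics")
}

#' @export
print.cpp_metrics <- function(x, ...) {
  vals <- vapply(unclass(x), function(v) {
    if (is.na(v)) "-" else sprintf("%.4f", v)
  }, character(1L))
  cat("<cpp_metrics>", paste(names(vals), vals, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, counting ties as one
#' half; equals U/(n1*n2) where U is the rank-sum statistic of the positive
#' scores.
#'
#' @param scores Numeric classifier scores.
#' @param labels 0/1 truth vector aligned to `scores`.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    cpp_stop("`scores` and `labels` lengths differ", "length_mismatch")
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n2 <- sum(labels == 0L)
  if (n1 == 0L || n2 == 0L) cpp_stop("both classes must be present", "single_class")
  r <- rank(scores)
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Full metric report from scores
#'
#' Hard labels are taken at `threshold`; AUC is computed from the raw
#' scores.
#'
#' @inheritParams auc
#' @param threshold Score cut-off for the hard label (default 0.5).
#' @return A `cpp_metrics` report including AUC.
#' @export
metrics_from_scores <- function(scores, labels, threshold = 0.5) {
  rep <- metrics_from_counts(
    confusion_from_labels(as.integer(scores >= threshold), labels)
  )
  rep$AUC <- auc(scores, labels)
  rep
}
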