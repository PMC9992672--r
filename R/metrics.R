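#' Classification metrics from confusion counts
#'
#' Closed-form battery from TP/FP/TN/FN with "late stage" conventionally the
#' positive class: accuracy, sensitivity and specificity in percent,
#' per-class F1 (`f1_positive` counts the positive class as hits,
#' `f1_negative` the complementary relabeling), and the Matthews correlation
#' coefficient. When any MCC denominator factor is zero the MCC is reported
#' as 0 by convention.
#'
#' @param counts named numeric vector or list with `TP`, `FP`, `TN`, `FN`
#'   (non-negative, not all zero).
#' @return list: `accuracy` (%), `f1_positive`, `f1_negative`, `mcc`,
#'   `sensitivity` (%), `specificity` (%).
#' @export
compute_metrics <- function(counts) {
  cn <- c("TP", "FP", "TN", "FN")
  if (!all(cn %in% names(counts))) {
    stop_config("counts must carry TP, FP, TN, FN")
  }
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop_config("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0) stop_config("counts are all zero")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  f1 <- function(tp, fp, fn) {
    d <- tp + 0.5 * (fp + fn)
    if (d == 0) 0 else tp / d
  }
  list(accuracy = (tp + tn) / total * 100,
       f1_positive = f1(tp, fp, fn),
       f1_negative = f1(tn, fn, fp),
       mcc = mcc,
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn) * 100,
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp) * 100)
}

#' Confusion counts from labels and predictions
#'
#' @param truth,predicted factors/characters of class labels.
#' @param positive the positive class; default `"late"`.
#' @return named vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "late") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  c(TP = sum(predicted == positive & truth == positive),
    FP = sum(predicted == positive & truth != positive),
    TN = sum(predicted != positive & truth != positive),
    FN = sum(predicted != positive & truth == positive))
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann--Whitney) estimator: the probability that a randomly drawn
#' positive sample outscores a randomly drawn negative one, ties counted one
#' half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores, larger meaning more positive-like.
#' @param labels class labels; both classes must be present.
#' @param positive the positive class; default `"late"`.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels, positive = "late") {
  pos <- as.character(labels) == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_config("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
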