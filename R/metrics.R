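# Binary classification metrics and rank-based ROC-AUC.

#' Confusion counts
#'
#' @param labels 0/1 vector of true labels.
#' @param predicted 0/1 vector of predicted labels, same length.
#' @return list with `tp`, `tn`, `fp`, `fn` (integers summing to the
#'   number of samples).
#' @export
confusion_counts <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("labels and predictions must be 0 or 1")
  }
  list(tp = sum(labels == 1 & predicted == 1),
       tn = sum(labels == 0 & predicted == 0),
       fp = sum(labels == 0 & predicted == 1),
       fn = sum(labels == 1 & predicted == 0))
}

#' Threshold classification metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity, F1 and the
#' Matthews correlation coefficient, computed from confusion counts with
#' the standard formulas. Any metric whose denominator is zero is
#' defined as 0; this convention makes the degenerate all-negative
#' predictor report F1 = 0 and recall = 0 rather than NaN.
#'
#' @param counts list with `tp`, `tn`, `fp`, `fn` (from
#'   [confusion_counts()]).
#' @return list of metrics plus `n`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  stopifnot(n > 0)
  safe_div <- function(num, den) if (den > 0) num / den else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       specificity = specificity, f1 = f1, mcc = mcc, n = n)
}

#' Rank-based ROC-AUC
#'
#' The probability that a randomly chosen positive receives a higher
#' score than a randomly chosen negative, with ties counted half
#' (Mann-Whitney formulation, equivalent to the trapezoidal area under
#' the ROC curve). Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("ROC-AUC undefined with a single class")
  r <- rank(scores)  # average ranks give half credit for ties
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Full metrics report
#'
#' @param labels 0/1 true labels.
#' @param scores predicted probabilities (or any monotone score).
#' @param threshold probability cutoff for the thresholded metrics
#'   (predicted active iff score > threshold; default 0.5).
#' @return a `metrics_report` list: accuracy, roc_auc, f1, mcc, recall,
#'   precision, specificity, n.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  m <- classification_metrics(confusion_counts(labels, pred))
  auc <- if (length(unique(labels)) == 2L) roc_auc(labels, scores) else NA_real_
  structure(list(accuracy = m$accuracy, roc_auc = auc, f1 = m$f1,
                 mcc = m$mcc, recall = m$recall, precision = m$precision,
                 specificity = m$specificity, n = m$n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, "\n")
  for (k in c("accuracy", "roc_auc", "f1", "mcc", "recall", "precision",
              "specificity")) {
    cat(sprintf("  %-12s %.4f\n", k, x[[k]]))
  }
  invisible(x)
}

#' Write a metrics report
#'
#' Emits the report as JSON and, optionally, a one-line TSV in the
#' column order accuracy, ROC-AUC, F1, MCC, recall, precision,
#' specificity.
#'
#' @param report a `metrics_report`.
#' @param json_path output JSON path (NULL to skip).
#' @param tsv_path output TSV path (NULL to skip).
#' @return the report, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    cols <- c("accuracy", "roc_auc", "f1", "mcc", "recall", "precision",
              "specificity")
    df <- as.data.frame(report[cols])
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(report)
}
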