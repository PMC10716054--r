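#' Confusion counts from labels and class calls
#'
#' @param truth 0/1 (or logical) true labels; 1 = positive.
#' @param predicted 0/1 (or logical) predicted labels.
#' @return List of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  structure(list(TP = sum(truth == 1L & predicted == 1L),
                 TN = sum(truth == 0L & predicted == 0L),
                 FP = sum(truth == 0L & predicted == 1L),
                 FN = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' Binary classification metrics
#'
#' Computes sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, accuracy
#' `Acc = (TP + TN) / (TP + TN + FP + FN)` and the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never as 0. When `scores` and `labels` are supplied, AUROC is added,
#' computed from score rankings (Mann-Whitney statistic; ties get mid-rank
#' credit).
#'
#' @param counts A [confusion_counts()] object or a named list/vector with
#'   `TP`, `TN`, `FP`, `FN`.
#' @param scores Optional numeric scores for AUROC.
#' @param labels Optional 0/1 labels matching `scores`.
#' @return Named list with `Sn`, `Sp`, `Acc`, `MCC` (and `AUROC`).
#' @export
binary_metrics <- function(counts, scores = NULL, labels = NULL) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- list(
    Sn = safe_div(tp, tp + fn),
    Sp = safe_div(tn, tn + fp),
    Acc = (tp + tn) / (tp + tn + fp + fn),
    MCC = if (mcc_den == 0) NA_real_ else
      (tp * tn - fp * fn) / sqrt(mcc_den)
  )
  if (!is.null(scores)) {
    if (is.null(labels)) stop("labels required with scores", call. = FALSE)
    out$AUROC <- auroc(scores, labels)
  }
  out
}

#' Area under the ROC curve from score rankings
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, ties counted half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) labels.
#' @return AUROC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation between predicted and observed values
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2,
#'   both non-constant).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 2L) {
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(predicted, observed)
}
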