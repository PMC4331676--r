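#' Confusion-matrix metrics
#'
#' Closed-form sensitivity, specificity, accuracy and Matthews correlation
#' coefficient from confusion counts:
#' * `SN = TP / (TP + FN)`
#' * `SP = TN / (TN + FP)`
#' * `ACC = (TP + TN) / (TP + FP + TN + FN)`
#' * `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`
#'
#' A metric whose denominator is 0 is reported as 0 for MCC (the standard
#' convention, which keeps random predictions centred at 0 even on
#' degenerate draws) and as `NaN` for SN/SP.
#'
#' @param TP,FP,TN,FN Non-negative confusion counts; alternatively pass a
#'   single list/vector with those names as `TP`.
#' @return A one-row tibble with columns `TP`, `FP`, `TN`, `FN`, `sn`, `sp`,
#'   `acc`, `mcc`.
#' @examples
#' compute_metrics(TP = 3, FP = 1, TN = 2, FN = 2)
#' @export
compute_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.list(TP) || (length(TP) == 4L && !is.null(names(TP)))) {
    counts <- TP
    TP <- counts[["TP"]]; FP <- counts[["FP"]]
    TN <- counts[["TN"]]; FN <- counts[["FN"]]
  }
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n == 0) abort("All confusion counts are zero; nothing was evaluated.")
  mcc_den2 <- (TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
  mcc <- if (mcc_den2 == 0) 0 else (TP * TN - FP * FN) / sqrt(mcc_den2)
  tibble::tibble(
    TP = TP, FP = FP, TN = TN, FN = FN,
    sn = TP / (TP + FN),
    sp = TN / (TN + FP),
    acc = (TP + TN) / n,
    mcc = mcc)
}

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,predicted Label vectors over \{+1, -1\} of equal length.
#' @return A named list with `TP`, `FP`, `TN`, `FN`, suitable for
#'   [compute_metrics()].
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(TP = sum(truth == 1 & predicted == 1),
       FP = sum(truth == -1 & predicted == 1),
       TN = sum(truth == -1 & predicted == -1),
       FN = sum(truth == 1 & predicted == -1))
}

#' ROC curve and AUC from decision values
#'
#' Builds the ROC curve by sweeping the decision threshold over the distinct
#' decision values (sensitivity versus 1 - specificity), and computes the
#' area under it as the Mann–Whitney statistic with ties credited 0.5 —
#' which coincides with the trapezoidal area under the swept curve.
#'
#' @param decision_values Numeric scores, larger meaning more positive.
#' @param labels True labels over \{+1, -1\}; both classes must be present.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`, from (0,0)
#'   to (1,1)) and `auc`.
#' @examples
#' roc_auc(c(.9, .8, .3, .2), c(1, -1, 1, -1))$auc  # 0.75
#' @export
roc_auc <- function(decision_values, labels) {
  stopifnot(length(decision_values) == length(labels),
            all(is.finite(decision_values)))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) abort("Labels must lie in {+1, -1}.")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs both classes among the labels.")
  }
  thresholds <- sort(unique(decision_values), decreasing = TRUE)
  pts <- vapply(thresholds, function(t) {
    pred_pos <- decision_values >= t
    c(fpr = sum(pred_pos & labels == -1) / n_neg,
      tpr = sum(pred_pos & labels == 1) / n_pos)
  }, numeric(2))
  roc <- tibble::tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, pts["fpr", ]),
    tpr = c(0, pts["tpr", ]))
  if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1) {
    roc <- dplyr::bind_rows(roc, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  # midranks credit ties 0.5 per tied positive-negative pair
  r <- rank(decision_values, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(roc = roc, auc = auc)
}
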