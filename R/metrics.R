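# Evaluation metrics for the binary diagnostic task. Positive class is 1
# (pneumonia). Undefined metrics (empty denominator, single-class stratum)
# are reported as NA, never silently coerced to 0.

METRIC_NAMES <- c("balanced_accuracy", "sensitivity", "specificity",
                  "precision", "f1", "roc_auc", "brier")
# Brier is a loss (lower is better); everything else is a score.
LOSS_METRICS <- "brier"

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred equal-length 0/1 vectors; class 1 (pneumonia) is the
#'   positive class.
#' @return list of class `"daplex_confusion"` with integer `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_daplex("y_true and y_pred lengths differ")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop_daplex("labels must be 0/1")
  }
  structure(
    list(TP = sum(y_true == 1 & y_pred == 1),
         TN = sum(y_true == 0 & y_pred == 0),
         FP = sum(y_true == 0 & y_pred == 1),
         FN = sum(y_true == 1 & y_pred == 0)),
    class = "daplex_confusion"
  )
}

#' Threshold-based classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), balanced accuracy = (sensitivity + specificity)/2, F1 =
#' 2 * precision * sensitivity / (precision + sensitivity). A metric whose
#' denominator is zero is returned as `NA` (flagged undefined).
#'
#' @param cc a `"daplex_confusion"` from [confusion_counts()].
#' @return named numeric vector `sensitivity`, `specificity`, `precision`,
#'   `balanced_accuracy`, `f1`.
#' @export
threshold_metrics <- function(cc) {
  stopifnot(inherits(cc, "daplex_confusion"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(cc$TP, cc$TP + cc$FN)
  spec <- safe_div(cc$TN, cc$TN + cc$FP)
  prec <- safe_div(cc$TP, cc$TP + cc$FP)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  c(sensitivity = sens, specificity = spec, precision = prec,
    balanced_accuracy = ba, f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 * P(tie)` via midranks; equivalent to the
#' trapezoidal area under the empirical ROC curve, with deterministic tie
#' handling, and invariant to strictly monotone transforms of the scores.
#'
#' @param y_true 0/1 labels.
#' @param scores real-valued scores, higher = more pneumonia-like.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop_daplex("length mismatch")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted positive-class probabilities and
#' observed 0/1 outcomes; a proper scoring rule measuring calibration (lower
#' is better).
#'
#' @param y_true 0/1 labels.
#' @param probs predicted probabilities in `[0, 1]`.
#' @return the Brier score.
#' @export
brier_score <- function(y_true, probs) {
  if (length(y_true) != length(probs)) stop_daplex("length mismatch")
  if (any(probs < 0 | probs > 1)) stop_daplex("probabilities must lie in [0, 1]")
  mean((probs - y_true)^2)
}

#' All seven evaluation metrics from probabilities
#'
#' Convenience wrapper computing sensitivity, specificity, precision,
#' balanced accuracy, F1, ROC-AUC and Brier score from positive-class
#' probabilities, thresholding at `threshold` for the label-based metrics.
#'
#' @param y_true 0/1 labels.
#' @param probs positive-class probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector over [`METRIC_NAMES`].
#' @export
binary_metrics <- function(y_true, probs, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  tm <- threshold_metrics(confusion_counts(y_true, pred))
  out <- c(tm, roc_auc = roc_auc(y_true, probs),
           brier = brier_score(y_true, probs))
  out[METRIC_NAMES]
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' @param per_fold list (length >= 2) of equally named metric vectors, one
#'   per fold.
#' @return data.frame `metric`, `mean`, `sd` (sample SD, denominator n-1),
#'   `n_folds`.
#' @export
aggregate_cv <- function(per_fold) {
  if (length(per_fold) < 2) stop_daplex("need at least 2 folds")
  nms <- names(per_fold[[1]])
  for (f in per_fold) {
    if (!identical(sort(names(f)), sort(nms))) {
      stop_daplex("inconsistent metric sets across folds")
    }
  }
  m <- do.call(rbind, lapply(per_fold, function(f) f[nms]))
  data.frame(metric = nms,
             mean = apply(m, 2, mean),
             sd = apply(m, 2, stats::sd),
             n_folds = length(per_fold),
             row.names = NULL, stringsAsFactors = FALSE)
}
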