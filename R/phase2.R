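# Phase II: stability-gap-based ensemble pruning. A learner whose mean
# training-fold score exceeds its mean validation-fold score by more than a
# threshold on the anchor metric (balanced accuracy by default) is flagged
# as overfitting and removed from the ensemble.

#' Per-metric train-validation stability gaps
#'
#' For score-type metrics (higher is better) the gap is
#' `mean(train) - mean(validation)`; for loss-type metrics (Brier) the sign
#' is inverted (`mean(validation) - mean(train)`), so a positive gap always
#' signals worse generalization.
#'
#' @param fold_scores long data.frame with columns `fold`, `side`
#'   (`"train"`/`"validation"`), `metric`, `value` — as stored on a
#'   `"daplex_tuned"` object.
#' @return named numeric vector of gaps, one per metric.
#' @export
stability_gaps <- function(fold_scores) {
  need <- c("fold", "side", "metric", "value")
  if (!all(need %in% names(fold_scores))) stop_daplex("malformed fold scores")
  metrics <- unique(fold_scores$metric)
  vapply(metrics, function(m) {
    tr <- fold_scores$value[fold_scores$metric == m & fold_scores$side == "train"]
    va <- fold_scores$value[fold_scores$metric == m & fold_scores$side == "validation"]
    if (!length(tr) || !length(va)) stop_daplex("missing %s scores", m)
    gap <- mean(tr) - mean(va)
    if (m %in% LOSS_METRICS) -gap else gap
  }, numeric(1))
}

#' Apply the stability-gap pruning rule to a gap table
#'
#' A model is pruned iff its anchor-metric gap strictly exceeds the
#' threshold; a gap exactly at the threshold is retained.
#'
#' @param gaps data.frame with a `model` column and one column per metric
#'   gap (at least the anchor metric).
#' @param threshold positive exclusion threshold (default 0.05).
#' @param anchor metric anchoring the decision (default
#'   `"balanced_accuracy"`).
#' @return list of class `"daplex_prune"`: `report` (the gap table with a
#'   `status` column, `"retained"`/`"pruned"`), `retained` (model names, in
#'   input order), `threshold`, `anchor`. Errors if no model survives.
#' @export
apply_pruning_rule <- function(gaps, threshold = 0.05,
                               anchor = "balanced_accuracy") {
  if (threshold <= 0) stop_daplex("threshold must be > 0")
  if (!anchor %in% names(gaps)) {
    stop_daplex("gap table lacks anchor metric column '%s'", anchor)
  }
  status <- ifelse(gaps[[anchor]] > threshold, "pruned", "retained")
  report <- gaps
  report$status <- status
  retained <- report$model[status == "retained"]
  if (!length(retained)) {
    stop_daplex(paste("all models pruned at threshold %.3g on '%s';",
                      "review the threshold or the learner pool"),
                threshold, anchor)
  }
  structure(list(report = report, retained = retained,
                 threshold = threshold, anchor = anchor),
            class = "daplex_prune")
}

#' Prune a tuned pool by generalization stability
#'
#' Computes all-metric stability gaps for every tuned learner and applies
#' the anchor-metric rule of [apply_pruning_rule()].
#'
#' @param tuned named list of `"daplex_tuned"` objects.
#' @inheritParams apply_pruning_rule
#' @return a `"daplex_prune"` object whose `report` has one row per model
#'   and one column per metric gap.
#' @export
prune_learners <- function(tuned, threshold = 0.05,
                           anchor = "balanced_accuracy") {
  gaps <- do.call(rbind, lapply(tuned, function(tm) {
    g <- stability_gaps(tm$fold_scores)
    cbind(data.frame(model = tm$name, stringsAsFactors = FALSE),
          as.data.frame(as.list(g)))
  }))
  rownames(gaps) <- NULL
  apply_pruning_rule(gaps, threshold = threshold, anchor = anchor)
}
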