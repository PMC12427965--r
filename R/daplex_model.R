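# End-to-end model: Phase I tuning, Phase II pruning, Phase III fusion,
# wrapped in one fitted object with a predict method.

#' Fit the full three-phase ensemble on a training cohort
#'
#' Runs the complete framework on training rows: fits the leakage-free
#' transformation, tunes every pool learner by cross-validated grid search
#' optimizing balanced accuracy (Phase I), prunes learners whose
#' anchor-metric stability gap exceeds the threshold (Phase II), then
#' quantifies complementarity (Friedman test on validation-fold balanced
#' accuracies, pairwise JSD of OOF probabilities), derives the Borda
#' consensus of grouped permutation importances, assembles the hybrid
#' meta-input and tunes the MLP meta-learner on the same folds (Phase III).
#'
#' @param train training cohort data.frame (with `diagnosis`).
#' @param pool named list of [base_learner_spec()] (default [default_pool()]).
#' @param k_folds cross-validation folds (default 5).
#' @param prune_threshold stability-gap exclusion threshold (default 0.05).
#' @param anchor pruning anchor metric (default `"balanced_accuracy"`).
#' @param k_consensus number of consensus features fused into the meta-input
#'   (default 5).
#' @param n_repeats permutation-importance repeats per variable per fold
#'   (default 10).
#' @param meta_spec meta-learner spec (default [default_meta_spec()]).
#' @param seed single seed driving folds and every learner fit.
#' @return object of class `"daplex_model"` with components: `transform`,
#'   `tuned` (all pool learners, each refit on the full training set),
#'   `pool_report`, `pruning` (`"daplex_prune"`), `retained`,
#'   `complementarity` (`friedman`, `jsd`), `importance` (per retained
#'   model), `consensus` (`"daplex_borda"`), `meta` (standardization
#'   parameters, representative columns, tuned MLP), `threshold` (decision
#'   threshold, 0.5), `folds`, `seed`.
#' @export
fit_daplex <- function(train, pool = default_pool(), k_folds = 5L,
                       prune_threshold = 0.05, anchor = "balanced_accuracy",
                       k_consensus = 5L, n_repeats = 10L,
                       meta_spec = default_meta_spec(), seed = 1L) {
  transform <- fit_transform_spec(train)
  feats <- apply_transform(transform, train)
  x <- feats$x
  y <- feats$y
  if (is.null(y)) stop_daplex("training table lacks a 'diagnosis' column")

  folds <- make_cv_folds(y, k = k_folds, seed = child_seed(seed, 11L))
  tuned <- tune_pool(pool, x, y, folds, seed = child_seed(seed, 23L))
  pool_report <- collect_pool_report(tuned)

  pruning <- prune_learners(tuned, threshold = prune_threshold, anchor = anchor)
  retained <- tuned[pruning$retained]

  oof <- oof_probabilities(retained, x, y, folds)
  ba_matrix <- vapply(retained, function(tm) {
    fs <- tm$fold_scores
    sel <- fs$side == "validation" & fs$metric == "balanced_accuracy"
    fs$value[sel][order(fs$fold[sel])]
  }, numeric(k_folds))
  friedman <- if (length(retained) >= 2) friedman_rank_test(ba_matrix) else NULL

  importance <- pool_permutation_importance(oof, x, y, feats$feature_group,
                                            n_repeats = n_repeats,
                                            seed = child_seed(seed, 41L))
  consensus <- borda_aggregate(importance, k = k_consensus)
  meta_input <- build_meta_input(oof$prob, x, y, feats$feature_group, consensus)
  meta_tuned <- train_meta_learner(meta_input, y, folds, spec = meta_spec,
                                   seed = child_seed(seed, 59L))

  structure(
    list(transform = transform, tuned = tuned, pool_report = pool_report,
         pruning = pruning, retained = names(retained),
         complementarity = list(friedman = friedman, jsd = jsd_matrix(oof$prob)),
         importance = importance, consensus = consensus,
         meta = list(center = meta_input$center, scale = meta_input$scale,
                     rep_cols = meta_input$rep_cols, tuned = meta_tuned),
         oof_prob = oof$prob, threshold = 0.5,
         folds = folds, seed = as.integer(seed)),
    class = "daplex_model"
  )
}

# Assemble the meta-feature matrix for new data: base probabilities from the
# full-training-refit retained learners plus the stored representative
# consensus columns, standardized with the stored parameters.
meta_features <- function(object, x) {
  base_prob <- vapply(object$retained, function(nm) {
    predict_prob(object$tuned[[nm]]$fit, x)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) base_prob <- matrix(base_prob, nrow = 1,
                                         dimnames = list(NULL, object$retained))
  raw <- cbind(base_prob, x[, object$meta$rep_cols, drop = FALSE])
  colnames(raw) <- names(object$meta$center)
  sweep(sweep(raw, 2, object$meta$center), 2, object$meta$scale, "/")
}

#' Predict diagnoses for new patients
#'
#' Applies the stored transformation, obtains base probabilities from the
#' retained learners (refit on the full training set, as in standard
#' stacking), assembles and standardizes the meta-row and returns the MLP
#' meta-learner's probability, thresholded at the model's decision threshold.
#'
#' @param object a `"daplex_model"`.
#' @param newdata cohort data.frame with all source variables.
#' @param ... unused.
#' @return data.frame: `probability` (positive class = pneumonia), `label`
#'   (0/1).
#' @export
predict.daplex_model <- function(object, newdata, ...) {
  feats <- apply_transform(object$transform, newdata)
  mx <- meta_features(object, feats$x)
  p <- predict_prob(object$meta$tuned$fit, mx)
  data.frame(probability = p,
             label = as.integer(p >= object$threshold))
}

#' @export
print.daplex_model <- function(x, ...) {
  cat("Three-phase diagnostic ensemble\n")
  cat("  pool:     ", paste(names(x$tuned), collapse = ", "), "\n")
  cat("  retained: ", paste(x$retained, collapse = ", "),
      sprintf(" (gap threshold %.3g on %s)\n", x$pruning$threshold, x$pruning$anchor))
  cat("  consensus features:", paste(x$consensus$top_k, collapse = ", "), "\n")
  mlp <- x$meta$tuned
  gaps <- stability_gaps(mlp$fold_scores)
  cat(sprintf("  meta-learner: MLP (size %s, decay %g), CV balanced accuracy %.4f, gap %.4f\n",
              mlp$best_params$size, mlp$best_params$decay,
              mean(mlp$fold_scores$value[mlp$fold_scores$side == "validation" &
                                         mlp$fold_scores$metric == "balanced_accuracy"]),
              gaps[["balanced_accuracy"]]))
  invisible(x)
}
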