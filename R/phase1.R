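# Phase I: diversity-aware base-learner deployment. Each learner in the
# pool is tuned by a k-fold cross-validated grid search that optimizes mean
# validation balanced accuracy, recording all seven metrics on both the
# training folds and the validation fold at every configuration. One fold
# partition is shared by every learner (and later by the meta-learner), a
# prerequisite for the Friedman comparison and the OOF stacking alignment.

#' Stratified cross-validation fold assignment
#'
#' @param y 0/1 label vector.
#' @param k number of folds (default 5); each class must have at least `k`
#'   members.
#' @param seed integer seed; the same seed always yields the same folds.
#' @return integer vector of fold ids in `1..k`, one per observation. Fold
#'   sizes differ by at most 1 and each fold's class mix matches the global
#'   mix to within one patient per class.
#' @export
make_cv_folds <- function(y, k = 5L, seed = 1L) {
  if (k < 2) stop_daplex("k must be >= 2")
  counts <- table(y)
  if (any(counts < k)) stop_daplex("each class needs at least k members")
  folds <- integer(length(y))
  with_seed(seed, {
    # offset the fold cycle between classes so total fold sizes stay within 1
    assigned <- 0L
    for (cls in names(counts)) {
      idx <- sample(which(y == as.numeric(cls)))
      folds[idx] <- ((seq_along(idx) - 1L + assigned) %% k) + 1L
      assigned <- assigned + length(idx)
    }
  })
  folds
}

metric_row <- function(model, config_id, fold, side, metrics) {
  data.frame(model = model, config_id = config_id, fold = fold, side = side,
             metric = names(metrics), value = unname(metrics),
             stringsAsFactors = FALSE)
}

grid_configs <- function(grid) {
  g <- do.call(expand.grid, c(grid, list(stringsAsFactors = FALSE,
                                         KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Cross-validated grid search for one base learner
#'
#' Enumerates the learner's hyperparameter grid in deterministic order; for
#' every configuration trains on k-1 folds and validates on the held-out
#' fold, k times, recording all seven metrics on both the training folds and
#' the validation fold. The configuration maximizing mean validation
#' balanced accuracy is selected (ties resolve to the earliest
#' configuration) and refit on the full training set. A configuration whose
#' fit fails on any fold is excluded and reported.
#'
#' @param spec a [base_learner_spec()].
#' @param x numeric feature matrix (training set).
#' @param y 0/1 labels.
#' @param folds fold ids from [make_cv_folds()] (shared across learners).
#' @param seed integer seed driving the learner's own randomness.
#' @return object of class `"daplex_tuned"`: `name`, `best_params`, `fit`
#'   (refit on all rows), `fold_scores` (long data.frame for the selected
#'   configuration: fold x side x metric), `grid_summary` (per configuration:
#'   parameters, mean validation BA, status), `folds`, `seed`.
#' @export
run_grid_search <- function(spec, x, y, folds, seed = 1L) {
  stopifnot(inherits(spec, "daplex_learner_spec"))
  configs <- grid_configs(spec$grid)
  if (!length(configs)) stop_daplex("empty hyperparameter grid for %s", spec$name)
  k <- max(folds)
  results <- vector("list", length(configs))
  mean_val_ba <- rep(NA_real_, length(configs))
  status <- rep("ok", length(configs))
  for (ci in seq_along(configs)) {
    params <- configs[[ci]]
    rows <- list()
    failed <- FALSE
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- tryCatch(
        fit_base_learner(spec$name, x[tr, , drop = FALSE], y[tr], params,
                         seed = child_seed(seed, 97L * ci + f)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failed <- TRUE
        break
      }
      p_tr <- predict_prob(fit, x[tr, , drop = FALSE])
      p_va <- predict_prob(fit, x[!tr, , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        rbind(metric_row(spec$name, ci, f, "train", binary_metrics(y[tr], p_tr)),
              metric_row(spec$name, ci, f, "validation", binary_metrics(y[!tr], p_va)))
    }
    if (failed) {
      status[ci] <- "failed"
      next
    }
    fs <- do.call(rbind, rows)
    results[[ci]] <- fs
    ba <- fs$value[fs$side == "validation" & fs$metric == "balanced_accuracy"]
    mean_val_ba[ci] <- mean(ba)
  }
  if (all(status == "failed")) {
    stop_daplex("all grid configurations failed for %s", spec$name)
  }
  best <- which(mean_val_ba == max(mean_val_ba, na.rm = TRUE))[1]
  grid_summary <- cbind(
    do.call(rbind, lapply(configs, function(p) as.data.frame(p, stringsAsFactors = FALSE))),
    data.frame(mean_val_balanced_accuracy = mean_val_ba, status = status,
               selected = seq_along(configs) == best, stringsAsFactors = FALSE))
  full_fit <- fit_base_learner(spec$name, x, y, configs[[best]],
                               seed = child_seed(seed, 10007L))
  structure(
    list(name = spec$name, best_params = configs[[best]], fit = full_fit,
         fold_scores = results[[best]], grid_summary = grid_summary,
         folds = folds, seed = as.integer(seed)),
    class = "daplex_tuned"
  )
}

#' Tune every learner in a pool on a shared fold partition
#'
#' @param pool named list of [base_learner_spec()] (default [default_pool()]).
#' @param x,y training feature matrix and 0/1 labels.
#' @param folds shared fold assignment from [make_cv_folds()].
#' @param seed integer seed.
#' @return named list of `"daplex_tuned"` objects.
#' @export
tune_pool <- function(pool, x, y, folds, seed = 1L) {
  out <- lapply(seq_along(pool), function(i) {
    run_grid_search(pool[[i]], x, y, folds, seed = child_seed(seed, 131L * i))
  })
  stats::setNames(out, vapply(out, function(t) t$name, character(1)))
}

#' Cross-validation performance report for a tuned pool
#'
#' One row per model with mean +/- sample SD over validation folds for every
#' metric, at each model's selected configuration.
#'
#' @param tuned list of `"daplex_tuned"` objects.
#' @return data.frame: `model`, then `<metric>_mean` / `<metric>_sd` columns,
#'   and `n_folds`.
#' @export
collect_pool_report <- function(tuned) {
  if (!length(tuned)) stop_daplex("no tuned models")
  rows <- lapply(tuned, function(tm) {
    fs <- tm$fold_scores
    val <- fs[fs$side == "validation", ]
    per_fold <- lapply(split(val, val$fold), function(d) {
      stats::setNames(d$value, d$metric)
    })
    agg <- aggregate_cv(per_fold)
    row <- data.frame(model = tm$name, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(agg))) {
      row[[paste0(agg$metric[i], "_mean")]] <- agg$mean[i]
      row[[paste0(agg$metric[i], "_sd")]] <- agg$sd[i]
    }
    row$n_folds <- agg$n_folds[1]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
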