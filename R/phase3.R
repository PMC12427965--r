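# Phase III: complementarity-driven knowledge fusion. The retained
# learners' diversity is quantified (Friedman rank test over CV folds,
# pairwise Jensen-Shannon divergence of probability outputs); grouped
# permutation importance is computed per learner on held-out validation
# folds and aggregated across learners by rank-sum Borda count; the
# out-of-fold probabilities plus the top-k consensus features form the
# hybrid meta-input for the MLP meta-learner.

#' Friedman rank test across matched blocks
#'
#' Nonparametric test for differences among models (columns) across matched
#' cross-validation folds (rows), using within-row midranks and the
#' tie-corrected chi-square approximation with `models - 1` degrees of
#' freedom. A fully tied matrix yields statistic 0, p = 1.
#'
#' @param score_matrix numeric matrix, folds x models.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
friedman_rank_test <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop_daplex("need >= 2 folds and >= 2 models")
  r <- t(apply(m, 1, rank, ties.method = "average"))
  rj <- colSums(r)
  # tie correction: sum over rows of (t^3 - t) over tie groups
  ties <- sum(apply(m, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0) {
    return(list(statistic = 0, df = k - 1L, p_value = 1))
  }
  stat <- 12 * sum((rj - n * (k + 1) / 2)^2) / denom
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 JSD: `0.5 * KL(p || m) + 0.5 * KL(q || m)` with `m = (p + q) / 2`
#' and the convention `0 * log(0) = 0`; bounded in `[0, 1]`.
#'
#' @param p,q non-negative vectors, each summing to 1 (tolerance 1e-9).
#' @return the divergence.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop_daplex("distributions differ in length")
  if (any(p < 0) || any(q < 0) || abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop_daplex("p and q must be probability distributions summing to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# mean per-patient binary JSD between two positive-class probability vectors,
# via JSD = H(m) - (H(p) + H(q)) / 2 with binary entropies in bits
binary_jsd_mean <- function(pa, pb) {
  h <- function(p) {
    out <- numeric(length(p))
    i <- p > 0 & p < 1
    out[i] <- -p[i] * log2(p[i]) - (1 - p[i]) * log2(1 - p[i])
    out
  }
  pm <- (pa + pb) / 2
  mean(h(pm) - (h(pa) + h(pb)) / 2)
}

#' Pairwise Jensen-Shannon divergence matrix of model outputs
#'
#' Entry (a, b) is the mean over patients of the base-2 JSD between the two
#' models' per-patient binary outcome distributions `(p, 1 - p)`. Symmetric,
#' zero diagonal, entries in `[0, 1]`.
#'
#' @param prob_matrix patients x models matrix of positive-class
#'   probabilities (all models scored on the same patients).
#' @return models x models matrix.
#' @export
jsd_matrix <- function(prob_matrix) {
  p <- as.matrix(prob_matrix)
  if (any(p < 0 | p > 1)) stop_daplex("probabilities must lie in [0, 1]")
  k <- ncol(p)
  out <- matrix(0, k, k, dimnames = list(colnames(p), colnames(p)))
  if (k < 2) return(out)
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      out[a, b] <- out[b, a] <- binary_jsd_mean(p[, a], p[, b])
    }
  }
  out
}

#' Out-of-fold probability matrix for retained learners
#'
#' For every learner, refits its selected configuration on each set of k-1
#' folds and scores the held-out fold, so each patient's probability comes
#' from a model trained without that patient's fold. This is the standard
#' anti-leakage construction for stacking meta-features.
#'
#' @param tuned list of `"daplex_tuned"` objects (the retained learners).
#' @param x,y training feature matrix and labels.
#' @param folds the Phase I fold assignment (must match the one stored on
#'   every tuned model).
#' @return list of class `"daplex_oof"`: `prob` (patients x models matrix),
#'   `fold_fits` (per model, per fold, the fitted fold model — reused by the
#'   permutation-importance step), `folds`.
#' @export
oof_probabilities <- function(tuned, x, y, folds) {
  for (tm in tuned) {
    if (!identical(tm$folds, folds)) {
      stop_daplex("fold assignment mismatch for %s: OOF must reuse the Phase I partition",
                  tm$name)
    }
  }
  k <- max(folds)
  prob <- matrix(NA_real_, nrow = nrow(x), ncol = length(tuned),
                 dimnames = list(NULL, vapply(tuned, `[[`, character(1), "name")))
  fold_fits <- lapply(tuned, function(tm) vector("list", k))
  names(fold_fits) <- colnames(prob)
  for (j in seq_along(tuned)) {
    tm <- tuned[[j]]
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_base_learner(tm$name, x[tr, , drop = FALSE], y[tr],
                              tm$best_params,
                              seed = child_seed(tm$seed, 499L * f))
      fold_fits[[j]][[f]] <- fit
      prob[!tr, j] <- predict_prob(fit, x[!tr, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(prob))
  structure(list(prob = prob, fold_fits = fold_fits, folds = folds),
            class = "daplex_oof")
}

#' Grouped permutation importance for one fitted model
#'
#' For each source clinical variable, jointly permutes all of its emitted
#' one-hot/continuous columns in the validation rows and measures the drop
#' in balanced accuracy, averaged over `n_repeats` permutations. Ranks are
#' assigned by descending importance, ties broken by variable name.
#'
#' @param fit a `"daplex_base_fit"`.
#' @param x_val,y_val validation feature matrix and labels.
#' @param group_map named character vector: emitted column -> source
#'   variable; must cover every column of `x_val`.
#' @param n_repeats permutations per variable (default 10).
#' @param seed integer seed.
#' @return data.frame of class `"daplex_importance"`: `variable`,
#'   `importance` (mean BA drop), `rank`.
#' @export
permutation_importance <- function(fit, x_val, y_val, group_map,
                                   n_repeats = 10L, seed = 1L) {
  if (!nrow(x_val)) stop_daplex("empty validation set")
  if (!all(colnames(x_val) %in% names(group_map))) {
    stop_daplex("group_map does not cover every feature column")
  }
  base_ba <- binary_metrics(y_val, predict_prob(fit, x_val))[["balanced_accuracy"]]
  vars <- unique(unname(group_map[colnames(x_val)]))
  n <- nrow(x_val)
  # stack every (variable, repeat) permutation into one matrix so the model
  # predicts once per call — fixed predict overhead dominates otherwise
  blocks <- with_seed(seed, {
    lapply(vars, function(v) {
      cols <- intersect(names(group_map)[group_map == v], colnames(x_val))
      lapply(seq_len(n_repeats), function(r) {
        xp <- x_val
        xp[, cols] <- x_val[sample.int(n), cols, drop = FALSE]
        xp
      })
    })
  })
  big <- do.call(rbind, unlist(blocks, recursive = FALSE))
  p <- predict_prob(fit, big)
  block_ba <- vapply(seq_len(length(vars) * n_repeats), function(b) {
    pr <- p[((b - 1) * n + 1):(b * n)]
    binary_metrics(y_val, pr)[["balanced_accuracy"]]
  }, numeric(1))
  imp <- base_ba - colMeans(matrix(block_ba, nrow = n_repeats))
  names(imp) <- vars
  ord <- order(-imp, vars)
  rank <- integer(length(vars))
  rank[ord] <- seq_along(vars)
  structure(
    data.frame(variable = vars, importance = unname(imp), rank = rank,
               stringsAsFactors = FALSE),
    class = c("daplex_importance", "data.frame")
  )
}

#' Fold-averaged permutation importance for every retained learner
#'
#' Applies [permutation_importance()] on held-out validation folds using the
#' corresponding fold-fitted models (from the OOF pass), so the estimates
#' never reuse the rows a model was trained on. The `n_repeats` permutation
#' draws per variable are distributed as evenly as possible across the k
#' validation folds, and the per-fold mean balanced-accuracy drops are
#' combined by a repeat-weighted mean before ranking.
#'
#' @param oof a `"daplex_oof"` object.
#' @param x,y training feature matrix and labels.
#' @param group_map emitted column -> source variable.
#' @param n_repeats total permutations per variable (default 10).
#' @param seed integer seed.
#' @return named list of `"daplex_importance"` data.frames, one per model.
#' @export
pool_permutation_importance <- function(oof, x, y, group_map,
                                        n_repeats = 10L, seed = 1L) {
  k <- max(oof$folds)
  reps <- diff(floor(seq(0, n_repeats, length.out = k + 1)))
  out <- lapply(names(oof$fold_fits), function(model) {
    per_fold <- lapply(which(reps > 0), function(f) {
      va <- oof$folds == f
      permutation_importance(oof$fold_fits[[model]][[f]],
                             x[va, , drop = FALSE], y[va], group_map,
                             n_repeats = reps[f],
                             seed = child_seed(seed, 271L * f))
    })
    vars <- per_fold[[1]]$variable
    w <- reps[reps > 0]
    imp <- as.numeric(vapply(per_fold, function(d) {
      d$importance[match(vars, d$variable)]
    }, numeric(length(vars))) %*% (w / sum(w)))
    ord <- order(-imp, vars)
    rank <- integer(length(vars))
    rank[ord] <- seq_along(vars)
    structure(
      data.frame(variable = vars, importance = unname(imp), rank = rank,
                 stringsAsFactors = FALSE),
      class = c("daplex_importance", "data.frame")
    )
  })
  stats::setNames(out, names(oof$fold_fits))
}

#' Borda-count consensus of per-model importance rankings
#'
#' Rank-sum Borda variant: each variable's score is the sum of its per-model
#' ranks, so lower scores mean stronger consensus importance (a variable
#' ranked first by all of `m` models scores exactly `m`). Ties are broken by
#' mean raw importance (descending), then variable name.
#'
#' @param rankings list of `"daplex_importance"` data.frames over the same
#'   variable set.
#' @param k size of the consensus feature list (default 5).
#' @return list of class `"daplex_borda"`: `table` (variable, borda_score,
#'   consensus_rank, mean_importance), `top_k` (character vector of the k
#'   consensus variables), `k`.
#' @export
borda_aggregate <- function(rankings, k = 5L) {
  if (!length(rankings)) stop_daplex("no rankings to aggregate")
  vars <- sort(rankings[[1]]$variable)
  for (r in rankings) {
    if (!identical(sort(r$variable), vars)) {
      stop_daplex("rankings cover inconsistent variable sets")
    }
  }
  if (k > length(vars)) stop_daplex("k exceeds the number of variables")
  rank_mat <- matrix(vapply(rankings, function(r) {
    r$rank[match(vars, r$variable)]
  }, numeric(length(vars))), nrow = length(vars))
  imp_mat <- matrix(vapply(rankings, function(r) {
    r$importance[match(vars, r$variable)]
  }, numeric(length(vars))), nrow = length(vars))
  score <- rowSums(rank_mat)
  mean_imp <- rowMeans(imp_mat)
  ord <- order(score, -mean_imp, vars)
  tab <- data.frame(variable = vars[ord], borda_score = score[ord],
                    consensus_rank = seq_along(vars),
                    mean_importance = mean_imp[ord],
                    stringsAsFactors = FALSE)
  structure(list(table = tab, top_k = tab$variable[seq_len(k)], k = as.integer(k)),
            class = "daplex_borda")
}

# Pick one representative emitted column per consensus variable so the
# meta-input has exactly (retained + k) columns: a continuous variable maps
# to its z-scored column; a categorical/binary variable maps to the single
# indicator column most correlated (|r|) with the training labels.
representative_columns <- function(x_train, y_train, group_map, vars) {
  vapply(vars, function(v) {
    cols <- names(group_map)[group_map == v]
    cols <- intersect(cols, colnames(x_train))
    if (!length(cols)) stop_daplex("consensus variable '%s' absent from the feature matrix", v)
    if (length(cols) == 1L) return(cols)
    cors <- vapply(cols, function(cl) {
      s <- stats::sd(x_train[, cl])
      if (s == 0) 0 else abs(stats::cor(x_train[, cl], y_train))
    }, numeric(1))
    cols[which.max(cors)]
  }, character(1))
}

#' Assemble the hybrid meta-input
#'
#' Columns are, in order, each retained learner's positive-class OOF
#' probability followed by one representative column per consensus variable;
#' the assembled matrix is z-scored with parameters stored for test time.
#'
#' @param oof_prob patients x models OOF probability matrix.
#' @param x_train training feature matrix (row-aligned with `oof_prob`).
#' @param y_train 0/1 training labels (used only to pick the representative
#'   indicator column of a categorical consensus variable).
#' @param group_map emitted column -> source variable.
#' @param consensus a `"daplex_borda"` object.
#' @return list of class `"daplex_meta_input"`: `x` (standardized matrix,
#'   `ncol = ncol(oof_prob) + k`), `center`, `scale`, `rep_cols` (consensus
#'   variable -> representative column).
#' @export
build_meta_input <- function(oof_prob, x_train, y_train, group_map, consensus) {
  stopifnot(inherits(consensus, "daplex_borda"))
  if (nrow(oof_prob) != nrow(x_train)) stop_daplex("row misalignment between OOF and features")
  rep_cols <- representative_columns(x_train, y_train, group_map, consensus$top_k)
  raw <- cbind(oof_prob, x_train[, rep_cols, drop = FALSE])
  colnames(raw) <- c(paste0("oof_", colnames(oof_prob)),
                     paste0("feat_", consensus$top_k))
  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  scale[scale == 0] <- 1
  x <- sweep(sweep(raw, 2, center), 2, scale, "/")
  structure(list(x = x, center = center, scale = scale, rep_cols = rep_cols),
            class = "daplex_meta_input")
}

#' Tune the MLP meta-learner on the hybrid meta-input
#'
#' Runs the same balanced-accuracy-optimized grid-search machinery as
#' Phase I, on the same fold partition, so the meta-learner's own stability
#' gap is reportable alongside the base learners'.
#'
#' @param meta a `"daplex_meta_input"`.
#' @param y 0/1 training labels.
#' @param folds the shared fold assignment.
#' @param spec meta-learner spec (default [default_meta_spec()]).
#' @param seed integer seed.
#' @return a `"daplex_tuned"` object for the MLP.
#' @export
train_meta_learner <- function(meta, y, folds, spec = default_meta_spec(),
                               seed = 1L) {
  stopifnot(inherits(meta, "daplex_meta_input"))
  run_grid_search(spec, meta$x, y, folds, seed = seed)
}
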