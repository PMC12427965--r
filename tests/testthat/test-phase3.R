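# Phase III: Friedman test, Jensen-Shannon divergence, OOF stacking,
# permutation importance, Borda consensus, meta-input and meta-learner.

test_that("friedman test matches brute-force rank formula and stats oracle", {
  # brute-force oracle: midranks within rows, tie-corrected chi-square
  friedman_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    r <- t(apply(m, 1, rank))
    rj <- colSums(r)
    ties <- sum(apply(m, 1, function(row) {
      t <- as.numeric(table(row)); sum(t^3 - t)
    }))
    12 * sum((rj - n * (k + 1) / 2)^2) / (n * k * (k + 1) - ties / (k - 1))
  }
  set.seed(17)
  for (dims in list(c(4, 3), c(5, 5), c(3, 2), c(5, 4))) {
    m <- matrix(round(runif(prod(dims)), 1), dims[1], dims[2])  # forces ties
    ft <- friedman_rank_test(m)
    expect_near(ft$statistic, friedman_oracle(m))
    expect_equal(ft$df, dims[2] - 1L)
    # independent implementation cross-check
    st <- stats::friedman.test(m)
    expect_near(ft$statistic, unname(st$statistic))
    expect_near(ft$p_value, st$p.value)
  }
  # five models give four degrees of freedom
  expect_equal(friedman_rank_test(matrix(runif(25), 5, 5))$df, 4L)
  # fully tied matrix: statistic 0, p = 1
  degen <- friedman_rank_test(matrix(1, 4, 3))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)
})

test_that("js_divergence matches a hand-evaluated base-2 oracle", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  # direct two-term KL summation, logs base 2, m = (p+q)/2 = (0.5, 0.5)
  oracle <- 0.5 * (0.8 * log2(0.8 / 0.5) + 0.2 * log2(0.2 / 0.5)) +
            0.5 * (0.2 * log2(0.2 / 0.5) + 0.8 * log2(0.8 / 0.5))
  expect_near(js_divergence(c(0.8, 0.2), c(0.2, 0.8)), oracle)
  expect_error(js_divergence(c(0.5, 0.6), c(0.5, 0.5)), "summing to 1")
  expect_error(js_divergence(c(-0.1, 1.1), c(0.5, 0.5)), "distribution")
})

test_that("jsd_matrix is a symmetric zero-diagonal per-patient average", {
  # three-model toy set of 4 patients: brute-force per-patient averaging
  p <- cbind(a = c(0.9, 0.1, 0.5, 0.7),
             b = c(0.8, 0.3, 0.5, 0.2),
             c = c(0.1, 0.9, 0.5, 0.3))
  jm <- jsd_matrix(p)
  oracle <- function(pa, pb) {
    mean(vapply(seq_along(pa), function(i) {
      js_divergence(c(pa[i], 1 - pa[i]), c(pb[i], 1 - pb[i]))
    }, numeric(1)))
  }
  for (a in 1:3) {
    for (b in 1:3) {
      expect_near(jm[a, b], if (a == b) 0 else oracle(p[, a], p[, b]))
    }
  }
  expect_near(jm, t(jm), tol = 1e-12)
  expect_true(all(jm >= 0 & jm <= 1))
  # identical models diverge by zero; antipodal extreme probabilities tend to 1
  same <- jsd_matrix(cbind(m1 = c(0.2, 0.9), m2 = c(0.2, 0.9)))
  expect_equal(same[1, 2], 0)
  anti <- jsd_matrix(cbind(m1 = c(1e-9, 1 - 1e-9), m2 = c(1 - 1e-9, 1e-9)))
  expect_gt(anti[1, 2], 0.999)
})

test_that("OOF probabilities cover every patient without leakage", {
  co <- separable_cohort(n = 100, seed = 21)
  ft <- apply_transform(fit_transform_spec(co), co)
  folds <- make_cv_folds(ft$y, 5, seed = 1)
  tuned <- tune_pool(tiny_pool(), ft$x, ft$y, folds, seed = 2)
  oof <- oof_probabilities(tuned, ft$x, ft$y, folds)
  expect_false(anyNA(oof$prob))
  expect_equal(dim(oof$prob), c(100L, 2L))
  # determinism
  oof2 <- oof_probabilities(tuned, ft$x, ft$y, folds)
  expect_identical(oof$prob, oof2$prob)
  # fold mismatch is an error
  other <- make_cv_folds(ft$y, 5, seed = 99)
  expect_error(oof_probabilities(tuned, ft$x, ft$y, other), "fold")
})

test_that("a memorizing learner's OOF score collapses to chance on noise labels", {
  # features informative, labels pure noise: in-sample 1-NN is perfect,
  # out-of-fold it must be chance-level
  co <- generate_cohort(default_lrti_config(), seed = 31)
  daplex:::with_seed(99, co$diagnosis <- sample(co$diagnosis))
  ft <- apply_transform(fit_transform_spec(co), co)
  folds <- make_cv_folds(ft$y, 5, seed = 1)
  tm <- run_grid_search(memorizer_spec(), ft$x, ft$y, folds, seed = 1)
  oof <- oof_probabilities(list(KNN = tm), ft$x, ft$y, folds)
  in_sample <- binary_metrics(ft$y, daplex:::predict_prob(tm$fit, ft$x))
  oof_ba <- binary_metrics(ft$y, oof$prob[, "KNN"])[["balanced_accuracy"]]
  expect_equal(in_sample[["balanced_accuracy"]], 1)
  expect_lt(abs(oof_ba - 0.5), 0.05)
})

test_that("permutation importance finds signal and ignores noise", {
  daplex:::with_seed(41, {
    n <- 400
    y <- rbinom(n, 1, 0.5)
    x <- cbind(label_copy = y, noise1 = rnorm(n), noise2 = rnorm(n))
  })
  gm <- setNames(colnames(x), colnames(x))
  fit <- daplex:::fit_base_learner("GNB", x, y, list(var_smoothing = 1e-9), 1)
  imp <- permutation_importance(fit, x, y, gm, n_repeats = 10, seed = 5)
  expect_equal(imp$variable[imp$rank == 1], "label_copy")
  # a label-copy feature carries all the signal: importance ~ BA - 0.5
  expect_gt(imp$importance[imp$variable == "label_copy"], 0.4)
  expect_lt(max(abs(imp$importance[imp$variable != "label_copy"])), 0.05)
  # ranks are a permutation of 1..V; determinism under a fixed seed
  expect_setequal(imp$rank, 1:3)
  imp2 <- permutation_importance(fit, x, y, gm, n_repeats = 10, seed = 5)
  expect_identical(imp, imp2)
})

test_that("grouped permutation destroys a variable's one-hot columns jointly", {
  co <- separable_cohort(n = 200, seed = 8)
  co$cat <- factor(ifelse(co$diagnosis == 1, "P", "B"))  # categorical label copy
  ft <- apply_transform(fit_transform_spec(co), co)
  fit <- daplex:::fit_base_learner("GNB", ft$x, ft$y, list(var_smoothing = 1e-9), 1)
  imp <- permutation_importance(fit, ft$x, ft$y, ft$feature_group,
                                n_repeats = 5, seed = 2)
  expect_setequal(imp$variable, c("f1", "f2", "cat"))
  expect_gt(imp$importance[imp$variable == "cat"], 0)
})

test_that("borda aggregation matches the exhaustive rank-sum oracle", {
  mk <- function(vars, ranks, imps) {
    structure(data.frame(variable = vars, importance = imps, rank = ranks,
                         stringsAsFactors = FALSE),
              class = c("daplex_importance", "data.frame"))
  }
  vars <- c("a", "b", "c", "d")
  r1 <- mk(vars, c(1, 2, 3, 4), c(0.4, 0.3, 0.2, 0.1))
  r2 <- mk(vars, c(2, 1, 3, 4), c(0.3, 0.5, 0.2, 0.1))
  r3 <- mk(vars, c(1, 3, 2, 4), c(0.5, 0.2, 0.3, 0.1))
  bc <- borda_aggregate(list(r1, r2, r3), k = 2)
  # exhaustive rank sums: a = 4, b = 6, c = 8, d = 12
  expect_equal(bc$table$borda_score[match(c("a", "b", "c", "d"),
                                          bc$table$variable)],
               c(4, 6, 8, 12))
  expect_equal(bc$top_k, c("a", "b"))
  # consensus scores non-decreasing down the ranking
  expect_true(all(diff(bc$table$borda_score) >= 0))
  # unanimity lower bound: score = number of models iff ranked 1 by all
  r4 <- mk(vars, c(1, 2, 3, 4), c(0.4, 0.3, 0.2, 0.1))
  bc2 <- borda_aggregate(list(r1, r4), k = 1)
  expect_equal(min(bc2$table$borda_score), 2)
  expect_equal(bc2$table$variable[1], "a")
  expect_error(borda_aggregate(list(r1, mk(c("a", "b", "x", "d"),
                                           1:4, rep(0, 4))), 2),
               "inconsistent")
  expect_error(borda_aggregate(list(r1), k = 9), "k exceeds")
})

test_that("ties in borda score break by mean importance, then name", {
  mk <- function(ranks, imps) {
    structure(data.frame(variable = c("a", "b"), importance = imps,
                         rank = ranks, stringsAsFactors = FALSE),
              class = c("daplex_importance", "data.frame"))
  }
  bc <- borda_aggregate(list(mk(c(1, 2), c(0.1, 0.9)),
                             mk(c(2, 1), c(0.1, 0.9))), k = 1)
  expect_equal(bc$top_k, "b")  # tied score 3/3, b has larger mean importance
})

test_that("meta-input has retained + k standardized columns", {
  co <- separable_cohort(n = 120, seed = 33)
  ft <- apply_transform(fit_transform_spec(co), co)
  folds <- make_cv_folds(ft$y, 5, seed = 1)
  tuned <- tune_pool(tiny_pool(), ft$x, ft$y, folds, seed = 2)
  oof <- oof_probabilities(tuned, ft$x, ft$y, folds)
  imp <- pool_permutation_importance(oof, ft$x, ft$y, ft$feature_group,
                                     n_repeats = 5, seed = 3)
  cons <- borda_aggregate(imp, k = 2)
  meta <- build_meta_input(oof$prob, ft$x, ft$y, ft$feature_group, cons)
  expect_equal(ncol(meta$x), length(tuned) + 2L)
  expect_equal(nrow(meta$x), 120L)
  expect_true(all(abs(colMeans(meta$x)) < 1e-9))
  expect_true(all(abs(apply(meta$x, 2, sd) - 1) < 1e-9))
})

test_that("meta-learner reaches BA ~ 1 on a separable meta-input", {
  daplex:::with_seed(3, {
    n <- 200
    y <- rbinom(n, 1, 0.5)
    oof <- cbind(m1 = y * 0.9 + 0.05, m2 = y * 0.8 + 0.1)
    x <- cbind(f = rnorm(n))
  })
  gm <- c(f = "f")
  cons <- borda_aggregate(list(structure(
    data.frame(variable = "f", importance = 0, rank = 1L,
               stringsAsFactors = FALSE),
    class = c("daplex_importance", "data.frame"))), k = 1)
  meta <- build_meta_input(oof, x, y, gm, cons)
  folds <- make_cv_folds(y, 5, seed = 1)
  mt <- train_meta_learner(meta, y, folds,
                           spec = base_learner_spec("MLP", list(size = 4L, decay = 1e-3,
                                                                maxit = 200L)),
                           seed = 2)
  val_ba <- mt$fold_scores$value[mt$fold_scores$side == "validation" &
                                 mt$fold_scores$metric == "balanced_accuracy"]
  expect_gt(mean(val_ba), 0.99)
  # meta stability report carries all seven metrics
  expect_setequal(unique(mt$fold_scores$metric), daplex:::METRIC_NAMES)
  # fixed seed: identical selected hyperparameters
  mt2 <- train_meta_learner(meta, y, folds,
                            spec = base_learner_spec("MLP", list(size = 4L, decay = 1e-3,
                                                                 maxit = 200L)),
                            seed = 2)
  expect_identical(mt$best_params, mt2$best_params)
})
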