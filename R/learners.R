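# Base-learner registry. Every learner exposes the same minimal surface:
#   fit(x, y, params, seed)  -> fitted object
#   prob(fit, x)             -> positive-class probability per row
# which is all the grid search, OOF stacking, permutation importance and
# final prediction need. Backends: ranger (RF), xgboost, e1071 (SVMs);
# k-NN and Gaussian naive Bayes are implemented here directly (no installed
# backend exposes distance-weighted k-NN probabilities or Gaussian variance
# smoothing); the MLP is nnet.

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# --- SVM helpers -----------------------------------------------------------

svm_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) 1 / (ncol(x) * stats::var(as.vector(x))) else as.numeric(gamma)
}

# Platt-style sigmoid calibration of SVM decision values: a binomial glm of
# the training labels on the decision values. Deterministic, unlike libsvm's
# internal cross-validated probability fitting.
fit_platt <- function(dv, y) {
  df <- data.frame(dv = dv, y = y)
  suppressWarnings(stats::glm(y ~ dv, family = stats::binomial(), data = df))
}

svm_decision_values <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values")[, 1])
}

fit_svm <- function(x, y, kernel, params, seed) {
  args <- list(x = x, y = factor(y, levels = c(0, 1)), kernel = kernel,
               cost = params$cost, scale = FALSE, probability = FALSE)
  if (kernel == "radial") args$gamma <- svm_gamma(params$gamma, x)
  # inhomogeneous polynomial kernel: coef0 = 1 keeps lower-order terms, so
  # even degrees are not blind to the sign symmetry of centered features
  if (kernel == "polynomial") {
    args$degree <- params$degree
    args$coef0 <- 1
  }
  fit <- with_seed(seed, do.call(e1071::svm, args))
  calib <- fit_platt(svm_decision_values(fit, x), y)
  list(svm = fit, calib = calib)
}

prob_svm <- function(fit, x) {
  dv <- svm_decision_values(fit$svm, x)
  clamp_prob(as.numeric(stats::predict(fit$calib, data.frame(dv = dv),
                                       type = "response")))
}

# --- k-nearest neighbours --------------------------------------------------

# Plain Euclidean k-NN with uniform or inverse-distance vote weights.
# Predicting on a training row finds the row itself at distance zero, so a
# 1-NN model memorizes its training labels — the behaviour the stability-gap
# and OOF-leakage diagnostics rely on.
fit_knn <- function(x, y, params, seed) {
  list(x = x, y = as.numeric(y), k = params$k,
       weights = params$weights %||% "uniform")
}

prob_knn <- function(fit, x) {
  n_train <- nrow(fit$x)
  k <- fit$k
  xt2 <- rowSums(fit$x^2)
  out <- numeric(nrow(x))
  # chunk the distance matrix; select the k nearest with k vectorized
  # max.col passes (ties broken by first index — deterministic)
  chunk <- max(1L, floor(2e7 / n_train))
  for (start in seq(1, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    xa <- x[idx, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), xt2, "+") - 2 * tcrossprod(xa, fit$x)
    d2[d2 < 0] <- 0
    m <- length(idx)
    nn_idx <- matrix(0L, m, k)
    nn_d2 <- matrix(0, m, k)
    neg <- -d2
    for (j in seq_len(k)) {
      jmin <- max.col(neg, ties.method = "first")
      sel <- cbind(seq_len(m), jmin)
      nn_idx[, j] <- jmin
      nn_d2[, j] <- d2[sel]
      neg[sel] <- -Inf
    }
    yk <- matrix(fit$y[nn_idx], m, k)
    if (fit$weights == "distance") {
      exact <- nn_d2 < 1e-12
      w <- 1 / sqrt(pmax(nn_d2, 1e-24))
      p <- rowSums(w * yk) / rowSums(w)
      has_exact <- rowSums(exact) > 0
      if (any(has_exact)) {
        # an exact feature match memorizes: vote only among zero-distance rows
        p[has_exact] <- rowSums(yk * exact)[has_exact] / rowSums(exact)[has_exact]
      }
      out[idx] <- p
    } else {
      out[idx] <- rowMeans(yk)
    }
  }
  out
}

# --- Gaussian naive Bayes --------------------------------------------------

# Per-class Gaussian likelihoods with additive variance smoothing:
# var_smoothing * max(per-feature pooled variance) is added to every
# class-conditional variance, stabilizing near-constant indicator columns.
fit_gnb <- function(x, y, params, seed) {
  eps <- params$var_smoothing * max(apply(x, 2, stats::var))
  stats_by_class <- lapply(c(0, 1), function(cls) {
    xc <- x[y == cls, , drop = FALSE]
    v <- apply(xc, 2, stats::var)
    v[is.na(v)] <- 0
    list(mean = colMeans(xc), var = v + eps, prior = nrow(xc) / nrow(x))
  })
  names(stats_by_class) <- c("0", "1")
  stats_by_class
}

prob_gnb <- function(fit, x) {
  loglik <- vapply(fit, function(s) {
    centered2 <- sweep(x, 2, s$mean)^2
    log(s$prior) - 0.5 * sum(log(2 * pi * s$var)) -
      rowSums(sweep(centered2, 2, 2 * s$var, "/"))
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) loglik <- matrix(loglik, nrow = 1)
  1 / (1 + exp(loglik[, 1] - loglik[, 2]))
}

# --- registry --------------------------------------------------------------

learner_registry <- function() {
  list(
    RF = list(
      fit = function(x, y, params, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       probability = TRUE,
                       num.trees = params$num_trees,
                       max.depth = params$max_depth,
                       seed = seed, num.threads = 1L)
      },
      prob = function(fit, x) {
        as.numeric(stats::predict(fit, data = x, num.threads = 1L)$predictions[, "1"])
      }
    ),
    XGBoost = list(
      fit = function(x, y, params, seed) {
        dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        eta = params$eta, max_depth = params$max_depth,
                        nthread = 1L, seed = seed),
          data = dtrain, nrounds = params$nrounds, verbose = 0)
      },
      prob = function(fit, x) {
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(data = x)))
      }
    ),
    SVM_RBF = list(
      fit = function(x, y, params, seed) fit_svm(x, y, "radial", params, seed),
      prob = prob_svm
    ),
    SVM_Poly = list(
      fit = function(x, y, params, seed) fit_svm(x, y, "polynomial", params, seed),
      prob = prob_svm
    ),
    KNN = list(fit = fit_knn, prob = prob_knn),
    GNB = list(fit = fit_gnb, prob = prob_gnb),
    MLP = list(
      # BFGS from a single random init occasionally stalls in a poor local
      # minimum (training points left at extreme wrong probabilities); fit
      # from several inits and keep the lowest-loss solution
      fit = function(x, y, params, seed) {
        starts <- params$n_starts %||% 2L
        fits <- lapply(seq_len(starts), function(i) {
          with_seed(child_seed(seed, i),
                    nnet::nnet(x = x, y = y, size = params$size,
                               decay = params$decay,
                               maxit = params$maxit %||% 500L,
                               entropy = TRUE, trace = FALSE,
                               MaxNWts = 10000L))
        })
        fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      },
      prob = function(fit, x) clamp_prob(as.numeric(stats::predict(fit, x)))
    )
  )
}

#' Declare a base learner and its hyperparameter grid
#'
#' @param name one of `"RF"`, `"XGBoost"`, `"SVM_RBF"`, `"SVM_Poly"`,
#'   `"KNN"`, `"GNB"`, `"MLP"`.
#' @param grid named list: parameter name -> ordered candidate vector. The
#'   grid is enumerated in deterministic [expand.grid()] order; ties in mean
#'   validation balanced accuracy resolve to the earliest configuration.
#' @return object of class `"daplex_learner_spec"`.
#' @export
base_learner_spec <- function(name, grid) {
  reg <- learner_registry()
  if (!name %in% names(reg)) {
    stop_daplex("unknown learner '%s' (available: %s)", name,
                paste(names(reg), collapse = ", "))
  }
  structure(list(name = name, grid = grid), class = "daplex_learner_spec")
}

#' Default six-learner pool with hyperparameter grids
#'
#' The heterogeneous pool spans bagging (random forest), boosting (XGBoost),
#' margin-based kernels (SVM with RBF and polynomial kernels), instance-based
#' learning (k-NN) and a probabilistic model (Gaussian naive Bayes). Grids
#' are modest, documented defaults and fully overridable.
#'
#' @return named list of [base_learner_spec()] objects.
#' @export
default_pool <- function() {
  list(
    RF = base_learner_spec("RF", list(num_trees = c(100L, 300L, 500L),
                                      max_depth = c(0L, 5L, 10L))),
    XGBoost = base_learner_spec("XGBoost", list(nrounds = c(100L, 300L),
                                                eta = c(0.05, 0.1, 0.3),
                                                max_depth = c(3L, 5L))),
    SVM_RBF = base_learner_spec("SVM_RBF", list(cost = c(0.1, 1, 10),
                                                gamma = c("scale", "0.01", "0.1"))),
    SVM_Poly = base_learner_spec("SVM_Poly", list(cost = c(0.1, 1, 10),
                                                  degree = c(2L, 3L))),
    KNN = base_learner_spec("KNN", list(k = c(3L, 5L, 7L, 11L),
                                        weights = c("uniform", "distance"))),
    GNB = base_learner_spec("GNB", list(var_smoothing = c(1e-9, 1e-8)))
  )
}

#' Default meta-learner (MLP) grid
#'
#' Single-hidden-layer perceptron sizes with two L2 penalties; ample
#' capacity for the low-dimensional hybrid meta-input.
#' @return a [base_learner_spec()] for the MLP.
#' @export
default_meta_spec <- function() {
  base_learner_spec("MLP", list(size = c(8L, 16L, 32L),
                                decay = c(1e-4, 1e-3)))
}

fit_base_learner <- function(name, x, y, params, seed) {
  reg <- learner_registry()[[name]]
  structure(list(name = name, fit = reg$fit(x, y, params, seed),
                 params = params),
            class = "daplex_base_fit")
}

predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "daplex_base_fit"))
  learner_registry()[[fit$name]]$prob(fit$fit, x)
}
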