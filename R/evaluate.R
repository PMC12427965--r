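# Holdout benchmarking of the fused model against every base learner,
# relative-improvement summaries, and demographic subgroup analysis.

#' Benchmark the fused model and every base learner on the holdout set
#'
#' Computes the seven metrics for each tuned base learner (full-training
#' fit) and for the fused meta-model on the untouched holdout rows, plus
#' relative improvements of the fused model over the weakest and strongest
#' base learner: `100 * (fused - base) / base` for score metrics (balanced
#' accuracy, F1, sensitivity) and `100 * (base - fused) / base` for the
#' Brier score (a reduction percentage).
#'
#' @param model a `"daplex_model"`.
#' @param test holdout cohort data.frame (with `diagnosis`).
#' @param include_pruned also benchmark pruned learners (default `TRUE`,
#'   mirroring a comparison over the full pool).
#' @return list of class `"daplex_holdout"`: `metrics` (one row per model,
#'   fused model last, row `DAPLEX`), `improvements` (metric, vs_weakest,
#'   vs_strongest), `n_test`.
#' @export
evaluate_holdout <- function(model, test, include_pruned = TRUE) {
  if (!nrow(test)) stop_daplex("empty holdout set")
  feats <- apply_transform(model$transform, test)
  y <- feats$y
  base_names <- if (include_pruned) names(model$tuned) else model$retained
  rows <- lapply(base_names, function(nm) {
    p <- predict_prob(model$tuned[[nm]]$fit, feats$x)
    cbind(data.frame(model = nm, stringsAsFactors = FALSE),
          as.data.frame(as.list(binary_metrics(y, p, model$threshold))))
  })
  p_fused <- predict(model, test)$probability
  rows[[length(rows) + 1L]] <-
    cbind(data.frame(model = "DAPLEX", stringsAsFactors = FALSE),
          as.data.frame(as.list(binary_metrics(y, p_fused, model$threshold))))
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  improvements <- improvement_summary(metrics)
  structure(list(metrics = metrics, improvements = improvements,
                 n_test = nrow(test)),
            class = "daplex_holdout")
}

#' Relative-improvement summary from a holdout metrics table
#'
#' @param metrics data.frame with a `model` column (the fused model in row
#'   `"DAPLEX"`) and metric columns `balanced_accuracy`, `f1`,
#'   `sensitivity`, `brier`.
#' @return data.frame: `metric`, `vs_weakest`, `vs_strongest` — percentage
#'   improvements of the fused model over the weakest/strongest base learner
#'   (for Brier: percentage reduction vs the worst/best-calibrated base).
#' @export
improvement_summary <- function(metrics) {
  fused <- metrics[metrics$model == "DAPLEX", , drop = FALSE]
  base <- metrics[metrics$model != "DAPLEX", , drop = FALSE]
  if (!nrow(fused) || !nrow(base)) stop_daplex("metrics table must contain DAPLEX and base rows")
  rows <- lapply(c("balanced_accuracy", "f1", "sensitivity"), function(m) {
    d <- fused[[m]]
    data.frame(metric = m,
               vs_weakest = 100 * (d - min(base[[m]])) / min(base[[m]]),
               vs_strongest = 100 * (d - max(base[[m]])) / max(base[[m]]),
               stringsAsFactors = FALSE)
  })
  d <- fused$brier
  rows[[length(rows) + 1L]] <-
    data.frame(metric = "brier",
               vs_weakest = 100 * (max(base$brier) - d) / max(base$brier),
               vs_strongest = 100 * (min(base$brier) - d) / min(base$brier),
               stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

age_bin <- function(age_months) {
  cut(age_months, breaks = c(0, 12, 60, Inf), right = FALSE,
      labels = c("infancy_0_11m", "early_childhood_12_59m", "school_age_60m_plus"))
}

#' Demographic subgroup analysis on the holdout set
#'
#' Stratifies the holdout set by sex and by age bins (months, half-open:
#' `[0, 12)` infancy, `[12, 60)` early childhood, `[60, Inf)` school age)
#' and reports the seven metrics per stratum. Strata containing a single
#' class report `NA` (flagged undefined) for the metrics that need both
#' classes.
#'
#' @param model a `"daplex_model"`.
#' @param test holdout cohort data.frame.
#' @param sex_col name of the binary sex column (default `"sex_male"`,
#'   1 = male).
#' @param age_col name of the age-in-months column (default `"age_months"`).
#' @return data.frame: `stratum_type`, `stratum`, `n`, metric columns.
#' @export
subgroup_analysis <- function(model, test, sex_col = "sex_male",
                              age_col = "age_months") {
  for (col in c(sex_col, age_col)) {
    if (!col %in% names(test)) stop_daplex("holdout table lacks demographic column '%s'", col)
  }
  p <- predict(model, test)$probability
  y <- as.integer(test$diagnosis)
  strata <- list(
    sex = factor(ifelse(test[[sex_col]] == 1, "male", "female"),
                 levels = c("male", "female")),
    age = age_bin(test[[age_col]])
  )
  rows <- list()
  for (type in names(strata)) {
    f <- strata[[type]]
    for (lev in levels(f)) {
      sel <- !is.na(f) & f == lev
      met <- if (any(sel)) {
        binary_metrics(y[sel], p[sel], model$threshold)
      } else {
        stats::setNames(rep(NA_real_, length(METRIC_NAMES)), METRIC_NAMES)
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(stratum_type = type, stratum = lev, n = sum(sel),
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(met)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
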