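# One-call pipeline: simulate (optional) -> split -> preprocess -> Phase I
# -> Phase II -> Phase III -> holdout evaluation -> subgroup analysis, with
# all reports written as JSON/CSV artifacts. Fully reproducible from
# (config, seed); the holdout rows are hashed before any fitting and the
# hash is verified again before evaluation.

report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run the full diagnostic pipeline and write its artifacts
#'
#' @param cohort a cohort data.frame, or `NULL` to simulate one from
#'   `config`.
#' @param config a `"daplex_cohort_config"` used when `cohort` is `NULL`
#'   (default [default_lrti_config()]).
#' @param out_dir output directory for reports (created if missing); `NULL`
#'   skips writing.
#' @param seed master seed for simulation, split, folds and fits.
#' @param fraction training fraction for the stratified split.
#' @param ... passed to [fit_daplex()].
#' @return (invisibly) list: `model`, `split`, `baseline`, `holdout`,
#'   `subgroups`, `holdout_hash`, plus the cohort used.
#' @export
run_daplex_pipeline <- function(cohort = NULL, config = default_lrti_config(),
                                out_dir = NULL, seed = 1L, fraction = 0.8,
                                ...) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(config, seed = child_seed(seed, 1L))
  }
  baseline <- baseline_compare(cohort)
  split <- stratified_split(cohort, fraction = fraction,
                            seed = child_seed(seed, 2L))
  train <- cohort[split$train_indices, , drop = FALSE]
  test <- cohort[split$test_indices, , drop = FALSE]
  hash_before <- content_hash(test)

  model <- fit_daplex(train, seed = child_seed(seed, 3L), ...)

  hash_after <- content_hash(test)
  if (!identical(hash_before, hash_after)) {
    stop_daplex("holdout rows changed between split and evaluation")
  }
  holdout <- evaluate_holdout(model, test)
  subgroups <- subgroup_analysis(model, test)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(baseline, file.path(out_dir, "baseline_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(model$pool_report, file.path(out_dir, "pool_report.csv"),
                     row.names = FALSE)
    utils::write.csv(model$pruning$report,
                     file.path(out_dir, "stability_report.csv"),
                     row.names = FALSE)
    utils::write.csv(model$consensus$table,
                     file.path(out_dir, "consensus_features.csv"),
                     row.names = FALSE)
    utils::write.csv(holdout$metrics, file.path(out_dir, "holdout_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(subgroups, file.path(out_dir, "subgroup_report.csv"),
                     row.names = FALSE)
    report_json(model$pool_report, file.path(out_dir, "pool_report.json"))
    report_json(model$pruning$report, file.path(out_dir, "stability_report.json"))
    report_json(list(friedman = model$complementarity$friedman,
                     jsd_matrix = model$complementarity$jsd),
                file.path(out_dir, "complementarity_report.json"))
    report_json(list(table = model$consensus$table,
                     top_k = model$consensus$top_k),
                file.path(out_dir, "consensus_features.json"))
    report_json(list(
      seed = seed,
      n_patients = nrow(cohort),
      n_train = length(split$train_indices),
      n_test = length(split$test_indices),
      holdout_hash = hash_before,
      retained = model$retained,
      pruned = setdiff(names(model$tuned), model$retained),
      friedman = model$complementarity$friedman,
      jsd = list(min = min(model$complementarity$jsd[upper.tri(model$complementarity$jsd)]),
                 max = max(model$complementarity$jsd)),
      consensus_features = model$consensus$top_k,
      meta_params = model$meta$tuned$best_params,
      improvements = holdout$improvements,
      r_version = as.character(getRversion())
    ), file.path(out_dir, "run_summary.json"))
  }
  invisible(list(model = model, split = split, baseline = baseline,
                 holdout = holdout, subgroups = subgroups,
                 holdout_hash = hash_before, cohort = cohort))
}
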