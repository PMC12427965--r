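# Leakage-free stratified splitting and feature transformation. All
# transformation parameters (z-score means/SDs, one-hot category lists) are
# learned exclusively from training rows and applied identically to any
# table, so a holdout set never influences the fitted pipeline.

#' Stratified train/holdout split
#'
#' Splits the cohort into a training part and an independent holdout part
#' with stratification by diagnosis. Per-class training counts use
#' largest-remainder rounding so each part's class proportions differ from
#' the exact stratified proportion by at most one patient (868 rows at 0.8
#' give 694 train / 174 holdout).
#'
#' @param cohort data.frame with a 0/1 `diagnosis` column.
#' @param fraction training proportion in (0, 1); default 0.8.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list of class `"daplex_split"`: `train_indices`, `test_indices`,
#'   `fraction`, `seed`.
#' @export
stratified_split <- function(cohort, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_daplex("fraction must be in (0, 1)")
  y <- cohort$diagnosis
  if (is.null(y)) stop_daplex("cohort lacks a 'diagnosis' column")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < 2)) stop_daplex("each class needs at least 2 members to split")
  target_total <- round(nrow(cohort) * fraction)
  exact <- as.numeric(counts) * fraction
  n_train <- floor(exact)
  remainder <- exact - n_train
  short <- target_total - sum(n_train)
  if (short > 0) {
    bump <- order(remainder, decreasing = TRUE)[seq_len(short)]
    n_train[bump] <- n_train[bump] + 1L
  }
  names(n_train) <- names(counts)
  train_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(cls) {
      idx <- which(y == as.numeric(cls))
      sample(idx, n_train[[cls]])
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  structure(
    list(train_indices = train_idx,
         test_indices = setdiff(seq_len(nrow(cohort)), train_idx),
         fraction = fraction, seed = as.integer(seed)),
    class = "daplex_split"
  )
}

#' Fit the feature-transformation specification on training data
#'
#' Learns, from training rows only: z-score parameters (mean and sample SD)
#' for every continuous predictor, and the ordered category list for every
#' categorical or binary predictor (one-hot encoded with the full indicator
#' set, no reference-level drop). A continuous feature with zero training
#' variance is scaled by 1 and flagged rather than dropped, keeping the
#' column layout stable.
#'
#' @param train training-rows data.frame (predictors plus optional
#'   `patient_id`/`diagnosis` columns, which are ignored as features).
#' @return object of class `"daplex_transform"` with per-variable parameters,
#'   the emitted column layout and `feature_group_map` (emitted column ->
#'   source clinical variable).
#' @export
fit_transform_spec <- function(train) {
  vars <- setdiff(names(train), c("patient_id", "diagnosis"))
  if (!length(vars) || !nrow(train)) stop_daplex("empty training table")
  spec <- list()
  columns <- character(0)
  group <- character(0)
  flagged <- character(0)
  for (nm in vars) {
    x <- train[[nm]]
    if (is.numeric(x) && !is_binary01(x)) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) {
        s <- 1
        flagged <- c(flagged, nm)
      }
      spec[[nm]] <- list(type = "continuous", mean = mean(x), sd = s)
      columns <- c(columns, nm)
      group <- c(group, nm)
    } else {
      lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      spec[[nm]] <- list(type = "categorical", levels = lev)
      cols <- paste0(nm, "=", lev)
      columns <- c(columns, cols)
      group <- c(group, rep(nm, length(lev)))
    }
  }
  structure(
    list(variables = spec, columns = columns,
         feature_group_map = stats::setNames(group, columns),
         zero_variance = flagged),
    class = "daplex_transform"
  )
}

#' Apply a fitted transformation to a cohort table
#'
#' Emits the numeric feature matrix with exactly the column layout learned at
#' fit time. Continuous features are z-scored with the stored training
#' parameters; categorical features become 0/1 indicators over the stored
#' training levels, with categories unseen in training mapping to an all-zero
#' indicator block.
#'
#' @param spec a `"daplex_transform"` from [fit_transform_spec()].
#' @param table data.frame containing all source variables.
#' @return list of class `"daplex_features"`: `x` (numeric matrix, rows
#'   aligned with `table`), `y` (0/1 labels if a `diagnosis` column exists,
#'   else `NULL`), and `feature_group` (column -> source variable).
#' @export
apply_transform <- function(spec, table) {
  stopifnot(inherits(spec, "daplex_transform"))
  missing_vars <- setdiff(names(spec$variables), names(table))
  if (length(missing_vars)) {
    stop_daplex("table lacks source variable(s): %s",
                paste(missing_vars, collapse = ", "))
  }
  n <- nrow(table)
  x <- matrix(0, nrow = n, ncol = length(spec$columns),
              dimnames = list(NULL, spec$columns))
  for (nm in names(spec$variables)) {
    v <- spec$variables[[nm]]
    col <- table[[nm]]
    if (v$type == "continuous") {
      if (!is.numeric(col)) stop_daplex("variable '%s' must be numeric", nm)
      x[, nm] <- (col - v$mean) / v$sd
    } else {
      chr <- as.character(col)
      for (lev in v$levels) {
        x[, paste0(nm, "=", lev)] <- as.numeric(chr == lev)
      }
    }
  }
  structure(
    list(x = x,
         y = if ("diagnosis" %in% names(table)) as.integer(table$diagnosis) else NULL,
         feature_group = spec$feature_group_map),
    class = "daplex_features"
  )
}

#' Serialize a transformation spec to JSON for audit
#' @param spec a `"daplex_transform"`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_transform_spec <- function(spec, path) {
  jsonlite::write_json(
    list(variables = spec$variables, columns = spec$columns,
         feature_group_map = as.list(spec$feature_group_map),
         zero_variance = spec$zero_variance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
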