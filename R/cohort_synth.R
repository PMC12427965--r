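# Synthetic cohort generation for the pediatric LRTI (pneumonia vs acute
# bronchitis) diagnostic task, plus the univariate baseline comparison.

DOMAINS <- c("demographic", "symptom", "exam", "laboratory", "radiology")
VAR_TYPES <- c("continuous", "binary", "categorical")

#' Describe one predictor variable of a synthetic cohort
#'
#' A `variable_spec` carries the per-class marginal distribution of a single
#' predictor: mean/SD per class for continuous variables (optionally
#' log-normal for skewed, non-negative quantities), an event probability per
#' class for binary variables, and a category probability vector per class
#' for categorical variables. Class 1 is pneumonia, class 0 acute bronchitis.
#'
#' @param name variable name (unique within a config).
#' @param domain clinical domain, one of `"demographic"`, `"symptom"`,
#'   `"exam"`, `"laboratory"`, `"radiology"`. Variables within a domain share
#'   latent correlation when the config requests it.
#' @param type `"continuous"`, `"binary"` or `"categorical"`.
#' @param mean,sd numeric length-2 vectors `c(class1, class0)` (continuous
#'   only); `sd` must be strictly positive.
#' @param prob for binary: length-2 event probability `c(class1, class0)`;
#'   for categorical: a matrix with one row per level (rownames = level
#'   labels) and columns `c(class1, class0)`, each column summing to 1.
#' @param dist `"normal"` or `"lognormal"` (continuous only). Log-normal
#'   draws match the requested mean and SD by moment matching.
#' @return an object of class `"daplex_variable_spec"`.
#' @export
variable_spec <- function(name, domain, type, mean = NULL, sd = NULL,
                          prob = NULL, dist = "normal") {
  domain <- match.arg(domain, DOMAINS)
  type <- match.arg(type, VAR_TYPES)
  dist <- match.arg(dist, c("normal", "lognormal"))
  if (type == "continuous") {
    if (length(mean) != 2L || length(sd) != 2L) {
      stop_daplex("variable '%s': continuous spec needs mean and sd of length 2", name)
    }
    if (any(sd <= 0)) {
      stop_daplex("variable '%s': standard deviations must be > 0", name)
    }
    if (dist == "lognormal" && any(mean <= 0)) {
      stop_daplex("variable '%s': log-normal mean must be > 0", name)
    }
  } else if (type == "binary") {
    if (length(prob) != 2L || any(prob < 0) || any(prob > 1)) {
      stop_daplex("variable '%s': binary spec needs two event probabilities in [0,1]", name)
    }
  } else {
    if (!is.matrix(prob) || ncol(prob) != 2L || is.null(rownames(prob))) {
      stop_daplex("variable '%s': categorical spec needs a levels x 2 probability matrix with rownames", name)
    }
    if (any(prob < 0) || any(abs(colSums(prob) - 1) > 1e-9)) {
      stop_daplex("variable '%s': categorical probabilities must be >= 0 and sum to 1 per class", name)
    }
  }
  structure(
    list(name = name, domain = domain, type = type,
         mean = unname(mean), sd = unname(sd), prob = prob, dist = dist),
    class = "daplex_variable_spec"
  )
}

#' Assemble a synthetic cohort configuration
#'
#' @param n_patients cohort size (>= 10).
#' @param prevalence fraction of class-1 (pneumonia) patients, in (0, 1).
#' @param variables list of [variable_spec()] objects with unique names.
#' @param latent_correlation within-domain correlation of the latent Gaussian
#'   copula in `[0, 1)`; 0 gives independent marginals.
#' @param seed default seed used by [generate_cohort()] when none is given.
#' @return an object of class `"daplex_cohort_config"`.
#' @export
cohort_config <- function(n_patients, prevalence, variables,
                          latent_correlation = 0, seed = 1L) {
  if (n_patients < 10) stop_daplex("n_patients must be >= 10")
  if (prevalence <= 0 || prevalence >= 1) stop_daplex("prevalence must be in (0, 1)")
  nm <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nm)) stop_daplex("variable names must be unique")
  if (latent_correlation < 0 || latent_correlation >= 1) {
    stop_daplex("latent_correlation must be in [0, 1)")
  }
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         variables = stats::setNames(variables, nm),
         latent_correlation = latent_correlation, seed = as.integer(seed)),
    class = "daplex_cohort_config"
  )
}

# Printed group dispersions are standard errors of the mean; convert to SDs
# with the group sizes (474 pneumonia, 394 bronchitis).
sem_to_sd <- function(sem, n = c(474, 394)) sem * sqrt(n)

#' Default synthetic pediatric LRTI cohort configuration
#'
#' Encodes the study population the package emulates: 868 children, 54.6%
#' pneumonia, and 28 predictors over five clinical domains. Group-wise
#' summaries known for the population (age, CRP, fever, myalgia, crackles,
#' rhonchus, prolonged expiration, hyperpnea, radiological findings) are
#' encoded exactly; printed +/- dispersions are interpreted as standard
#' errors of the mean and converted to SDs using the group sizes (474, 394).
#' The remaining predictors, needed to reach the 28-variable panel, are
#' weakly informative symptom/laboratory variables with clinically plausible
#' rates, documented in the methods vignette. Skewed, non-negative
#' quantities (age in months, CRP, ESR, procalcitonin) are log-normal with
#' matched mean/SD.
#'
#' @param latent_correlation within-domain latent copula correlation
#'   (default 0.3, giving realistic predictor redundancy).
#' @return a `"daplex_cohort_config"` with `n_patients = 868`,
#'   `prevalence = 0.546` and 28 variable specs.
#' @export
default_lrti_config <- function(latent_correlation = 0.3) {
  v <- list(
    # demographics -----------------------------------------------------
    variable_spec("age_months", "demographic", "continuous",
                  mean = c(53.2, 35.9), sd = sem_to_sd(c(2.4, 2.0)),
                  dist = "lognormal"),
    variable_spec("sex_male", "demographic", "binary", prob = c(0.55, 0.53)),
    # presenting symptoms ----------------------------------------------
    variable_spec("fever", "symptom", "binary", prob = c(0.772, 0.381)),
    variable_spec("cough", "symptom", "binary", prob = c(0.93, 0.95)),
    variable_spec("myalgia", "symptom", "binary", prob = c(0.224, 0.165)),
    variable_spec("fatigue", "symptom", "binary", prob = c(0.42, 0.38)),
    variable_spec("chest_pain", "symptom", "binary", prob = c(0.18, 0.07)),
    variable_spec("vomiting", "symptom", "binary", prob = c(0.22, 0.19)),
    variable_spec("loss_of_appetite", "symptom", "binary", prob = c(0.48, 0.41)),
    # physical examination ----------------------------------------------
    variable_spec("crackles", "exam", "binary", prob = c(0.914, 0.178)),
    variable_spec("rhonchus", "exam", "binary", prob = c(0.186, 0.987)),
    variable_spec("prolonged_expiration", "exam", "binary", prob = c(0.148, 0.967)),
    variable_spec("hyperpnea", "exam", "binary", prob = c(0.652, 0.858)),
    variable_spec("respiratory_distress", "exam", "binary", prob = c(0.25, 0.45)),
    variable_spec("tachypnea", "exam", "binary", prob = c(0.40, 0.62)),
    variable_spec("tachycardia", "exam", "binary", prob = c(0.35, 0.55)),
    variable_spec("nasal_flaring", "exam", "binary", prob = c(0.15, 0.33)),
    variable_spec("intercostal_retractions", "exam", "binary", prob = c(0.20, 0.42)),
    variable_spec("cyanosis", "exam", "binary", prob = c(0.06, 0.10)),
    # laboratory ---------------------------------------------------------
    variable_spec("crp_mg_l", "laboratory", "continuous",
                  mean = c(40.4, 14.2), sd = sem_to_sd(c(3.1, 1.1)),
                  dist = "lognormal"),
    variable_spec("wbc_10e9_l", "laboratory", "continuous",
                  mean = c(14.8, 11.2), sd = c(6.0, 4.5)),
    variable_spec("neutrophil_pct", "laboratory", "continuous",
                  mean = c(62, 48), sd = c(14, 15)),
    variable_spec("lymphocyte_pct", "laboratory", "continuous",
                  mean = c(28, 42), sd = c(12, 15)),
    variable_spec("hemoglobin_g_dl", "laboratory", "continuous",
                  mean = c(11.8, 12.0), sd = c(1.4, 1.3)),
    variable_spec("platelets_10e9_l", "laboratory", "continuous",
                  mean = c(340, 320), sd = c(110, 100)),
    variable_spec("esr_mm_h", "laboratory", "continuous",
                  mean = c(32, 18), sd = c(18, 12), dist = "lognormal"),
    variable_spec("procalcitonin_ng_ml", "laboratory", "continuous",
                  mean = c(1.8, 0.4), sd = c(3.5, 0.9), dist = "lognormal"),
    # radiology ----------------------------------------------------------
    variable_spec("radiological_finding", "radiology", "categorical",
                  prob = matrix(c(0.857, 0.127, 0.016,
                                  0.008, 0.921, 0.071), ncol = 2,
                                dimnames = list(c("infiltration",
                                                  "increased_aeration_bronchogram",
                                                  "normal"), NULL)))
  )
  cohort_config(868L, 0.546, v, latent_correlation = latent_correlation)
}

# Draw the latent Gaussian block for one class: variables within a clinical
# domain share an equicorrelated latent factor (rho), domains are independent.
latent_gaussian <- function(n, specs, rho) {
  z <- matrix(stats::rnorm(n * length(specs)), nrow = n)
  colnames(z) <- names(specs)
  if (rho > 0) {
    domains <- vapply(specs, function(v) v$domain, character(1))
    for (d in unique(domains)) {
      cols <- which(domains == d)
      if (length(cols) > 1) {
        shared <- stats::rnorm(n)
        z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
      }
    }
  }
  z
}

marginal_from_latent <- function(z, spec, class_col) {
  if (spec$type == "continuous") {
    m <- spec$mean[class_col]
    s <- spec$sd[class_col]
    if (spec$dist == "lognormal") {
      sigma2 <- log(1 + (s / m)^2)
      mu <- log(m) - sigma2 / 2
      exp(mu + sqrt(sigma2) * z)
    } else {
      m + s * z
    }
  } else if (spec$type == "binary") {
    as.integer(z < stats::qnorm(spec$prob[class_col]))
  } else {
    cum <- cumsum(spec$prob[, class_col])
    lev <- rownames(spec$prob)
    idx <- pmin(findInterval(stats::pnorm(z), cum, left.open = TRUE) + 1L,
                length(lev))
    factor(lev[idx], levels = lev)
  }
}

#' Generate a synthetic cohort table
#'
#' Draws `n_patients` rows from the per-class marginals of the configuration
#' through a latent Gaussian copula (equicorrelated within clinical domains
#' when `latent_correlation > 0`). Class counts are the rounding of
#' `n_patients * prevalence`. Deterministic: identical `(config, seed)` give
#' identical tables.
#'
#' @param config a `"daplex_cohort_config"`.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a data.frame with `patient_id`, `diagnosis` (1 = pneumonia) and
#'   one column per configured predictor; no missing values.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "daplex_cohort_config"))
  n1 <- as.integer(round(config$n_patients * config$prevalence))
  n0 <- config$n_patients - n1
  specs <- config$variables
  with_seed(seed, {
    blocks <- lapply(c(1L, 2L), function(class_col) {
      n <- if (class_col == 1L) n1 else n0
      z <- latent_gaussian(n, specs, config$latent_correlation)
      cols <- lapply(names(specs), function(nm) {
        marginal_from_latent(z[, nm], specs[[nm]], class_col)
      })
      names(cols) <- names(specs)
      df <- as.data.frame(cols, stringsAsFactors = FALSE)
      df$diagnosis <- if (class_col == 1L) 1L else 0L
      df
    })
    out <- rbind(blocks[[1]], blocks[[2]])
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    cbind(patient_id = sprintf("P%04d", seq_len(nrow(out))),
          out[c("diagnosis", names(specs))])
  })
}

#' Univariate baseline comparison between diagnostic groups
#'
#' Compares every predictor between the class-1 (pneumonia) and class-0
#' (acute bronchitis) groups: Welch's t-test (unpooled variances,
#' Welch-Satterthwaite degrees of freedom) for continuous variables and
#' Pearson's chi-square test without continuity correction for binary and
#' categorical variables.
#'
#' @param cohort a cohort data.frame with a 0/1 `diagnosis` column.
#' @return data.frame with one row per predictor: `variable`, `test`,
#'   `statistic`, `df`, `p_value`, group summaries (`summary_class1`,
#'   `summary_class0`, mean +/- SD or n (%)), and a `flag` column marking
#'   rows whose statistic is undefined (e.g. zero variance in both groups).
#' @export
baseline_compare <- function(cohort) {
  if (!"diagnosis" %in% names(cohort)) stop_daplex("cohort lacks a 'diagnosis' column")
  g <- cohort$diagnosis
  if (length(unique(g)) != 2L) stop_daplex("both diagnostic classes must be present")
  vars <- setdiff(names(cohort), c("patient_id", "diagnosis"))
  rows <- lapply(vars, function(nm) {
    x <- cohort[[nm]]
    continuous <- is.numeric(x) && !is_binary01(x)
    if (continuous) {
      x1 <- x[g == 1]; x0 <- x[g == 0]
      s1 <- sprintf("%.1f ± %.1f", mean(x1), stats::sd(x1))
      s0 <- sprintf("%.1f ± %.1f", mean(x0), stats::sd(x0))
      if (stats::sd(x1) == 0 && stats::sd(x0) == 0) {
        return(data.frame(variable = nm, test = "welch_t", statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          summary_class1 = s1, summary_class0 = s0,
                          flag = "zero_variance", stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(x1, x0, var.equal = FALSE)
      data.frame(variable = nm, test = "welch_t",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, summary_class1 = s1, summary_class0 = s0,
                 flag = "", stringsAsFactors = FALSE)
    } else {
      xf <- if (is_binary01(x)) factor(x, levels = c(0, 1)) else factor(x)
      tab <- table(xf, g)
      n1 <- sum(g == 1); n0 <- sum(g == 0)
      ev <- if (is_binary01(x)) {
        c(sum(x[g == 1]), sum(x[g == 0]))
      } else {
        c(tab[1, "1"], tab[1, "0"])
      }
      s1 <- sprintf("%d (%.1f%%)", ev[1], 100 * ev[1] / n1)
      s0 <- sprintf("%d (%.1f%%)", ev[2], 100 * ev[2] / n0)
      if (nrow(tab) < 2L) {
        return(data.frame(variable = nm, test = "chi_square", statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          summary_class1 = s1, summary_class0 = s0,
                          flag = "degenerate_table", stringsAsFactors = FALSE))
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = nm, test = "chi_square",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, summary_class1 = s1, summary_class0 = s0,
                 flag = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Serialize / parse a cohort configuration
#'
#' Round-trippable YAML (or JSON via file extension) representation of a
#' [cohort_config()], so study conditions can be audited and edited outside R.
#' @param config a `"daplex_cohort_config"`.
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns the parsed config.
#' @export
write_cohort_config <- function(config, path) {
  rep <- list(
    n_patients = config$n_patients,
    prevalence = config$prevalence,
    latent_correlation = config$latent_correlation,
    seed = config$seed,
    variables = lapply(unname(config$variables), function(v) {
      out <- list(name = v$name, domain = v$domain, type = v$type)
      if (v$type == "continuous") {
        out$mean <- v$mean; out$sd <- v$sd; out$dist <- v$dist
      } else if (v$type == "binary") {
        out$prob <- v$prob
      } else {
        out$levels <- rownames(v$prob)
        out$prob_class1 <- unname(v$prob[, 1])
        out$prob_class0 <- unname(v$prob[, 2])
      }
      out
    })
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rep, path)
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  rep <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  vars <- lapply(rep$variables, function(v) {
    if (v$type == "continuous") {
      variable_spec(v$name, v$domain, "continuous", mean = unlist(v$mean),
                    sd = unlist(v$sd), dist = v$dist %||% "normal")
    } else if (v$type == "binary") {
      variable_spec(v$name, v$domain, "binary", prob = unlist(v$prob))
    } else {
      variable_spec(v$name, v$domain, "categorical",
                    prob = matrix(c(unlist(v$prob_class1), unlist(v$prob_class0)),
                                  ncol = 2,
                                  dimnames = list(unlist(v$levels), NULL)))
    }
  })
  cohort_config(rep$n_patients, rep$prevalence, vars,
                latent_correlation = rep$latent_correlation %||% 0,
                seed = rep$seed %||% 1L)
}
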