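# Synthetic cohort generator: configuration encoding, determinism, marginal
# fidelity, and the univariate baseline-comparison statistics.

test_that("default config encodes the study population", {
  cfg <- default_lrti_config()
  expect_s3_class(cfg, "daplex_cohort_config")
  expect_equal(cfg$n_patients, 868L)
  expect_equal(cfg$prevalence, 0.546)
  expect_length(cfg$variables, 28L)
  # event probabilities per class for hallmark auscultatory signs
  expect_equal(cfg$variables$crackles$prob, c(0.914, 0.178))
  expect_equal(cfg$variables$rhonchus$prob, c(0.186, 0.987))
  expect_equal(cfg$variables$prolonged_expiration$prob, c(0.148, 0.967))
  expect_equal(cfg$variables$fever$prob, c(0.772, 0.381))
  # printed +/- values are SEMs: SD = SEM * sqrt(group n)
  expect_equal(cfg$variables$age_months$mean, c(53.2, 35.9))
  expect_equal(cfg$variables$age_months$sd, c(2.4 * sqrt(474), 2.0 * sqrt(394)))
  expect_equal(cfg$variables$crp_mg_l$sd, c(3.1 * sqrt(474), 1.1 * sqrt(394)))
  # five clinical domains are all represented
  domains <- vapply(cfg$variables, function(v) v$domain, character(1))
  expect_setequal(unique(domains),
                  c("demographic", "symptom", "exam", "laboratory", "radiology"))
})

test_that("config serialization round-trips through YAML and JSON", {
  cfg <- default_lrti_config()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort_config(cfg, path)
    back <- read_cohort_config(path)
    expect_equal(back, cfg)
  }
})

test_that("invalid variable specs are rejected with the offending name", {
  expect_error(variable_spec("crp", "laboratory", "continuous",
                             mean = c(40, 14), sd = c(0, 2)),
               "crp")
  expect_error(variable_spec("fever", "symptom", "binary", prob = c(1.2, 0.4)),
               "fever")
  expect_error(variable_spec("rad", "radiology", "categorical",
                             prob = matrix(c(0.6, 0.6, 0.5, 0.5), 2,
                                           dimnames = list(c("a", "b"), NULL))),
               "rad")
})

test_that("generate_cohort is deterministic with exact class counts", {
  cfg <- default_lrti_config()
  co1 <- generate_cohort(cfg, seed = 7)
  co2 <- generate_cohort(cfg, seed = 7)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 868L)
  expect_equal(sum(co1$diagnosis == 1), 474L)
  expect_false(anyNA(co1))
  expect_false(identical(co1, generate_cohort(cfg, seed = 8)))
})

test_that("marginals are recovered at large n", {
  cfg <- default_lrti_config()
  cfg$n_patients <- 50000L
  co <- generate_cohort(cfg, seed = 11)
  pos <- co$diagnosis == 1
  # continuous means within 2% of spec
  expect_lt(abs(mean(co$crp_mg_l[pos]) - 40.4) / 40.4, 0.02)
  expect_lt(abs(mean(co$crp_mg_l[!pos]) - 14.2) / 14.2, 0.02)
  expect_lt(abs(mean(co$age_months[pos]) - 53.2) / 53.2, 0.02)
  # binary rates within +/- 0.01
  expect_lt(abs(mean(co$crackles[pos]) - 0.914), 0.01)
  expect_lt(abs(mean(co$rhonchus[!pos]) - 0.987), 0.01)
  expect_lt(abs(mean(co$fever[pos]) - 0.772), 0.01)
  # categorical level rates within +/- 0.01
  expect_lt(abs(mean(co$radiological_finding[pos] == "infiltration") - 0.857), 0.01)
  expect_lt(abs(mean(co$radiological_finding[!pos] == "increased_aeration_bronchogram") - 0.921), 0.01)
  # non-negative skewed laboratory values
  expect_true(all(co$crp_mg_l > 0))
  expect_true(all(co$age_months > 0))
})

test_that("latent correlation induces within-domain association", {
  cfg <- default_lrti_config(latent_correlation = 0.5)
  co <- generate_cohort(cfg, seed = 3)
  pos <- co$diagnosis == 1
  r_within <- cor(co$wbc_10e9_l[pos], co$neutrophil_pct[pos])
  expect_gt(r_within, 0.2)
  cfg0 <- default_lrti_config(latent_correlation = 0)
  co0 <- generate_cohort(cfg0, seed = 3)
  expect_lt(abs(cor(co0$wbc_10e9_l[co0$diagnosis == 1],
                    co0$neutrophil_pct[co0$diagnosis == 1])), 0.15)
})

test_that("baseline_compare matches textbook Welch and Pearson formulas", {
  co <- generate_cohort(default_lrti_config(), seed = 5)
  bc <- baseline_compare(co)
  expect_equal(nrow(bc), 28L)
  expect_true(all(bc$test[bc$variable %in% c("age_months", "crp_mg_l")] == "welch_t"))
  expect_true(all(bc$test[bc$variable %in% c("fever", "radiological_finding")] == "chi_square"))

  # Welch oracle: t = (m1 - m0) / sqrt(s1^2/n1 + s0^2/n0)
  x1 <- co$crp_mg_l[co$diagnosis == 1]
  x0 <- co$crp_mg_l[co$diagnosis == 0]
  se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
  t_oracle <- (mean(x1) - mean(x0)) / se
  df_oracle <- se^4 / ((var(x1) / length(x1))^2 / (length(x1) - 1) +
                       (var(x0) / length(x0))^2 / (length(x0) - 1))
  expect_near(bc$statistic[bc$variable == "crp_mg_l"], t_oracle)
  expect_near(bc$df[bc$variable == "crp_mg_l"], df_oracle)

  # Pearson oracle: sum (O - E)^2 / E over the 2x2 table, no correction
  tab <- table(co$fever, co$diagnosis)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_oracle <- sum((tab - expected)^2 / expected)
  expect_near(bc$statistic[bc$variable == "fever"], chi_oracle)
})

test_that("identical samples give Welch t = 0 and null cohorts reject at ~5%", {
  co <- data.frame(diagnosis = c(1L, 1L, 1L, 0L, 0L, 0L),
                   v = c(1, 2, 3, 1, 2, 3))
  bc <- baseline_compare(co)
  expect_near(bc$statistic, 0)

  # both classes drawn from identical marginals: no systematic rejection
  cfg <- cohort_config(4000L, 0.5, list(
    variable_spec(paste0("v"), "laboratory", "continuous",
                  mean = c(10, 10), sd = c(2, 2)),
    variable_spec("b", "symptom", "binary", prob = c(0.4, 0.4))
  ))
  reject <- vapply(1:40, function(s) {
    bc <- baseline_compare(generate_cohort(cfg, seed = s))
    mean(bc$p_value < 0.05)
  }, numeric(1))
  expect_lt(mean(reject), 0.15)
})

test_that("zero-variance continuous variables are flagged, not crashed on", {
  co <- data.frame(diagnosis = rep(c(1L, 0L), each = 5),
                   flat = rep(2.5, 10), ok = rnorm(10))
  bc <- baseline_compare(co)
  expect_equal(bc$flag[bc$variable == "flat"], "zero_variance")
  expect_true(is.na(bc$statistic[bc$variable == "flat"]))
  expect_equal(bc$flag[bc$variable == "ok"], "")
})
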