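# Fixtures built in code: small cohorts and well-separated classification
# problems used across the suite.

# Two well-separated Gaussian classes: any sensible margin learner reaches
# validation BA 1 on this. Class means are orthogonal (not antipodal) so
# homogeneous even-degree polynomial kernels can also separate them.
separable_cohort <- function(n = 120, seed = 1) {
  daplex:::with_seed(seed, {
    n1 <- n %/% 2
    n0 <- n - n1
    data.frame(
      diagnosis = c(rep(1L, n1), rep(0L, n0)),
      f1 = c(rnorm(n1, 5), rnorm(n0, 0)),
      f2 = c(rnorm(n1, 0), rnorm(n0, 5))
    )
  })
}

# Default LRTI cohort with a fraction of labels flipped: the overfitting /
# leakage canary for the stability-gap and OOF diagnostics.
noisy_cohort <- function(noise = 0.3, seed = 1, config = default_lrti_config()) {
  co <- generate_cohort(config, seed = seed)
  daplex:::with_seed(seed + 7919, {
    flip <- sample(nrow(co), round(noise * nrow(co)))
    co$diagnosis[flip] <- 1L - co$diagnosis[flip]
  })
  co
}

# A tiny pool that tunes in well under a second, for plumbing tests.
tiny_pool <- function() {
  list(
    KNN = base_learner_spec("KNN", list(k = c(1L, 5L), weights = "uniform")),
    GNB = base_learner_spec("GNB", list(var_smoothing = 1e-9))
  )
}

# Memorizing learner: 1-NN (predicting a training row finds itself).
memorizer_spec <- function() {
  base_learner_spec("KNN", list(k = 1L, weights = "uniform"))
}

expect_near <- function(object, expected, tol = 1e-10) {
  expect_equal(object, expected, tolerance = tol)
}
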