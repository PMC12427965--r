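Package: daplex
Title: Stability-Pruned Knowledge-Fusion Stacking for Pediatric Respiratory Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-phase ensemble framework for binary diagnostic
    classification on tabular clinical data, applied to differentiating
    pediatric pneumonia from acute bronchitis. Phase I deploys a heterogeneous
    pool of six base learners tuned by balanced-accuracy-optimized 5-fold
    cross-validated grid search; Phase II prunes learners whose
    train-validation stability gap in balanced accuracy exceeds a threshold;
    Phase III quantifies complementarity (Friedman rank test, pairwise
    Jensen-Shannon divergence), aggregates grouped permutation importance
    across learners by Borda count, and fuses out-of-fold probabilities with
    the consensus features into a multilayer-perceptron meta-learner. Includes
    a synthetic cohort generator emulating a pediatric lower-respiratory-tract
    infection population, leakage-free preprocessing, holdout benchmarking
    with relative-improvement summaries, and demographic subgroup analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
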