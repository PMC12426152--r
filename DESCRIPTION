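Package: bitterling
Title: Swarm-Intelligence Feature Selection and Hyperparameter Tuning for
    Clinical Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the bitterling fish optimizer (BFO) and an improved
    variant (IBFO) with sine-chaotic initialization and Gaussian random-walk
    mutation, together with a hybrid binary-real chromosome that selects
    features and tunes classifier hyperparameters simultaneously. Ships the
    classic 23-function optimizer benchmark suite, a preprocessing pipeline
    (Tukey outlier screening, quantile winsorization, z-scoring, categorical
    encoding), LASSO lambda-1SE feature selection, four base learners
    (logistic regression, RBF support vector machine, single-hidden-layer
    backpropagation network, gradient-boosted trees) behind one fit/predict
    contract, exact and permutation-sampled Shapley attributions, and a
    seeded synthetic postoperative-recovery cohort generator so the whole
    pipeline is testable without patient data. A command-line interface
    exposes simulation, preprocessing, selection, optimization, evaluation,
    explanation, benchmarking, and a seven-feature prediction endpoint.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
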