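Package: svmtune
Title: Comparison of Hyperparameter Search Strategies for RBF-Kernel SVM
    Classification of Bioactive Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking strategies that select the regularization
    strength C and kernel width gamma of a radial-basis-function support
    vector machine used to classify bioactive compounds from binary
    molecular fingerprints.  Implements two fixed heuristics (the libSVM and
    SVMlight defaults), log-scale grid search with column raveling, a
    budget-constrained "small grid" variant, log-uniform random search, and
    Gaussian-process Bayesian optimization with the expected-improvement
    acquisition, all under a common trace-producing contract.  Includes a
    seeded generator of sparse binary fingerprint datasets with controllable
    class overlap and imbalance, cross-validated accuracy objectives,
    analytic benchmark surfaces with known optima, and evaluation utilities
    (best-so-far curves, normalized curve AUC, win counting with draws,
    simple regret) for comparing optimizer anytime performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
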