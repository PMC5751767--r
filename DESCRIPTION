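Package: lnside
Title: Drug Side-Effect Prediction via Linear Neighborhood Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug side effects by computing linear neighborhood
    similarity between drugs (per-drug constrained quadratic programs that
    reconstruct each drug from its nearest neighbors), propagating known
    side-effect labels over the resulting similarity graph, and integrating
    multiple binary feature views with analytically estimated simplex
    weights. Covers both prediction of side effects for new drugs (LNSM and
    LNSM-SMI) and recovery of missing side effects for approved drugs from
    their association profiles (LNSM-MSE), together with multi-label and
    binary evaluation metrics, the two matching cross-validation protocols,
    a cluster-structured synthetic data generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
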