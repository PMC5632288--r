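Package: bmanet
Title: Gene Regulatory Network Inference by Bayesian Model Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers weighted directed gene regulatory networks from
    time-series (or steady-state) expression data by Bayesian model
    averaging over linear regression models. Models are scored with a
    Zellner g-prior marginal likelihood, searched with an Occam's-window
    scan that expands the current best models by single-variable additions
    and removals, fitted incrementally by rank-one Cholesky updates,
    and de-duplicated with a constant-space XOR-updatable bit filter.
    Edge weights are posterior inclusion probabilities. Post-processing
    removes direct edges dominated by higher-probability indirect paths
    via bounded shortest-path search, and inferred networks are scored
    against gold standards with threshold-swept precision-recall and ROC
    curves. A synthetic VAR(1) generator provides ground-truth fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
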