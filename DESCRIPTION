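Package: hierpc
Title: Hierarchical Predictive-Coding Analysis of Local-Global Oddball ERSP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hierarchical predictive coding in the
    local-global auditory oddball paradigm. Implements a two-stream,
    three-level quantitative model with scaling factors for sensory
    adaptation and first- and second-level prediction strength, fixed-mode
    PARAFAC decomposition of deviant event-related spectral perturbation
    (ERSP) responses into local (PE1) and global (PE2) prediction-error
    components, cluster-based permutation statistics, single-trial
    projection variability, and a consistency-threshold sensitivity
    analysis. Includes a synthetic-data generator with known ground truth
    for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
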