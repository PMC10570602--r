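Package: lassonetrnn
Title: Hierarchical Sparse Feature Selection for Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Panel", "Methods", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature selection for multivariate time-series classification
    with a LassoNet-style architecture in which a per-variable linear skip
    connection gates, through a hierarchical l-infinity constraint, whether
    that variable may feed a recurrent neural network. Implements the exact
    hierarchical proximal operator, the dense-to-sparse regularization path
    whose per-variable exit lambda yields an importance ranking, readers for
    long/wide CSV and sktime-style .ts panels, CESD-10 depression-scale
    scoring, classification metrics, Pearson chi-square association tests,
    and a synthetic survey-panel generator with planted static and temporal
    effects for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
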