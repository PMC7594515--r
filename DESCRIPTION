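Package: pminr
Title: Pointwise Mutual Information Network Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network regression for case-control studies of biological
    networks. Each edge of a known pathway topology is converted into a
    per-individual pointwise mutual information (PMI) feature using
    bivariate kernel density estimation, and a logistic model relates the
    binary outcome to covariates, node levels, and edge PMI features.
    Per-term Wald tests identify outcome-associated nodes and edges, and a
    global likelihood-ratio test assesses whole-network association. A
    product-moment variant using standardized node cross-products is
    included as the linear-correlation baseline, together with a
    Monte-Carlo harness for type-I error and power evaluation under
    linear and nonlinear inter-node dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
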