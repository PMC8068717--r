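Package: smrmap
Title: Bayesian Small-Area Mapping of Standardized Mortality Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-area disease-mapping pipeline for standardized mortality
    ratios (SMRs) over an administrative adjacency graph. Computes expected
    event counts by indirect standardization from gender- and age-specific
    reference rates, fits Besag-York-Mollie (BYM) hierarchical Poisson models
    with intrinsic conditional autoregressive (ICAR) structured and
    independent unstructured random effects by Markov chain Monte Carlo, and
    reports smoothed SMRs, residual SMRs, and rate ratios across rurality
    deciles with 95% credible intervals. Includes a synthetic-data generator
    with ground truth for parameter-recovery experiments, readers for
    GAL-dialect neighbor lists and area-level CSV tables, and categorized
    GeoJSON map export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
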