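Package: vsmulti
Title: Multiverse and Distributional Regression Tree Analysis of Visual
    Search Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-level visual search data from
    case-control studies: trial inclusion rules and accuracy scoring,
    variable-importance screening (Boruta shadow features and One Rule),
    a multiverse of quantile, robust and distributional regression fits,
    rank-based ANOVA-type statistics and robust correlations, and
    distributional regression trees that fit Ex-Gaussian or generalized
    beta type 1 distributions at every node and split on score-based
    parameter instability. Includes a synthetic visual-search experiment
    generator for testing the full pipeline without access to raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
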