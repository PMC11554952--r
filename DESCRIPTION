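Package: wtsfs
Title: Ensemble Feature Selection with Weighted Total Scores and Causal Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines several feature-importance methods (Pearson and distance
    correlation, lasso, random-forest permutation importance, stability
    selection) into a single exponential Weighted Total Score (WTS), searches
    the method-weight simplex on a delta-lattice by greedy hill climbing with
    memoized subset evaluation, prunes multicollinear features by iterative
    variance-inflation-factor removal, and analyses the selected features with
    a DirectLiNGAM-style causal ordering followed by recursive path-model
    significance tests. Includes seeded synthetic-data generators and a bundled
    copy of the open 442-patient diabetes benchmark dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    readr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
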