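Package: adagraph
Title: Graph-Based Adaptive Two-Stage Closed Testing for Multiarm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of two-stage adaptive multiarm clinical
    trials with multiple endpoints under strong familywise error rate
    control.  Hierarchical testing priorities are expressed as a weighted
    directed graph whose node-removal updates induce weights for every
    intersection hypothesis of the closed test.  Intersection hypotheses
    are tested with weighted Bonferroni, weighted parametric (Dunnett
    type) or mixed tests depending on which test-statistic correlations
    are known.  Two adaptive two-stage procedures are provided: the
    inverse-normal p-value combination test and the conditional error
    rate (CER/PCER) method with group-sequential error spending.  Both
    support early rejection at an interim analysis, treatment or
    hypothesis selection, sample-size reassessment and re-weighting of
    the testing strategy.  A Monte-Carlo trial simulator estimates
    disjunctive power, conjunctive power and the familywise error rate
    under data-dependent arm-dropping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mvtnorm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
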