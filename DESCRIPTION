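Package: foxsna
Title: Social Network Analysis of Camera-Trap Detections in Territorial Canids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds animal social networks from camera-trap detection records at
    food patches and analyses their structure and temporal stability. Detections
    are grouped into patch visits and noon-to-noon sampling periods under the
    gambit of the group; dyadic association strength is measured with the simple
    ratio index. The package estimates social differentiation and data power by
    beta-binomial maximum likelihood, tests for preferred and avoided
    companionships with Manly/Bejder permutation chains (group swaps and
    within-day association swaps), detects communities by leading-eigenvector
    and average-linkage modularity maximisation with a gregariousness-preserving
    null, computes lagged association and identification rates with exponential
    decay model fitting and QAIC selection, and compares association matrices
    across seasons with Mantel and Dietz-R permutation tests combined by
    Fisher's omnibus method. A synthetic detection generator with planted social
    structure supports calibration and power analysis of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
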