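Package: egotopo
Title: Neighbourhood-Based Topology of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for neighbourhood-based analysis of weighted functional
    connectivity networks in epilepsy-surgery cohorts: disparity-filter
    backbone extraction, node-level centrality metrics (clustering,
    betweenness, clique-count curvature), extended-neighbourhood (ego
    network) topology summarised through clique-complex Betti numbers,
    partition of nodes around a resection area, bootstrap group
    comparisons with Bonferroni correction, and distinguishability-score
    classification of surgical outcome via ROC/AUC with bootstrap
    confidence intervals. Includes a synthetic-cohort generator with
    planted hub effects so the full pipeline can be exercised without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
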