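Package: dfcstates
Title: Dynamic Functional Connectivity Brain States from ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis of
    parcellated BOLD time series: band-pass filtering, windowed Pearson
    correlation with Fisher z transform, Manhattan-distance k-means
    identification of recurring connectivity states with model selection by
    a mixed performance criterion (cluster size x silhouette x Dunn /
    Davies-Bouldin), characterization of states by signed-network Louvain
    modularity and system segregation, fraction-time and dwell-time
    temporal dynamics, and group/correlation statistics. Ships a
    Markov-switching multivariate Gaussian cohort simulator with stored
    ground truth so the full pipeline is testable end to end.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
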