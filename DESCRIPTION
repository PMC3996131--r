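Package: severance
Title: Spatial Network Severance Metrics and Community Cohesion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Link-based spatial network analysis for studying physical
    severance and walkability in road networks, and its association with
    community social cohesion. Computes sixteen localized network metrics
    (radius-limited reach, angular geodesic statistics, convex-hull reach
    including the maximum hull radius HullR, junction counts, and two
    betweenness variants) at multiple walking-scale network radii, aggregates
    link metrics to areal units with boundary buffering, and provides the
    accompanying statistical pipeline: a Bonferroni-corrected correlation
    screen over the metric-by-radius grid, standardized-coefficient OLS
    models, deprivation-tertile stratification, and a network-radius sweep.
    A synthetic-data module generates street networks with controllable
    severance (grids, cul-de-sac estates, linear settlements, loops),
    district partitions, and outcome variables, so the whole pipeline is
    testable without survey or road data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
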