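Package: netcog
Title: Structural Brain Network Associations with General Cognitive Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking structural brain connectomes to a
    latent factor of general cognitive function (g) across multiple cohorts.
    Builds a cross-cohort reference network by consistency thresholding and
    mask intersection, computes weighted graph metrics (mean edge weight,
    global efficiency, clustering, local efficiency), estimates g by
    one-factor confirmatory factor analysis with full-information maximum
    likelihood for missing test scores, fits MIMIC-style structural
    regressions of g on network metrics adjusting for age, sex and site,
    pools cohort effects by random-effects meta-analysis with REML and
    Benjamini-Hochberg false-discovery-rate control, and evaluates edge-wise
    composite prediction of g in hold-out samples. Includes a multi-cohort
    synthetic-data generator emulating the statistical structure the
    analysis assumes, so the whole chain is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    metafor,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    data.table
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
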