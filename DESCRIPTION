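Package: spatipv
Title: Spatially Aware Analysis of Drought Exposure and Survey-Reported
    Intimate-Partner Violence
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying associations between drought exposure and
    binary household-survey outcomes while controlling for spatial
    autocorrelation. Classifies drought from trailing twelve-month rainfall
    percentiles against a site baseline, fits penalized logistic regressions
    with a low-rank thin-plate spline smoother on the sphere, diagnoses
    residual spatial autocorrelation with a memory-bounded Moran's I whose
    spatial weights are computed on the fly in C++, selects the smallest
    spline basis whose residuals pass the Moran test, and reports average
    marginal effects of drought in percentage points with Bonferroni
    correction. Includes a synthetic-data generator for clustered,
    geolocated survey respondents with a spatially correlated latent risk
    field and a gridded monthly rainfall cube, plus simulation studies of
    Type I error under spatial confounding and of effect recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
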