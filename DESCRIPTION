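Package: pollenflow
Title: Zero-Inflated Count Models for Pollen-Mediated Gene Flow and
    Isolation Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing cross-pollination risk between adjacent
    Brassica napus (pollen donor) and Brassica rapa (recipient) plots on a
    small field scale.  Simulates progeny-assay datasets that reproduce the
    design of a multi-year two-site field trial (19 sampling distances,
    384-seed assays, excess zeros, overdispersion), diagnoses excess zeros
    and overdispersion, fits zero-inflated Poisson and negative-binomial
    models whose mean structure is driven by one of eleven named pollen
    dispersal kernels, selects models by fit and prediction criteria
    (RMSE, adjusted R-squared, AIC, BIC, MSPR) on a 70/30 split, and
    derives isolation distances for regulatory cross-pollination
    thresholds (3%, 1%, 0.9%) with a bootstrap conservative estimate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
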