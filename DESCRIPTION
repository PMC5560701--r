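Package: freshmap
Title: Automated Cropland Mapping from Outdated Land Cover Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Updates cropland extent maps from multi-date surface reflectance
    time series using an outdated land cover map as the only label source.
    Implements spectral-temporal feature compositing (median and NDVI-decile
    reflectance), reliable training-pixel harvesting via self-organizing-map
    cluster purity, stratum-specific random forest classification with
    geometric-mean fusion of class memberships, entropy-consistent
    classification confidence (equivalent reference probability),
    confidence-weighted majority filtering, and global plus spatially
    constrained accuracy assessment. Includes a seeded synthetic scene
    generator so the whole pipeline can be exercised without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    stats,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
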