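Package: instarcluster
Title: Density-Based Instar Determination from Larval Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines insect larval instars from head-capsule and mandible
    measurements by density-based OPTICS clustering, with DBSCAN, k-means and
    Gaussian-mixture (BIC-selected) comparators, and validates the resulting
    instar groups with the Brooks-Dyar rule, the Crosby rule, size-frequency
    analysis and log-linear growth regression. Includes a synthetic-data
    generator that reproduces the four-instar geometric-growth structure of a
    published Tuta absoluta measurement table so every stage of the analysis
    is reproducible without raw specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
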