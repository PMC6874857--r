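Package: ecointegrity
Title: Anthropogenic Threat Surfaces and Ecological Integrity of River Networks
Version: 0.1.0
Authors@R: person("Ecointegrity", "Developers", role = c("aut", "cre"),
    email = "maintainers@ecointegrity.invalid")
Description: Builds cumulative anthropogenic threat surfaces from vector
    features (distance-decayed impact magnitudes on a regular grid), computes
    a benthic-macroinvertebrate-based Ecological Integrity Index (EII) for
    river sites from biotic, habitat and physical-chemical components, and
    links the two with all-subsets Gaussian linear model selection under AICc
    with collinearity screening and repeated k-fold cross-validation, at both
    pixel (local) and microbasin (regional) scales. Includes a seeded
    synthetic-landscape generator so the whole pipeline is testable without
    external GIS data, Moran's I spatial autocorrelation testing, zonal
    aggregation to microbasins, and a command-line pipeline driver with
    GeoJSON, ESRI ASCII grid and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
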