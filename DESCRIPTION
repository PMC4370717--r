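Package: farmbird
Title: Farmland Bird Community Responses to Agricultural Intensity and
    Its Spatial Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing breeding-bird point-count surveys along a
    continuous agricultural-intensity gradient. Computes species-level
    habitat specialisation (SSI), trophic (STI) and grassland
    specialisation (SSIg) indices and their abundance-weighted community
    counterparts (CSI, CTI, CSIg); builds the input-cost-per-hectare
    (IC/ha) intensity indicator from farm accounting records and its
    neighbourhood aggregation index over a region contiguity matrix;
    provides Moran's I, distance-class correlograms and permutation
    tests; fits fixed-degree-of-freedom spline regressions and
    intensity-by-aggregation interaction models with backward stepwise
    AIC selection, leave-one-out cross-validation error and residual
    diagnostics; and ships a synthetic survey generator emulating the
    structure of national breeding-bird monitoring data for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    lmtest,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
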