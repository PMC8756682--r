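Package: sbaspatial
Title: Spatial Autocorrelation and Spatial Regression for District Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: District-level spatial analysis of health-indicator coverage,
    built around skilled-birth-attendance mapping: queen and shared-border
    contiguity weights from polygon geometry, global univariate and bivariate
    Moran's I with permutation pseudo p-values, local Moran (LISA) cluster
    classification into hotspots, coldspots and spatial outliers, and
    maximum-likelihood spatial-lag and spatial-error regression with AIC model
    comparison. Includes a synthetic district-lattice generator with known
    spatial parameters so every stage is testable without restricted survey
    microdata, plus GeoJSON, shapefile, CSV and GAL weights input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    foreign,
    jsonlite,
    methods,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
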