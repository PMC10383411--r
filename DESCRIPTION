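Package: sanlodge
Title: Rice Lodging Severity and Soil Available Nitrogen Mapping from
    UAS Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives rice lodging severity from unmanned-aircraft-system
    canopy height models (inclination angle on a six-level 18-degree
    scale), estimates the spatial distribution of soil available
    nitrogen (SAN) from bare-soil multispectral reflectance by
    single-regression screening of a 28-feature band inventory, and
    joins the two on a 1 m mesh to map lodging risk against
    absorbable-nitrogen thresholds. Includes zonal statistics over
    buffer circles and mesh grids, a red-NIR soil-line logistic
    classifier for vegetation-contaminated mixels, and a synthetic
    paddy-field generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
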