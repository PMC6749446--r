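Package: vinemetrics
Title: Grape Bunch Yield Estimation from RGB Images and RGB-D Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for image- and geometry-based vineyard yield estimation.
    Implements the 2-D branch (scale calibration from an in-frame reference
    length, HSV colour-threshold segmentation, calibrated pixel area, and
    total bunch area per vine) and the 3-D branch (mesh cropping, watertight
    reconstruction, divergence-theorem mesh volume, point-cloud colour
    filtering, alpha-complex volume with alpha tuning, and total bunch
    volume per vine) of a proximal-sensing yield pipeline, together with
    repeated k-fold cross-validated linear calibration of mass against area
    or volume and a sensor volume-bias correction. A synthetic-scene
    generator produces grape-bunch images, point clouds, meshes and
    reference tables with known ground truth so every stage can be
    validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
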