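Package: desertvi
Title: Grassland Desertification Assessment from Visible-Band Vegetation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading grassland desertification from nadir RGB
    (visible-light) imagery such as low-altitude UAV scenes. Computes 19
    visible-band vegetation indices (ExG, GLI, CIVE, RGBVI, V-MSAVI and
    others), segments vegetation from soil by Otsu's between-class-variance
    threshold, estimates fractional vegetation coverage (FVC), assigns one of
    five desertification grades from FVC bands, and scores index-based maps
    against an SVM supervised-classification reference using overall accuracy,
    the kappa coefficient and the relative error of FVC. Grade-wise index
    comparison is provided through one-way ANOVA and Duncan's multiple range
    test. A seeded synthetic-scene generator produces grassland scenes with
    ground-truth vegetation masks across all five grades for validation and
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    jpeg,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
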