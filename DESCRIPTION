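Package: grazspec
Title: Grazing-Intensity Classification from UAV Visible and Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for monitoring grassland grazing intensity from fused
    visible (RGB digital-number) and multispectral (green, red, red-edge,
    near-infrared reflectance) observations. Provides a registry of
    conventional and purpose-built spectral indices with chromatic-coordinate
    normalization, class-separability analytics (ANOVA, Tukey multiple
    comparisons, pairwise M-statistic), an automatic incremental feature
    selection algorithm combining random-forest permutation importance with
    Pearson-correlation filtering and cross-validated accuracy gating, SPXY
    (joint X-Y distance) train/test partitioning, grid-searched KNN/SVM/RF
    classifiers with overall-accuracy and Kappa evaluation, and pixel-level
    classification mapping with categorical mode filtering. A synthetic-data
    generator reproduces the statistical structure of a balanced four-level
    grazing trial so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
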