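Package: seedcfa
Title: Seed Phenotype Classification from Color-Filter-Array Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying pepper seed types from
    16-bit color-filter-array (CFA) grayscale images. Covers PGM/PNG raster
    input and output, Otsu segmentation with connected-component seed
    detection and bounding-box cropping, an 18-attribute feature extractor
    (shape, Gabor filter statistics, local binary pattern texture, and
    grey-level co-occurrence matrix descriptors, with the full 20-descriptor
    Haralick-style texture library), isolation-forest outlier cleaning,
    robust median/IQR scaling, five feature-selection schemes, and a
    four-model classification and evaluation stage with grid search,
    confusion matrices, and learning curves. Includes a synthetic CFA seed
    scene generator emulating four seed classes so the whole pipeline is
    testable without a physical acquisition rig.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    class,
    e1071,
    randomForest,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
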