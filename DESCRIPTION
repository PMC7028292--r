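Package: tilescope
Title: Tile-Based Whole-Slide Image Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tile-based map-reduce engine for quantitative analysis of
    whole-slide microscopy images. Provides a pyramidal tiled-image model with
    synthetic-slide generation for testing, ROI/exclusion/inclusion annotation
    algebra, structure-size texture features with linear-SVM pixel
    classification, watershed object segmentation with cross-tile object
    merging and SVM object classification, dual-threshold hysteresis nerve
    fibre tracing with junction-crossing counts, and tile-mask refinement
    (translation-union, re-centring, covering deduplication) with
    object-size-weighted Dice evaluation for segmentation predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    parallel,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
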