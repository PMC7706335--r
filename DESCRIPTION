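Package: mvgc
Title: Multiview Ground-Cover Imaging Traits for Seedling-Stage Wheat Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multiview ground-cover images (per-plot rasters of
    plant-pixel fractions) from many overlapping segmented drone views of a
    field plot, and extracts seedling-stage wheat traits from them: the
    beginning of stem elongation (growth stage GS30) via support-vector
    regression on ground-cover percentiles, plant counts via seeded
    watershed partitioning of plant cover, and shoot (tiller) counts via a
    thermal-time-anchored logistic leaf-area model. Includes growing
    degree-day computation, plot geometry (polygon buffering,
    back-projection of plot corners through a pinhole camera, affine
    resampling to a plot frame), Bayer-aware colour-feature pixel
    segmentation, P-spline spatial correction with generalized
    heritability and relative efficiency of indirect selection, and a
    synthetic-field simulator that provides ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    e1071,
    ranger,
    mgcv,
    lme4,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
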