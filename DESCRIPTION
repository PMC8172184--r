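Package: thermotouch
Title: Touch-Point Detection in Thermal Video Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects surface touch-points in thermal image sequences for
    infection-control surface monitoring. Implements per-frame background
    subtraction, three-class semantic segmentation (background, touch-point,
    human subject) with a from-scratch U-net and a deterministic rule-based
    baseline, multi-frame accumulation of touch labels into a cumulative
    duration map, duration thresholding, effective-region post-processing
    (area filtering, centroid clustering, containment merging), and
    region-level evaluation (precision, F1, FNR, FDR, Dice). Ships a seeded
    synthetic thermal-scene simulator with ground truth so the full pipeline
    can be trained and tested without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
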