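Package: vesselnet
Title: Segmentation, Skeletonization and Network Analysis of 3D Vascular
    Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying vascular networks in
    three-dimensional fluorescence microscopy z-stacks. Raw calibrated
    volumes are preprocessed (optional x/y downscaling, brightness
    windowing, per-slice rolling-ball background subtraction, separable 3D
    Gaussian smoothing), binarized by Yen's automatic threshold with
    morphological postprocessing (slice-wise particle removal, 3D
    closing via maximum/minimum filters, 3D hole filling), reduced to a
    one-voxel-thick centerline by topology-preserving medial-axis
    thinning, and decomposed into a skeleton graph of segments, junctions
    and end points. Seven per-image network measurements, ground-truth
    skeleton-overlap evaluation with dilation tolerance, effect sizes
    (Glass's delta) and exact/approximate two-sided Mann-Whitney U tests
    with Bonferroni correction are provided, together with a synthetic
    vessel-phantom generator with known ground-truth topology so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
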