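Package: dfma
Title: Seedling Phenotyping by Partial-Convolution Semantic Segmentation and
    Skeleton-Based Length Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput phenotyping of germinating seedlings
    from images of germination boards. Implements the DFMA semantic
    segmentation architecture, a DeepLabv3+ derivative built from a
    FasterNet-style partial-convolution backbone, efficient multi-scale
    attention (EMA), a series-parallel atrous pyramid (PSPA-ASPP) with paired
    dilation rates chosen to suppress the gridding effect, and content-aware
    reassembly (CARAFE) upsampling. Includes a self-contained reverse-mode
    autodiff engine with Rcpp kernels for training on CPU, Labelme annotation
    import, a synthetic scene generator with exact centerline ground truth,
    segmentation metrics, Hilditch skeletonization, Hough-gradient coin
    detection for pixel-to-millimetre calibration, and per-seedling shoot and
    root length measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
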