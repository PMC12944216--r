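Package: mosswave
Title: Unbiased ROI Segmentation and Calcium Wave Analysis for Protonemal
    Timelapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of widefield calcium-imaging timelapses of
    filamentous moss protonemal colonies expressing a genetically encoded
    calcium indicator. Segments colonies into regions of interest (ROIs) by
    k-means clustering of per-pixel fluorescence dynamics with a cosine
    distance, after foreground masking (rolling-ball background subtraction,
    disk median filtering, triangle auto-thresholding), Richardson-Lucy
    deconvolution, morphological background correction and per-pixel
    Z-normalization. Detects calcium waves in ROI traces by topographic peak
    prominence with a median-absolute-deviation threshold, and quantifies
    wave shape (FW10 duration, rise and fall times), timing (intervals,
    frequency, coefficient of variation), synchrony (lagged cross-correlation,
    instantaneous wave probability) and stimulus entrainment (per-pulse
    response latency, wave counts and normalized response area). Includes a
    synthetic timelapse generator with full ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
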