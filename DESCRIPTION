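Package: phenopipe
Title: Calibrated Colour Segmentation and Phenotype Measurement for
    High-Throughput Plant Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch image-analysis pipeline for high-throughput plant
    phenotyping. Classifies every pixel of top-view and side-view plant
    images by multidimensional histogram thresholding (closed min/max
    intervals on all six RGB and HSV channels), restricted to calibrated
    scene regions for non-plant objects; extracts the plant mask, cleans
    it by morphological opening, and measures height, width, x/y-extent,
    maximum Feret diameter and projected shoot area in millimetres.
    Includes a calibration helper that derives threshold profiles from
    labelled pixel samples, an annotation renderer (outline, extent and
    diameter overlays, scale bar, per-plant image stacks), a deterministic
    batch runner with CSV export and group summaries (mean +/- standard
    error of projected shoot area), and a synthetic scene generator with
    exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    grDevices,
    stats,
    utils,
    yaml,
    png,
    tiff
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
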