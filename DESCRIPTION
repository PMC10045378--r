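Package: cycleUS
Title: Ultrasound to Pseudo-Anatomical Image Translation with a
    Contrast-Inverting CycleGAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unpaired translation of B-mode breast ultrasound images into
    colour pseudo-anatomical displays using a CycleGAN whose identity loss
    is replaced by an "opposite" loss that rewards contrast inversion
    (dark ultrasound masses become light optical masses). Includes a
    seeded dual-domain phantom generator (speckle ultrasound images and
    optical tissue images with ground-truth lesion masks), BUSI-style
    image IO with patch cropping and stratified splitting, automatic
    lesion segmentation by inverse-Gaussian-gradient preprocessing and
    morphological geodesic active contours, and anatomical-fidelity
    metrics (Dice index, centroid error normalised by the image diagonal,
    and area index normalised by the image area) with per-class summary
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
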