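Package: trussseg
Title: Growing-Truss Segmentation from RGB Images via Depth-Colormap
    Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the growing truss (the actively growing stem tip)
    of greenhouse tomato plants in RGB images by translating them into
    depth-colormap images with a CycleGAN (two generators, two patch
    discriminators, adversarial plus cycle-consistency losses) and then
    extracting the near-camera red region with a deterministic HSV gate,
    Otsu binarisation and morphological cleanup chain.  Includes a
    synthetic paired-scene generator emulating the greenhouse imaging
    regime, pixel-level evaluation metrics (residual-ratio false
    negatives/positives, mean intersection-over-union, ROC/AUC), a
    compact convolutional-network engine with analytic backpropagation,
    and an end-to-end experiment driver comparing the depth-camera and
    CycleGAN segmentation paths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
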