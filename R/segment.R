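#' Extract the growing-truss mask from a depth-colormap image
#'
#' The full extraction chain: HSV gating (near-camera red band), luma
#' grayscale of the gated image, Otsu binarisation, and morphological
#' cleanup ([morph_clean()]).  The same chain applies to true depth
#' colormaps and to translated (CycleGAN-converted) images.
#'
#' @param image numeric array `(H, W, 3)` in `[0, 1]`: a rendered depth
#'   colormap or a converted RGB image.
#' @param config a [segmentation_config()].
#' @return logical mask matrix of the image's spatial dimensions.
#' @export
segment_truss <- function(image, config = segmentation_config()) {
  if (!inherits(config, "segmentation_config"))
    stop("config must be a segmentation_config")
  gate <- hsv_gate(image, config$hsv_range)
  gray <- (0.299 * image[, , 1] + 0.587 * image[, , 2] +
             0.114 * image[, , 3]) * gate
  bin <- otsu_threshold(gray)$binary
  morph_clean(bin, config)
}

#' Grayscale the segmentation chain thresholds
#'
#' The continuous per-pixel score the chain binarises: the luma of the
#' HSV-gated image (gated-out pixels are 0).  This is the score axis used
#' for ROC analysis of the segmentation.
#'
#' @inheritParams segment_truss
#' @return numeric matrix in `[0, 1]`.
#' @export
segmentation_scores <- function(image, config = segmentation_config()) {
  gate <- hsv_gate(image, config$hsv_range)
  (0.299 * image[, , 1] + 0.587 * image[, , 2] +
     0.114 * image[, , 3]) * gate
}
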