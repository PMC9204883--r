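# ---------------------------------------------------------------------------
# Morphological cleanup of a binary mask (EBImage-backed): closing to fill
# small fragments, contour fill, a single 3x3 erosion to strip noise, and
# small-component removal.
# ---------------------------------------------------------------------------

#' Segmentation configuration
#'
#' Bundles the tunables of the truss extraction chain.  The erosion
#' defaults (3x3 kernel, one iteration) are the protocol's noise-removal
#' step; the closing kernel (5x5 disc) is deliberately larger so fragments
#' are net-filled.
#'
#' @param hsv_range an [hsv_range()] or preset name; default preset `"c"`.
#' @param closing_kernel odd size of the disc structuring element for the
#'   morphological closing. Default 5.
#' @param erosion_kernel odd size of the box erosion kernel. Default 3.
#' @param erosion_iterations erosion repetitions. Default 1.
#' @param min_component_area connected components smaller than this many
#'   pixels are discarded. Default 25.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(hsv_range = "c", closing_kernel = 5L,
                                erosion_kernel = 3L,
                                erosion_iterations = 1L,
                                min_component_area = 25L) {
  if (is.character(hsv_range))
    hsv_range <- hsv_presets()[[match.arg(hsv_range, c("a", "b", "c"))]]
  stopifnot(inherits(hsv_range, "hsv_range"))
  if (closing_kernel %% 2L != 1L || erosion_kernel %% 2L != 1L)
    stop("kernel sizes must be odd")
  structure(list(hsv_range = hsv_range,
                 closing_kernel = as.integer(closing_kernel),
                 erosion_kernel = as.integer(erosion_kernel),
                 erosion_iterations = as.integer(erosion_iterations),
                 min_component_area = as.integer(min_component_area)),
            class = "segmentation_config")
}

#' Morphological cleanup of a binary mask
#'
#' Applies, in order: closing (dilate then erode, disc kernel) to fill
#' small fragments; filling of the external contours of each connected
#' component (hole fill); `erosion_iterations` erosions with the box
#' kernel to remove small noise objects; and removal of connected
#' components below `min_component_area` pixels.
#'
#' @param mask logical matrix.
#' @param config a [segmentation_config()].
#' @return logical matrix of the same dimensions.
#' @export
morph_clean <- function(mask, config = segmentation_config()) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(mask)
  img <- EBImage::Image(mask * 1.0)
  img <- EBImage::closing(img, EBImage::makeBrush(config$closing_kernel,
                                                  "disc"))
  img <- EBImage::fillHull(img)
  brush <- EBImage::makeBrush(config$erosion_kernel, "box")
  for (i in seq_len(config$erosion_iterations))
    img <- EBImage::erode(img, brush)
  out <- EBImage::imageData(img) > 0.5
  if (config$min_component_area > 0L && any(out)) {
    lab <- EBImage::bwlabel(EBImage::Image(out * 1.0))
    labs <- EBImage::imageData(lab)
    areas <- tabulate(labs[labs > 0])
    keep <- which(areas >= config$min_component_area)
    out <- matrix(labs %in% keep & labs > 0, nrow(mask), ncol(mask))
  }
  out
}
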