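# ---------------------------------------------------------------------------
# HSV gating: select pixels whose hue/saturation/value fall inside closed
# intervals, on the OpenCV-style 8-bit scales (H 0-179, S and V 0-255).
# Used to isolate the red (near-camera) region of a depth colormap.
# ---------------------------------------------------------------------------

#' HSV interval gate
#'
#' @param h_lo,h_hi hue bounds on the 0-179 scale (degrees / 2).
#' @param s_lo,s_hi saturation bounds on 0-255.
#' @param v_lo,v_hi value bounds on 0-255.
#' @return an `hsv_range` list.
#' @export
hsv_range <- function(h_lo, h_hi, s_lo, s_hi, v_lo, v_hi) {
  bounds <- c(h_lo, h_hi, s_lo, s_hi, v_lo, v_hi)
  if (any(bounds != round(bounds))) stop("bounds must be integers")
  if (h_lo > h_hi || s_lo > s_hi || v_lo > v_hi)
    stop("each lower bound must be <= its upper bound")
  if (h_lo < 0 || h_hi > 179) stop("hue bounds must be within 0-179")
  if (s_lo < 0 || s_hi > 255 || v_lo < 0 || v_hi > 255)
    stop("saturation/value bounds must be within 0-255")
  structure(list(h_lo = h_lo, h_hi = h_hi, s_lo = s_lo, s_hi = s_hi,
                 v_lo = v_lo, v_hi = v_hi),
            class = "hsv_range")
}

#' The three candidate HSV gating presets
#'
#' The three gating conditions evaluated during pipeline development,
#' reproduced verbatim: (a) H 0-65, S 150-255, V 150-255; (b) H 0-30,
#' S 180-245, V 250-255; (c) H 0-30, S 248-255, V 240-255.  Preset `c` is
#' the pipeline default: on depth colormaps it selects exactly the
#' saturated red-to-orange band that encodes near-camera objects.
#'
#' @return named list of [hsv_range()] objects `a`, `b`, `c`.
#' @export
hsv_presets <- function() {
  list(a = hsv_range(0, 65, 150, 255, 150, 255),
       b = hsv_range(0, 30, 180, 245, 250, 255),
       c = hsv_range(0, 30, 248, 255, 240, 255))
}

#' Convert an RGB raster to 8-bit HSV channels
#'
#' Standard RGB to HSV transform on the OpenCV-style scales: hue in
#' 0-179 (degrees halved), saturation and value in 0-255.
#'
#' @param img numeric array `(H, W, 3)` with values in `[0, 1]`.
#' @return list of integer matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv8 <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an (H, W, 3) array")
  m <- grDevices::rgb2hsv(t(matrix(img, d[1] * d[2], 3L)) * 255,
                          maxColorValue = 255)
  list(h = matrix(as.integer(round(m[1, ] * 180)) %% 180L, d[1], d[2]),
       s = matrix(as.integer(round(m[2, ] * 255)), d[1], d[2]),
       v = matrix(as.integer(round(m[3, ] * 255)), d[1], d[2]))
}

#' Gate an image by HSV intervals
#'
#' A pixel passes iff its (hue, saturation, value) triple lies inside all
#' three closed intervals of `range`.
#'
#' @param img numeric array `(H, W, 3)` in `[0, 1]`.
#' @param range an [hsv_range()], or a preset name `"a"`, `"b"`, `"c"`.
#' @return logical matrix of the image's spatial dimensions.
#' @export
hsv_gate <- function(img, range = "c") {
  if (is.character(range)) range <- hsv_presets()[[match.arg(range, c("a", "b", "c"))]]
  stopifnot(inherits(range, "hsv_range"))
  hsv <- rgb_to_hsv8(img)
  hsv$h >= range$h_lo & hsv$h <= range$h_hi &
    hsv$s >= range$s_lo & hsv$s <= range$s_hi &
    hsv$v >= range$v_lo & hsv$v <= range$v_hi
}
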