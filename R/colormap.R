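# ---------------------------------------------------------------------------
# Depth colormap rendering: metric depth -> 3-channel colour-coded image
# (near -> red, far -> blue), the target domain of the translation model.
# ---------------------------------------------------------------------------

#' The depth colour table
#'
#' A 256-entry jet-like colour table spanning hue red (near) to blue (far)
#' at full saturation and value.  Stored explicitly so tests and the
#' decoder can do exact per-entry lookups.
#'
#' @param n number of entries (default 256).
#' @return integer matrix `n x 3` of 8-bit RGB values; row 1 is pure red
#'   `(255, 0, 0)`, row `n` pure blue `(0, 0, 255)`.
#' @export
depth_color_table <- function(n = 256L) {
  t <- seq(0, 1, length.out = n)
  hex <- grDevices::hsv(h = (240 * t) / 360, s = 1, v = 1)
  t(grDevices::col2rgb(hex))
}

#' Render a depth map as a colormap image
#'
#' Clips depth to `[near, far]`, maps it through the colour table of
#' [depth_color_table()] with near depths red and far depths blue, and
#' renders invalid pixels (sensor dropouts) black.
#'
#' @param depth a `depth_map` (see [generate_scene()]) or a numeric matrix
#'   of distances in meters.
#' @param near,far colorizer range in meters (`near < far`); a fixed-range
#'   colorizer, so renderings are comparable across frames.
#' @return numeric array `(H, W, 3)` in `[0, 1]`, 8-bit quantised.
#' @export
render_depth_colormap <- function(depth, near = 0.4, far = 4.0) {
  if (near >= far) stop("near must be < far")
  if (inherits(depth, "depth_map")) {
    values <- depth$values
    valid <- depth$valid
  } else {
    values <- depth
    valid <- matrix(TRUE, nrow(values), ncol(values))
  }
  tab <- depth_color_table()
  t <- (values - near) / (far - near)
  t[t < 0] <- 0
  t[t > 1] <- 1
  idx <- as.integer(round(t * 255)) + 1L
  img <- array(0, c(nrow(values), ncol(values), 3L))
  for (ch in 1:3) {
    plane <- tab[idx, ch] / 255
    plane[!valid] <- 0
    img[, , ch] <- plane
  }
  img
}

#' Decode a rendered colormap back to depth
#'
#' Nearest-table-entry lookup: each pixel is matched to the closest entry
#' of [depth_color_table()] (squared-error in 8-bit RGB space) and mapped
#' back to meters.  Exact up to quantisation: error is at most one
#' table-step of `(far - near)`.  Black pixels decode as invalid.
#'
#' @param img array `(H, W, 3)` in `[0, 1]` as produced by
#'   [render_depth_colormap()].
#' @inheritParams render_depth_colormap
#' @return a `depth_map` list with `values` (meters) and `valid` matrices.
#' @export
decode_depth_colormap <- function(img, near = 0.4, far = 4.0) {
  if (near >= far) stop("near must be < far")
  d <- dim(img)
  tab <- depth_color_table()
  px <- matrix(img, d[1] * d[2], 3L) * 255
  valid <- rowSums(px) > 0
  idx <- rep(NA_integer_, nrow(px))
  # chunked nearest-entry search to bound memory
  chunk <- 8192L
  tt <- t(tab)
  tab_sq <- colSums(tt^2)
  for (start in seq(1L, nrow(px), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(px))
    sim <- px[rows, , drop = FALSE] %*% tt  # (m x 256)
    idx[rows] <- max.col(sweep(sim, 2, tab_sq / 2), ties.method = "first")
  }
  tvals <- (idx - 1L) / 255
  values <- matrix(near + tvals * (far - near), d[1], d[2])
  values[!valid] <- NA_real_
  structure(list(values = values, valid = matrix(valid, d[1], d[2])),
            class = "depth_map")
}
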