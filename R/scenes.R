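# ---------------------------------------------------------------------------
# Synthetic paired-scene generator.
#
# Emulates the greenhouse imaging regime the pipeline was designed for: a
# growing truss (branching stem + leaf canopy) nearest the camera, a
# cluttered far background, a metric depth map, and the ground-truth truss
# mask.  Every scene is a deterministic function of (config seed, index).
# ---------------------------------------------------------------------------

#' Scene generator configuration
#'
#' @param image_size square raster size in pixels (>= 64). Default 512,
#'   the translation network's native input size; use 1600x900 capture
#'   emulation by resizing externally.
#' @param n_trusses number of near-camera truss structures. Default 1.
#' @param near_depth_range numeric length-2, meters: depth band of the
#'   truss (camera to growing tip). Default `c(0.4, 0.9)`.
#' @param far_depth_range numeric length-2, meters: depth band of the
#'   background canopy/clutter. Default `c(1.5, 4.0)`. Must lie entirely
#'   beyond `near_depth_range`.
#' @param clutter_density fraction in `[0, 1]` controlling how much of the
#'   background is covered by clutter blobs. Default 0.3.
#' @param defocus_prob probability that a frame simulates a depth-camera
#'   defocus failure (a contiguous blob of invalid, corrupted depth).
#'   Default 0.
#' @param rng_seed integer master seed; with the scene index it fully
#'   determines each scene.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = 512L, n_trusses = 1L,
                         near_depth_range = c(0.4, 0.9),
                         far_depth_range = c(1.5, 4.0),
                         clutter_density = 0.3, defocus_prob = 0,
                         rng_seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be >= 64")
  if (length(near_depth_range) != 2L || diff(near_depth_range) <= 0)
    stop("near_depth_range must be an increasing length-2 range")
  if (length(far_depth_range) != 2L || diff(far_depth_range) <= 0)
    stop("far_depth_range must be an increasing length-2 range")
  if (near_depth_range[2] >= far_depth_range[1])
    stop("near_depth_range must lie entirely below far_depth_range")
  if (min(near_depth_range) <= 0) stop("depths must be positive")
  if (defocus_prob < 0 || defocus_prob > 1)
    stop("defocus_prob must be in [0, 1]")
  if (n_trusses < 0L) stop("n_trusses must be >= 0")
  structure(list(image_size = image_size, n_trusses = as.integer(n_trusses),
                 near_depth_range = near_depth_range,
                 far_depth_range = far_depth_range,
                 clutter_density = clutter_density,
                 defocus_prob = defocus_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

# Paint an ellipse (center cx, cy; radii rx, ry; rotation theta; all in
# pixels) into the scene, restricted to its bounding box for speed.
# `paint` is called with (rows, cols, inside-mask submatrix).
ellipse_apply <- function(size, cx, cy, rx, ry, theta, paint) {
  rmax <- max(rx, ry)
  rows <- max(1L, floor(cy - rmax)):min(size, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(size, ceiling(cx + rmax))
  if (!length(rows) || !length(cols)) return(invisible())
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  paint(rows, cols, u^2 + v^2 <= 1)
  invisible()
}

#' Generate one synthetic scene
#'
#' Produces a paired RGB image / metric depth map / ground-truth mask
#' triplet.  Trusses are branching curvilinear structures (a Bezier stem
#' with an elliptical leaf canopy and occasional fruit) in plant greens and
#' muted reds, placed at near-range depth over a cluttered far background.
#' With probability `defocus_prob` a contiguous region of the depth map is
#' invalidated and its values corrupted, emulating a depth-camera defocus
#' failure; the RGB image is unaffected.
#'
#' Deterministic: the same `(config, index)` always yields a bit-identical
#' triplet, and the caller's RNG state is left untouched.
#'
#' @param config a [scene_config()].
#' @param index non-negative scene index.
#' @return a `scene_triplet` list: `rgb` array `(H, W, 3)` in `[0, 1]`;
#'   `depth`, a `depth_map` with `values` (meters) and `valid` matrices;
#'   `truth`, logical truss mask.
#' @export
generate_scene <- function(config, index = 0L) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  index <- as.integer(index)
  if (index < 0L) stop("index must be >= 0")
  seed <- (as.numeric(config$rng_seed) * 48271 + index * 104729) %% 2147483629
  with_seed(as.integer(seed), generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  size <- config$image_size
  nr <- config$near_depth_range
  fr <- config$far_depth_range
  yg <- matrix(seq(0, 1, length.out = size), size, size)

  # background: greenhouse canopy wall, depth receding towards the bottom
  rgb <- array(0, c(size, size, 3L))
  rgb[, , 1] <- 0.32 + 0.08 * yg
  rgb[, , 2] <- 0.40 + 0.10 * yg
  rgb[, , 3] <- 0.28 + 0.06 * yg
  depth <- matrix(fr[1] + 0.65 * diff(fr), size, size) + (0.25 * diff(fr)) * yg
  depth <- pmin(pmax(depth + matrix(stats::rnorm(size^2, sd = 0.03),
                                    size, size), fr[1]), fr[2])

  # clutter: far-range leaves/stems/pipes as coloured ellipses
  n_clutter <- round(config$clutter_density * 55)
  palette <- rbind(c(0.20, 0.45, 0.18), c(0.30, 0.50, 0.22),
                   c(0.42, 0.36, 0.22), c(0.48, 0.46, 0.40),
                   c(0.15, 0.35, 0.15))
  for (i in seq_len(n_clutter)) {
    cx <- stats::runif(1, 1, size)
    cy <- stats::runif(1, 1, size)
    rx <- stats::runif(1, 0.03, 0.10) * size
    ry <- rx * stats::runif(1, 0.4, 1)
    th <- stats::runif(1, 0, pi)
    dep <- stats::runif(1, fr[1], fr[2])
    col <- palette[sample.int(nrow(palette), 1), ] +
      stats::runif(3, -0.05, 0.05)
    ellipse_apply(size, cx, cy, rx, ry, th, function(rows, cols, m) {
      sub <- depth[rows, cols]
      sub[m] <- pmin(pmax(dep + stats::rnorm(sum(m), sd = 0.02),
                          fr[1]), fr[2])
      depth[rows, cols] <<- sub
      for (ch in 1:3) {
        s <- rgb[rows, cols, ch]
        s[m] <- pmin(pmax(col[ch] + stats::rnorm(sum(m), sd = 0.02), 0), 1)
        rgb[rows, cols, ch] <<- s
      }
    })
  }

  # trusses: nearest the camera, drawn last (occluding)
  truth <- matrix(FALSE, size, size)
  truss_depth <- matrix(NA_real_, size, size)
  margin <- 0.05 * diff(nr)
  for (k in seq_len(config$n_trusses)) {
    cx <- stats::runif(1, 0.30, 0.70) * size
    cy <- stats::runif(1, 0.32, 0.55) * size
    base_d <- stats::runif(1, nr[1] + margin, nr[2] - margin)
    part <- matrix(FALSE, size, size)

    # curvilinear stem: quadratic Bezier from the bottom edge to the canopy
    p0 <- c(cx + stats::runif(1, -0.15, 0.15) * size, 0.98 * size)
    p1 <- c(cx + stats::runif(1, -0.20, 0.20) * size,
            (cy + 0.98 * size) / 2)
    p2 <- c(cx, cy)
    tseq <- seq(0, 1, length.out = 4L * size %/% 8L)
    bx <- (1 - tseq)^2 * p0[1] + 2 * (1 - tseq) * tseq * p1[1] + tseq^2 * p2[1]
    by <- (1 - tseq)^2 * p0[2] + 2 * (1 - tseq) * tseq * p1[2] + tseq^2 * p2[2]
    wstem <- max(1.2, 0.016 * size)
    for (j in seq_along(tseq)) {
      ellipse_apply(size, bx[j], by[j], wstem, wstem, 0,
                    function(rows, cols, m) {
                      part[rows, cols] <<- part[rows, cols] | m
                    })
    }

    # leaf canopy: overlapping ellipses clustered at the growing tip
    n_leaf <- sample(5:8, 1)
    for (j in seq_len(n_leaf)) {
      lx <- cx + stats::rnorm(1, sd = 0.055 * size)
      ly <- cy + stats::rnorm(1, sd = 0.050 * size)
      rx <- stats::runif(1, 0.07, 0.12) * size
      ry <- rx * stats::runif(1, 0.55, 1)
      th <- stats::runif(1, 0, pi)
      ellipse_apply(size, lx, ly, rx, ry, th, function(rows, cols, m) {
        part[rows, cols] <<- part[rows, cols] | m
      })
    }

    # occasional fruit below the canopy
    for (j in seq_len(sample(0:2, 1))) {
      ellipse_apply(size, cx + stats::rnorm(1, sd = 0.05 * size),
                    cy + stats::runif(1, 0.08, 0.16) * size,
                    0.022 * size, 0.022 * size, 0,
                    function(rows, cols, m) {
                      part[rows, cols] <<- part[rows, cols] | m
                    })
    }

    npx <- sum(part)
    if (npx > 0) {
      greens <- c(stats::runif(1, 0.16, 0.30), stats::runif(1, 0.42, 0.60),
                  stats::runif(1, 0.12, 0.24))
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[part] <- pmin(pmax(greens[ch] +
                                   stats::rnorm(npx, sd = 0.03), 0), 1)
        rgb[, , ch] <- plane
      }
      dvals <- base_d + 0.10 * diff(nr) * (yg[part] - 0.5) +
        stats::rnorm(npx, sd = 0.01)
      truss_depth[part] <- pmin(pmax(dvals, nr[1]), nr[2])
      truth <- truth | part
    }
  }
  depth[truth] <- truss_depth[truth]

  # sensor noise on the photo only
  rgb <- rgb + array(stats::rnorm(length(rgb), sd = 0.012), dim(rgb))
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1

  valid <- matrix(TRUE, size, size)
  if (config$defocus_prob > 0 && stats::runif(1) < config$defocus_prob) {
    ellipse_apply(size, stats::runif(1, 1, size), stats::runif(1, 1, size),
                  stats::runif(1, 0.12, 0.25) * size,
                  stats::runif(1, 0.12, 0.25) * size,
                  stats::runif(1, 0, pi),
                  function(rows, cols, m) {
                    v <- valid[rows, cols]
                    v[m] <- FALSE
                    valid[rows, cols] <<- v
                    sub <- depth[rows, cols]
                    sub[m] <- stats::runif(sum(m), fr[1], fr[2])
                    depth[rows, cols] <<- sub
                  })
  }

  structure(list(rgb = rgb,
                 depth = structure(list(values = depth, valid = valid),
                                   class = "depth_map"),
                 truth = truth,
                 config = config),
            class = "scene_triplet")
}

#' Train/test split sizes at the acquisition protocol's proportion
#'
#' The reference acquisition used 356 images split 276 train / 80 test;
#' requested counts are split at that proportion (`round(n * 276/356)`
#' train).
#'
#' @param n total number of scenes.
#' @param train_frac training fraction, default `276/356`.
#' @return named integer vector `c(train =, test =)`.
#' @export
split_sizes <- function(n, train_frac = 276 / 356) {
  n <- as.integer(n)
  ntr <- as.integer(round(n * train_frac))
  c(train = ntr, test = n - ntr)
}

#' Export a synthetic dataset to disk
#'
#' Writes, for each scene, the RGB image, the rendered depth colormap, the
#' ground-truth mask (all PNG) and the metric depth map (NPY, float32
#' meters, NaN at invalid pixels), plus a JSON manifest recording
#' train/test membership.
#'
#' @param config a [scene_config()].
#' @param n number of scenes.
#' @param out_dir output directory (created if needed).
#' @param train_frac training fraction; default the 276/356 protocol
#'   proportion.
#' @param near,far colorizer range passed to [render_depth_colormap()];
#'   defaults to the config's full depth span.
#' @return the manifest as a data.frame (`id`, `split`, and path columns),
#'   invisibly; also written to `manifest.json`.
#' @export
export_dataset <- function(config, n, out_dir,
                           train_frac = 276 / 356,
                           near = config$near_depth_range[1],
                           far = config$far_depth_range[2]) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  sizes <- split_sizes(n, train_frac)
  split <- rep(c("train", "test"), times = sizes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("scene_%04d", i - 1L)
    sc <- generate_scene(config, i - 1L)
    paths <- list(
      rgb = file.path(out_dir, paste0(id, "_rgb.png")),
      colormap = file.path(out_dir, paste0(id, "_depthcm.png")),
      mask = file.path(out_dir, paste0(id, "_mask.png")),
      depth = file.path(out_dir, paste0(id, "_depth.npy")))
    png::writePNG(sc$rgb, paths$rgb)
    png::writePNG(render_depth_colormap(sc$depth, near, far), paths$colormap)
    png::writePNG(sc$truth * 1.0, paths$mask)
    dvals <- sc$depth$values
    dvals[!sc$depth$valid] <- NaN
    write_npy(dvals, paths$depth)
    rows[[i]] <- data.frame(id = id, split = split[i],
                            rgb = paths$rgb, colormap = paths$colormap,
                            mask = paths$mask, depth = paths$depth,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0L) do.call(rbind, rows) else
    data.frame(id = character(), split = character(), rgb = character(),
               colormap = character(), mask = character(),
               depth = character(), stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
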