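# ---------------------------------------------------------------------------
# End-to-end experiment driver: simulate -> train -> convert -> segment ->
# evaluate, comparing the depth-camera path (segmenting the true rendered
# colormap) with the translation path (segmenting the CycleGAN-converted
# RGB) on the held-out test split.
# ---------------------------------------------------------------------------

#' Experiment configuration
#'
#' Bundles every stage's configuration so a run directory fully describes
#' the run that produced it.  The defaults are a desk-scale demonstration
#' (small rasters, short training); see the package vignette for the
#' rationale behind the scaled problem sizes.
#'
#' @param n_scenes total synthetic scenes; split train/test at the 276/356
#'   protocol proportion.
#' @param scene a [scene_config()] (its `image_size` also sizes the
#'   networks).
#' @param train a [train_config()].
#' @param seg a [segmentation_config()].
#' @param base_channels,transformer_blocks generator size (see
#'   [generator_config()]).
#' @param disc_channels,disc_layers discriminator size.
#' @param comparison_paths logical toggles `c(depth_direct =, cyclegan =)`.
#' @param colorizer_range meters `c(near, far)` for
#'   [render_depth_colormap()]; defaults to the scene's full depth span.
#' @param rng_seed master seed for model initialisation.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_scenes = 20L,
                              scene = scene_config(image_size = 64L),
                              train = train_config(iterations = 200L,
                                                   batch_size = 5L),
                              seg = segmentation_config(),
                              base_channels = 8L, transformer_blocks = 2L,
                              disc_channels = 8L, disc_layers = 2L,
                              comparison_paths = c(depth_direct = TRUE,
                                                   cyclegan = TRUE),
                              colorizer_range = NULL,
                              rng_seed = 1L) {
  if (!inherits(scene, "scene_config")) scene <- do.call(scene_config, scene)
  if (!inherits(train, "train_config")) train <- do.call(train_config, train)
  if (!inherits(seg, "segmentation_config"))
    seg <- do.call(segmentation_config, seg)
  if (is.null(colorizer_range))
    colorizer_range <- c(scene$near_depth_range[1], scene$far_depth_range[2])
  structure(list(n_scenes = as.integer(n_scenes), scene = scene,
                 train = train, seg = seg,
                 base_channels = as.integer(base_channels),
                 transformer_blocks = as.integer(transformer_blocks),
                 disc_channels = as.integer(disc_channels),
                 disc_layers = as.integer(disc_layers),
                 comparison_paths = comparison_paths,
                 colorizer_range = colorizer_range,
                 rng_seed = as.integer(rng_seed)),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return write: `path` invisibly; read: an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  plain <- list(
    n_scenes = config$n_scenes,
    scene = unclass(config$scene),
    train = unclass(config$train),
    seg = c(list(hsv_range = unclass(config$seg$hsv_range)),
            unclass(config$seg)[-1]),
    base_channels = config$base_channels,
    transformer_blocks = config$transformer_blocks,
    disc_channels = config$disc_channels,
    disc_layers = config$disc_layers,
    comparison_paths = as.list(config$comparison_paths),
    colorizer_range = config$colorizer_range,
    rng_seed = config$rng_seed)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  p <- yaml::read_yaml(path)
  experiment_config(
    n_scenes = p$n_scenes,
    scene = do.call(scene_config, p$scene),
    train = do.call(train_config, p$train),
    seg = segmentation_config(
      hsv_range = do.call(hsv_range, p$seg$hsv_range),
      closing_kernel = p$seg$closing_kernel,
      erosion_kernel = p$seg$erosion_kernel,
      erosion_iterations = p$seg$erosion_iterations,
      min_component_area = p$seg$min_component_area),
    base_channels = p$base_channels,
    transformer_blocks = p$transformer_blocks,
    disc_channels = p$disc_channels, disc_layers = p$disc_layers,
    comparison_paths = unlist(p$comparison_paths),
    colorizer_range = unlist(p$colorizer_range),
    rng_seed = p$rng_seed)
}

stage_log <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %-9s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the end-to-end comparison experiment
#'
#' Executes, with per-stage logging: scene simulation; CycleGAN training on
#' the train split (RGB and rendered-colormap domains treated as
#' unpaired); conversion of the test RGB images; segmentation of both the
#' converted images and the true rendered colormaps; and evaluation of
#' both paths against the generated truth masks.  The run directory
#' receives the exact configuration, all masks and metric tables, the loss
#' history, and a comparison summary; rerunning with the same
#' configuration reproduces all deterministic artifacts.
#'
#' @param config an [experiment_config()].
#' @param out_dir run directory (created).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `reports` (per enabled path), `state`
#'   (the trained `cyclegan_state`, NULL if the cyclegan path is
#'   disabled), `manifest`, and `dir`.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  log <- function(stage, msg) {
    if (!quiet) stage_log(logfile, stage, msg) else
      stage_log_quiet(logfile, stage, msg)
  }
  write_experiment_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(rng_seed = config$rng_seed,
         scene_seed = config$scene$rng_seed,
         train_seed = config$train$rng_seed,
         package_version = as.character(utils::packageVersion("trussseg")),
         r_version = R.version.string),
    file.path(out_dir, "versions.json"), auto_unbox = TRUE, pretty = TRUE)

  cz <- config$colorizer_range
  use_gan <- isTRUE(config$comparison_paths[["cyclegan"]])
  use_depth <- isTRUE(config$comparison_paths[["depth_direct"]])

  # -- simulate -------------------------------------------------------------
  log("simulate", sprintf("generating %d scenes (%dpx)", config$n_scenes,
                          config$scene$image_size))
  scenes <- lapply(seq_len(config$n_scenes) - 1L,
                   function(i) generate_scene(config$scene, i))
  sizes <- split_sizes(config$n_scenes)
  split <- rep(c("train", "test"), times = sizes)
  manifest <- data.frame(id = sprintf("scene_%04d",
                                      seq_len(config$n_scenes) - 1L),
                         split = split, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  colormaps <- lapply(scenes, function(s)
    render_depth_colormap(s$depth, cz[1], cz[2]))
  itrain <- which(split == "train")
  itest <- which(split == "test")
  if (!length(itest)) stop("stage simulate: no test scenes", call. = FALSE)

  state <- NULL
  if (use_gan) {
    # -- train --------------------------------------------------------------
    log("train", sprintf("%d iterations, batch %d",
                         config$train$iterations, config$train$batch_size))
    state <- cyclegan(input_size = config$scene$image_size,
                      base_channels = config$base_channels,
                      transformer_blocks = config$transformer_blocks,
                      disc_channels = config$disc_channels,
                      disc_layers = config$disc_layers,
                      rng_seed = config$rng_seed)
    state <- train_cyclegan(state,
                            lapply(scenes[itrain], function(s) s$rgb),
                            colormaps[itrain], config$train)
    write_loss_history(state, file.path(out_dir, "loss_history.csv"))
    save_checkpoint(state, file.path(out_dir, "checkpoint.rds"))
  }

  # -- convert / segment / evaluate ----------------------------------------
  truth <- lapply(scenes[itest], function(s) s$truth)
  ids <- manifest$id[itest]
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  reports <- list()

  if (use_depth) {
    log("segment", "depth_direct path: segmenting true rendered colormaps")
    pred <- lapply(colormaps[itest], segment_truss, config = config$seg)
    scr <- lapply(colormaps[itest], segmentation_scores,
                  config = config$seg)
    for (k in seq_along(pred))
      png::writePNG(pred[[k]] * 1.0,
                    file.path(mask_dir, paste0(ids[k], "_depth.png")))
    reports$depth_direct <- evaluate_dataset(pred, truth, scr, ids)
    write_eval_report(reports$depth_direct,
                      file.path(out_dir, "eval_depth_direct"))
  }
  if (use_gan) {
    log("convert", sprintf("converting %d test RGB images", length(itest)))
    fake <- lapply(scenes[itest], function(s) convert_to_depth(state, s$rgb))
    for (k in seq_along(fake))
      png::writePNG(fake[[k]],
                    file.path(mask_dir, paste0(ids[k], "_converted.png")))
    log("segment", "cyclegan path: segmenting converted images")
    pred <- lapply(fake, segment_truss, config = config$seg)
    scr <- lapply(fake, segmentation_scores, config = config$seg)
    for (k in seq_along(pred))
      png::writePNG(pred[[k]] * 1.0,
                    file.path(mask_dir, paste0(ids[k], "_cyclegan.png")))
    reports$cyclegan <- evaluate_dataset(pred, truth, scr, ids)
    write_eval_report(reports$cyclegan, file.path(out_dir, "eval_cyclegan"))
  }

  comparison <- lapply(reports, function(r) {
    stats::setNames(as.list(r$aggregate$mean), r$aggregate$metric)
  })
  for (nm in names(reports)) comparison[[nm]]$auc <- reports[[nm]]$auc
  jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done", sprintf("run directory: %s", out_dir))
  invisible(list(reports = reports, state = state, manifest = manifest,
                 dir = out_dir))
}

stage_log_quiet <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %-9s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Convert and segment an ordered frame sequence
#'
#' Applies [convert_to_depth()] and [segment_truss()] to each frame
#' independently (no inter-frame registration), preserving input order.
#' Frames may be `(H, W, 3)` arrays or PNG file paths; unreadable frames
#' are skipped with a warning.
#'
#' @param state a trained `cyclegan_state`.
#' @param frames non-empty list of arrays or PNG paths.
#' @param config a [segmentation_config()].
#' @return named list of logical masks, in input order (skipped frames
#'   omitted).
#' @export
scan_sequence <- function(state, frames, config = segmentation_config()) {
  if (length(frames) == 0L) stop("frames must be non-empty")
  out <- list()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.character(fr)) {
      fr <- tryCatch(png::readPNG(fr), error = function(e) {
        warning("skipping unreadable frame ", i, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(fr)) next
      if (length(dim(fr)) == 3L && dim(fr)[3] == 4L) fr <- fr[, , 1:3]
    }
    mask <- segment_truss(convert_to_depth(state, fr), config)
    out[[sprintf("frame_%03d", i)]] <- mask
  }
  out
}
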