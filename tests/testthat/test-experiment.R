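tiny_experiment <- function(gan = TRUE, iters = 4L, seed = 1L) {
  experiment_config(
    n_scenes = 8L,
    scene = scene_config(image_size = 64L, rng_seed = seed),
    train = train_config(iterations = iters, batch_size = 2L,
                         rng_seed = seed),
    base_channels = 4L, transformer_blocks = 1L,
    disc_channels = 4L, disc_layers = 2L,
    comparison_paths = c(depth_direct = TRUE, cyclegan = gan),
    rng_seed = seed)
}

test_that("a minimal end-to-end run completes and produces both reports", {
  dir <- withr::local_tempdir()
  res <- run_experiment(tiny_experiment(), dir, quiet = TRUE)
  expect_named(res$reports, c("depth_direct", "cyclegan"))
  for (r in res$reports) {
    expect_s3_class(r, "eval_report")
    expect_equal(nrow(r$per_image), 2)  # 8 scenes -> 6 train / 2 test
    expect_true(all(c("fn_pct", "fp_pct", "miou_pct") %in%
                      colnames(r$per_image)))
  }
  expect_true(all(file.exists(file.path(dir, c(
    "config.yaml", "manifest.csv", "loss_history.csv", "comparison.json",
    "versions.json", "checkpoint.rds", "run.log")))))
  expect_true(dir.exists(file.path(dir, "eval_depth_direct")))
  expect_true(dir.exists(file.path(dir, "eval_cyclegan")))
  cmp <- jsonlite::read_json(file.path(dir, "comparison.json"))
  expect_named(cmp, c("depth_direct", "cyclegan"))
  expect_true(is.numeric(cmp$depth_direct$miou_pct))
})

test_that("disabling the cyclegan path skips training and conversion", {
  dir <- withr::local_tempdir()
  res <- run_experiment(tiny_experiment(gan = FALSE), dir, quiet = TRUE)
  expect_named(res$reports, "depth_direct")
  expect_null(res$state)
  expect_false(file.exists(file.path(dir, "checkpoint.rds")))
  expect_false(dir.exists(file.path(dir, "eval_cyclegan")))
})

test_that("identical configs reproduce the depth-direct path bit-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_experiment(tiny_experiment(gan = FALSE), d1, quiet = TRUE)
  run_experiment(tiny_experiment(gan = FALSE), d2, quiet = TRUE)
  for (f in c("manifest.csv", file.path("eval_depth_direct",
                                        "per_image.csv"))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  m1 <- list.files(file.path(d1, "masks"), full.names = TRUE)
  m2 <- list.files(file.path(d2, "masks"), full.names = TRUE)
  expect_identical(basename(m1), basename(m2))
  for (k in seq_along(m1))
    expect_identical(readBin(m1[k], "raw", file.size(m1[k])),
                     readBin(m2[k], "raw", file.size(m2[k])))
})

test_that("experiment configurations round-trip through YAML", {
  cfg <- tiny_experiment(iters = 7L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back$scene, cfg$scene)
  expect_equal(back$train, cfg$train)
  expect_equal(back$seg$hsv_range, cfg$seg$hsv_range)
  expect_equal(back$comparison_paths, cfg$comparison_paths)
  expect_equal(back$colorizer_range, cfg$colorizer_range)
})

test_that("scan_sequence preserves frame order and per-frame independence", {
  st <- cyclegan(input_size = 32L, base_channels = 4L,
                 transformer_blocks = 1L, disc_channels = 4L,
                 disc_layers = 2L, rng_seed = 2L)
  cfg <- scene_config(image_size = 64L, rng_seed = 4L)
  frames <- lapply(0:2, function(i)
    generate_scene(cfg, i)$rgb[1:32, 1:32, ])
  frames <- c(frames, frames[1])  # repeat the first frame
  masks <- scan_sequence(st, frames)
  expect_length(masks, 4)
  expect_named(masks, sprintf("frame_%03d", 1:4))
  expect_identical(masks[[4]], masks[[1]])
  expect_error(scan_sequence(st, list()), "non-empty")
  # unreadable path frames are skipped with a warning
  good <- withr::local_tempfile(fileext = ".png")
  png::writePNG(frames[[2]], good)
  expect_warning(
    m2 <- scan_sequence(st, list(good, "/nonexistent/frame.png")),
    "skipping")
  expect_length(m2, 1)
  expect_identical(m2[[1]], masks[[2]])
})
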