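test_that("scene generation is bit-identical for the same (config, index)", {
  cfg <- scene_config(image_size = 64L, rng_seed = 7L)
  a <- generate_scene(cfg, 3L)
  b <- generate_scene(cfg, 3L)
  expect_identical(a, b)
  # a different index gives a different scene
  expect_false(identical(a$rgb, generate_scene(cfg, 4L)$rgb))
  # and the caller's RNG stream is untouched
  set.seed(99)
  before <- runif(3)
  invisible(generate_scene(cfg, 0L))
  set.seed(99)
  expect_identical(before, runif(3))
})

test_that("scene triplets satisfy their structural invariants", {
  cfg <- scene_config(image_size = 96L, rng_seed = 2L)
  for (i in 0:3) {
    sc <- generate_scene(cfg, i)
    expect_identical(dim(sc$rgb)[1:2], dim(sc$truth))
    expect_identical(dim(sc$depth$values), dim(sc$truth))
    # valid depths are positive
    expect_true(all(sc$depth$values[sc$depth$valid] > 0))
    # truss pixels (where valid) lie inside the near depth band
    td <- sc$depth$values[sc$truth & sc$depth$valid]
    expect_true(all(td >= cfg$near_depth_range[1]))
    expect_true(all(td <= cfg$near_depth_range[2]))
    # background pixels lie in the far band
    bd <- sc$depth$values[!sc$truth & sc$depth$valid]
    expect_true(all(bd >= cfg$far_depth_range[1]))
    expect_true(sum(sc$truth) > 0)
  }
})

test_that("defocus and truss-count switches behave as configured", {
  clean <- scene_config(image_size = 64L, defocus_prob = 0, rng_seed = 5L)
  for (i in 0:4)
    expect_true(all(generate_scene(clean, i)$depth$valid))

  always <- scene_config(image_size = 64L, defocus_prob = 1, rng_seed = 5L)
  sc <- generate_scene(always, 0L)
  expect_gt(sum(!sc$depth$valid), 0)
  # the invalidated region is contiguous (a single blob)
  lab <- EBImage::bwlabel(EBImage::Image((!sc$depth$valid) * 1.0))
  expect_equal(max(lab), 1)

  none <- scene_config(image_size = 64L, n_trusses = 0L)
  expect_false(any(generate_scene(none, 0L)$truth))
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(image_size = 32L), ">= 64")
  expect_error(scene_config(near_depth_range = c(0.9, 0.4)), "increasing")
  expect_error(scene_config(near_depth_range = c(0.4, 2.0),
                            far_depth_range = c(1.5, 4.0)), "entirely")
  expect_error(scene_config(defocus_prob = 1.5), "defocus_prob")
})

test_that("train/test split follows the 276/356 proportion", {
  expect_identical(split_sizes(89), c(train = 69L, test = 20L))
  expect_identical(split_sizes(0), c(train = 0L, test = 0L))
})

test_that("export_dataset writes triplets and a faithful manifest", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(image_size = 64L, rng_seed = 3L)
  man <- export_dataset(cfg, 5L, dir)
  expect_equal(nrow(man), 5)
  expect_equal(sum(man$split == "train"), 4)  # round(5 * 276/356)
  expect_true(all(file.exists(man$rgb, man$colormap, man$mask, man$depth)))
  # PNG and NPY round-trips reproduce the generated scene
  sc <- generate_scene(cfg, 2L)
  expect_equal(png::readPNG(man$rgb[3]), round(sc$rgb * 255) / 255,
               tolerance = 1e-12)
  expect_identical(png::readPNG(man$mask[3]) == 1, sc$truth)
  dep <- read_npy(man$depth[3])
  expect_equal(dep, sc$depth$values, tolerance = 1e-6)
  j <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  expect_identical(j$id, man$id)
  expect_identical(j$split, man$split)
})

test_that("an empty export produces an empty manifest and no scene files", {
  dir <- withr::local_tempdir()
  man <- export_dataset(scene_config(image_size = 64L), 0L, dir)
  expect_equal(nrow(man), 0)
  expect_length(list.files(dir, pattern = "scene_"), 0)
})

test_that("npy round-trips float32 matrices including NaN", {
  path <- withr::local_tempfile(fileext = ".npy")
  m <- matrix(rnorm(12), 3, 4)
  m[2, 2] <- NaN
  write_npy(m, path)
  back <- read_npy(path)
  expect_equal(back, m, tolerance = 1e-6)
  expect_true(is.nan(back[2, 2]))
})
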