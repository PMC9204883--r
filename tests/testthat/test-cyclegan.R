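ns <- asNamespace("trussseg")

tiny_state <- function(size = 32L, seed = 1L) {
  cyclegan(input_size = size, base_channels = 4L, transformer_blocks = 1L,
           disc_channels = 4L, disc_layers = 2L, rng_seed = seed)
}

tiny_domains <- function(n = 6L, size = 32L, seed = 2L) {
  cfg <- scene_config(image_size = 64L, rng_seed = seed)
  scenes <- lapply(seq_len(n) - 1L, function(i) generate_scene(cfg, i))
  xs <- lapply(scenes, function(s) s$rgb[seq_len(size), seq_len(size), ])
  ys <- lapply(scenes, function(s)
    render_depth_colormap(s$depth, 0.4, 4.0)[seq_len(size), seq_len(size), ])
  list(x = xs, y = ys)
}

test_that("generators conserve raster shape at any valid input size", {
  set.seed(91)
  gen <- build_generator(generator_config(64L, 4L, 2L))
  for (size in c(64L, 32L)) {
    x <- array(runif(size * size * 3) * 2 - 1, c(size, size, 3))
    expect_identical(dim(generator_apply(gen, x)), dim(x))
  }
  expect_error(generator_config(30L), "divisible by 4")
  expect_identical(generator_config()$transformer_blocks, 8L)
})

test_that("a zero-initialised residual block is the identity map", {
  set.seed(92)
  blk <- ns$layer_resblock(4L)
  for (i in seq_along(blk$sub))
    if (!is.null(blk$sub[[i]]$w)) blk$sub[[i]]$w[] <- 0
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  expect_equal(ns$layer_forward(blk, x)$out, x)
})

test_that("the discriminator's prediction field follows the layer arithmetic", {
  # 512 input through 3 stride-2 layers then two stride-1 4x4 layers:
  # 512 -> 256 -> 128 -> 64 -> 63 -> 62
  expect_identical(discriminator_output_size(512L, 3L), 62L)
  set.seed(93)
  dsc <- build_discriminator(discriminator_config(4L, 2L))
  for (size in c(32L, 48L)) {
    x <- array(runif(size * size * 3) * 2 - 1, c(size, size, 3))
    p <- discriminator_apply(dsc, x)
    expect_identical(dim(p)[1], discriminator_output_size(size, 2L))
    expect_true(all(is.finite(p)))
    expect_identical(p, discriminator_apply(dsc, x))  # eval determinism
  }
})

test_that("cycle losses equal the elementwise mean-absolute-deviation oracle", {
  st <- tiny_state(8L)
  set.seed(94)
  x <- array(runif(8 * 8 * 3) * 2 - 1, c(8, 8, 3))
  y <- array(runif(8 * 8 * 3) * 2 - 1, c(8, 8, 3))
  cl <- cycle_losses(st, x, y)
  rx <- generator_apply(st$F, generator_apply(st$G, x))
  ry <- generator_apply(st$G, generator_apply(st$F, y))
  fwd <- mean(abs(as.vector(rx) - as.vector(x)))
  rev <- mean(abs(as.vector(ry) - as.vector(y)))
  expect_equal(cl[["forward"]], fwd, tolerance = 1e-12)
  expect_equal(cl[["reverse"]], rev, tolerance = 1e-12)
  expect_true(all(cl >= 0))
})

test_that("an all-zero x with constant F(G(x)) gives forward loss |c|", {
  st <- tiny_state(8L)
  # zero every parameter, then set F's output bias so F(G(x)) = c everywhere
  zero_net <- function(layers) {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type %in% c("conv", "convt")) { l$w[] <- 0; l$b[] <- 0 }
      if (l$type == "instnorm") { l$gamma[] <- 0; l$beta[] <- 0 }
      if (l$type == "resblock") l$sub <- zero_net(l$sub)
      layers[[i]] <- l
    }
    layers
  }
  st$G$layers <- zero_net(st$G$layers)
  st$F$layers <- zero_net(st$F$layers)
  cval <- -0.3
  nf <- length(st$F$layers)
  st$F$layers[[nf - 1L]]$b[] <- atanh(cval)  # final conv feeds tanh
  x0 <- array(0, c(8, 8, 3))
  cl <- cycle_losses(st, x0, x0)
  expect_equal(cl[["forward"]], abs(cval), tolerance = 1e-12)
})

test_that("zero-iteration training returns the state untouched", {
  st <- tiny_state()
  d <- tiny_domains()
  out <- train_cyclegan(st, d$x, d$y, train_config(iterations = 0L))
  expect_identical(out, st)
  expect_equal(nrow(out$loss_history), 0)
})

test_that("training is reproducible and records every iteration's losses", {
  d <- tiny_domains()
  cfg <- train_config(iterations = 6L, batch_size = 2L, rng_seed = 3L)
  a <- train_cyclegan(tiny_state(seed = 5L), d$x, d$y, cfg)
  b <- train_cyclegan(tiny_state(seed = 5L), d$x, d$y, cfg)
  expect_identical(a$loss_history, b$loss_history)
  expect_equal(nrow(a$loss_history), 6)
  expect_true(all(is.finite(as.matrix(a$loss_history))))
  expect_equal(a$iterations, 6L)
  # unpaired domains of unequal size are accepted
  expect_no_error(train_cyclegan(tiny_state(), d$x[1:3], d$y,
                                 train_config(iterations = 1L,
                                              batch_size = 2L)))
  expect_error(train_cyclegan(tiny_state(), list(), d$y,
                              train_config(iterations = 1L)), "non-empty")
})

test_that("training aborts with the iteration index on non-finite loss", {
  st <- tiny_state()
  st$G$layers[[1]]$w[1] <- Inf
  d <- tiny_domains(n = 3L)
  expect_error(
    train_cyclegan(st, d$x, d$y,
                   train_config(iterations = 3L, batch_size = 2L)),
    "iteration 1")
})

test_that("short training reduces the recorded cycle losses", {
  d <- tiny_domains(n = 8L)
  st <- train_cyclegan(tiny_state(seed = 7L), d$x, d$y,
                       train_config(iterations = 40L, batch_size = 2L,
                                    rng_seed = 11L))
  h <- st$loss_history
  early <- mean(h$fwd_cycle[1:8] + h$rev_cycle[1:8])
  late <- mean(tail(h$fwd_cycle, 8) + tail(h$rev_cycle, 8))
  expect_lt(late, early)
})

test_that("conversion resizes, quantises to 8 bits, and is deterministic", {
  st <- tiny_state(32L)
  set.seed(95)
  rgb <- random_rgb(90, 160)  # oblong input exercises the resize path
  out <- convert_to_depth(st, rgb)
  expect_identical(dim(out), c(32L, 32L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(out, round(out * 255) / 255)  # 8-bit levels
  expect_identical(out, convert_to_depth(st, rgb))
  expect_error(convert_to_depth(st, matrix(1, 4, 4)), "3-channel")
})

test_that("checkpoints round-trip to bit-identical inference", {
  d <- tiny_domains(n = 4L)
  st <- train_cyclegan(tiny_state(seed = 9L), d$x, d$y,
                       train_config(iterations = 3L, batch_size = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  set.seed(96)
  rgb <- random_rgb(32)
  expect_identical(convert_to_depth(back, rgb), convert_to_depth(st, rgb))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$iterations, 3)
})
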