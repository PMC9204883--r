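# ---------------------------------------------------------------------------
# CycleGAN: two generators (G: RGB -> depth colormap, F: depth colormap ->
# RGB), two patch discriminators, least-squares adversarial losses and L1
# cycle-consistency losses, trained on unpaired image domains.
# ---------------------------------------------------------------------------

#' Create an untrained CycleGAN state
#'
#' Builds the two generators `G` (RGB to depth colormap) and `F` (depth
#' colormap to RGB) and discriminators `Dx`, `Dy` with freshly initialised
#' weights, plus an empty loss history.
#'
#' @param input_size square raster size the generators are built for
#'   (default 512; inputs of other sizes are resized at inference).
#' @param base_channels generator channel width (see [generator_config()]).
#' @param transformer_blocks residual blocks in each generator (default 8).
#' @param disc_channels,disc_layers discriminator width / number of strided
#'   layers (see [discriminator_config()]).
#' @param rng_seed seed for weight initialisation.
#' @return a `cyclegan_state` object.
#' @export
cyclegan <- function(input_size = 512L, base_channels = 64L,
                     transformer_blocks = 8L, disc_channels = base_channels,
                     disc_layers = 3L, rng_seed = 1L) {
  gcfg <- generator_config(input_size, base_channels, transformer_blocks)
  dcfg <- discriminator_config(disc_channels, disc_layers)
  with_seed(rng_seed, {
    G <- build_generator(gcfg)
    F_ <- build_generator(gcfg)
    Dx <- build_discriminator(dcfg)
    Dy <- build_discriminator(dcfg)
  })
  structure(list(G = G, F = F_, Dx = Dx, Dy = Dy,
                 loss_history = empty_loss_history(),
                 iterations = 0L,
                 config = list(generator = gcfg, discriminator = dcfg)),
            class = "cyclegan_state")
}

empty_loss_history <- function() {
  data.frame(iteration = integer(), g_loss = numeric(),
             dx_loss = numeric(), dy_loss = numeric(),
             fwd_cycle = numeric(), rev_cycle = numeric())
}

# Evaluate-and-restore RNG helper so model construction / training is
# reproducible without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Training configuration
#'
#' @param iterations optimisation iterations (each draws one unpaired batch
#'   from both domains and updates generators and discriminators once).
#'   Full-scale training in the source protocol is ~9600 iterations.
#' @param batch_size images per batch per domain. Default 5.
#' @param learning_rate Adam learning rate, default 2e-4.
#' @param beta1 Adam first-moment decay, default 0.5.
#' @param cycle_weight weight lambda of the L1 cycle-consistency losses,
#'   default 10.
#' @param identity_weight optional identity-loss weight (L1 between G(y)
#'   and y, F(x) and x); 0 disables it (the default).
#' @param rng_seed seed governing batch sampling.
#' @param verbose print a progress line every `verbose` iterations (0 =
#'   silent).
#' @return a `train_config` list.
#' @export
train_config <- function(iterations = 9600L, batch_size = 5L,
                         learning_rate = 2e-4, beta1 = 0.5,
                         cycle_weight = 10, identity_weight = 0,
                         rng_seed = 1L, verbose = 0L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (cycle_weight <= 0) stop("cycle_weight must be > 0")
  if (iterations < 0L) stop("iterations must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 cycle_weight = cycle_weight,
                 identity_weight = identity_weight,
                 rng_seed = as.integer(rng_seed),
                 verbose = as.integer(verbose)),
            class = "train_config")
}

# Coerce a dataset (list of (H,W,3) arrays in [0,1], or one 4-d array) to a
# list of normalised [-1,1] arrays.
as_domain_list <- function(x, name) {
  if (is.array(x) && length(dim(x)) == 4L)
    x <- lapply(seq_len(dim(x)[4]), function(i) x[, , , i, drop = TRUE])
  if (!is.list(x) || length(x) == 0L)
    stop("domain ", name, " must be a non-empty list of (H, W, 3) arrays")
  lapply(x, function(im) {
    if (length(dim(im)) != 3L || dim(im)[3] != 3L)
      stop("domain ", name, " images must be (H, W, 3) arrays")
    im * 2 - 1
  })
}

stack_batch <- function(imgs, idx) {
  d <- dim(imgs[[idx[1]]])
  out <- array(0, c(d, length(idx)))
  for (k in seq_along(idx)) out[, , , k] <- imgs[[idx[k]]]
  out
}

#' Train a CycleGAN on two unpaired image domains
#'
#' Runs least-squares adversarial plus cycle-consistency optimisation with
#' Adam.  The two domains need not be paired and may differ in size; each
#' iteration samples an independent batch from each.  All loss components
#' are recorded per iteration, and training aborts with the iteration index
#' if any loss becomes non-finite.
#'
#' @param state a `cyclegan_state` from [cyclegan()].
#' @param dataset_x RGB domain: list of `(H, W, 3)` arrays in `[0, 1]` (or
#'   a 4-d array).
#' @param dataset_y depth-colormap domain, same form.
#' @param config a [train_config()].
#' @return the updated `cyclegan_state` (loss history appended).
#' @export
train_cyclegan <- function(state, dataset_x, dataset_y,
                           config = train_config()) {
  stopifnot(inherits(state, "cyclegan_state"))
  if (!inherits(config, "train_config")) config <- do.call(train_config, config)
  xs <- as_domain_list(dataset_x, "x")
  ys <- as_domain_list(dataset_y, "y")
  if (config$iterations == 0L) return(state)

  G <- state$G$layers; F_ <- state$F$layers
  Dx <- state$Dx$layers; Dy <- state$Dy$layers
  adG <- adam_init(G); adF <- adam_init(F_)
  adDx <- adam_init(Dx); adDy <- adam_init(Dy)
  lam <- config$cycle_weight
  lr <- config$learning_rate
  b1 <- config$beta1
  hist <- matrix(NA_real_, config$iterations, 6)

  with_seed(config$rng_seed, {
    for (it in seq_len(config$iterations)) {
      ix <- sample.int(length(xs), config$batch_size,
                       replace = length(xs) < config$batch_size)
      iy <- sample.int(length(ys), config$batch_size,
                       replace = length(ys) < config$batch_size)
      x <- stack_batch(xs, ix)
      y <- stack_batch(ys, iy)

      # ---- generator update (Dx, Dy frozen) ----
      fG1 <- net_forward(G, x);    fy <- fG1$out      # G(x)
      fF1 <- net_forward(F_, fy);  rx <- fF1$out      # F(G(x))
      fF2 <- net_forward(F_, y);   fx <- fF2$out      # F(y)
      fG2 <- net_forward(G, fx);   ry <- fG2$out      # G(F(y))
      fDy <- net_forward(Dy, fy);  py <- fDy$out
      fDx <- net_forward(Dx, fx);  px <- fDx$out

      cyc_f <- mean(abs(rx - x))
      cyc_r <- mean(abs(ry - y))
      adv_g <- mean((py - 1)^2)
      adv_f <- mean((px - 1)^2)
      g_loss <- adv_g + adv_f + lam * (cyc_f + cyc_r)
      if (!is.finite(g_loss))
        stop("non-finite loss at iteration ", state$iterations + it)

      bF1 <- net_backward(F_, fF1$caches, lam * sign(rx - x) / length(rx))
      bDyf <- net_backward(Dy, fDy$caches, 2 * (py - 1) / length(py))
      bG1 <- net_backward(G, fG1$caches, bF1$dx + bDyf$dx)
      bG2 <- net_backward(G, fG2$caches, lam * sign(ry - y) / length(ry))
      bDxf <- net_backward(Dx, fDx$caches, 2 * (px - 1) / length(px))
      bF2 <- net_backward(F_, fF2$caches, bG2$dx + bDxf$dx)
      gG <- add_grads(bG1$grads, bG2$grads)
      gF <- add_grads(bF1$grads, bF2$grads)

      if (config$identity_weight > 0) {
        fGi <- net_forward(G, y); fFi <- net_forward(F_, x)
        wi <- config$identity_weight
        g_loss <- g_loss + wi * (mean(abs(fGi$out - y)) +
                                 mean(abs(fFi$out - x)))
        gG <- add_grads(gG, net_backward(
          G, fGi$caches, wi * sign(fGi$out - y) / length(y))$grads)
        gF <- add_grads(gF, net_backward(
          F_, fFi$caches, wi * sign(fFi$out - x) / length(x))$grads)
      }

      u <- adam_step(G, gG, adG, lr, b1, t = it)
      G <- u$layers; adG <- u$state
      u <- adam_step(F_, gF, adF, lr, b1, t = it)
      F_ <- u$layers; adF <- u$state

      # ---- discriminator updates (fakes from the pre-update generators) --
      fDyr <- net_forward(Dy, y);  pyr <- fDyr$out
      fDyf <- net_forward(Dy, fy); pyf <- fDyf$out
      dy_loss <- 0.5 * (mean((pyr - 1)^2) + mean(pyf^2))
      gDy <- add_grads(
        net_backward(Dy, fDyr$caches, (pyr - 1) / length(pyr))$grads,
        net_backward(Dy, fDyf$caches, pyf / length(pyf))$grads)
      u <- adam_step(Dy, gDy, adDy, lr, b1, t = it)
      Dy <- u$layers; adDy <- u$state

      fDxr <- net_forward(Dx, x);  pxr <- fDxr$out
      fDxf <- net_forward(Dx, fx); pxf <- fDxf$out
      dx_loss <- 0.5 * (mean((pxr - 1)^2) + mean(pxf^2))
      gDx <- add_grads(
        net_backward(Dx, fDxr$caches, (pxr - 1) / length(pxr))$grads,
        net_backward(Dx, fDxf$caches, pxf / length(pxf))$grads)
      u <- adam_step(Dx, gDx, adDx, lr, b1, t = it)
      Dx <- u$layers; adDx <- u$state

      losses <- c(g_loss, dx_loss, dy_loss, cyc_f, cyc_r)
      if (!all(is.finite(losses)))
        stop("non-finite loss at iteration ", state$iterations + it)
      hist[it, ] <- c(state$iterations + it, losses)
      if (config$verbose > 0L && it %% config$verbose == 0L)
        message(sprintf(
          "iter %d  g %.4f  dx %.4f  dy %.4f  cyc %.4f/%.4f",
          state$iterations + it, g_loss, dx_loss, dy_loss, cyc_f, cyc_r))
    }
  })

  hist <- as.data.frame(hist)
  names(hist) <- names(empty_loss_history())
  state$G$layers <- G; state$F$layers <- F_
  state$Dx$layers <- Dx; state$Dy$layers <- Dy
  state$loss_history <- rbind(state$loss_history, hist)
  state$iterations <- state$iterations + config$iterations
  state
}

#' Forward and reverse cycle-consistency losses
#'
#' Mean absolute deviation between `F(G(x))` and `x` (forward) and between
#' `G(F(y))` and `y` (reverse), evaluated without parameter updates.
#'
#' @param state a `cyclegan_state`.
#' @param x,y arrays `(H, W, 3)` or `(H, W, 3, N)` in the networks'
#'   normalised range `[-1, 1]`.
#' @return named numeric vector `c(forward =, reverse =)`.
#' @export
cycle_losses <- function(state, x, y) {
  stopifnot(inherits(state, "cyclegan_state"))
  if (!identical(dim(x)[3], 3L) && dim(x)[3] != 3) stop("x must be 3-channel")
  if (dim(y)[3] != 3) stop("y must be 3-channel")
  rx <- generator_apply(state$F, generator_apply(state$G, x))
  ry <- generator_apply(state$G, generator_apply(state$F, y))
  c(forward = mean(abs(rx - x)), reverse = mean(abs(ry - y)))
}

#' Convert an RGB image to a depth-colormap image
#'
#' Resizes the input to the generator's native size if needed (plain
#' bilinear resize, matching the acquisition protocol's direct 1600x900 to
#' 512x512 resize), applies `G`, and de-normalises to 8-bit colour levels.
#'
#' @param state a `cyclegan_state`.
#' @param rgb numeric array `(H, W, 3)` with values in `[0, 1]`.
#' @return array `(input_size, input_size, 3)` with values quantised to
#'   8-bit levels `k/255`.
#' @export
convert_to_depth <- function(state, rgb) {
  stopifnot(inherits(state, "cyclegan_state"))
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("input must be a 3-channel (H, W, 3) array")
  size <- state$config$generator$input_size
  if (d[1] != size || d[2] != size)
    rgb <- resize_bilinear(rgb, size, size)
  out <- generator_apply(state$G, rgb * 2 - 1)
  out <- (out + 1) / 2
  out[out < 0] <- 0
  out[out > 1] <- 1
  round(out * 255) / 255
}

resize_bilinear <- function(img, h, w) {
  out <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                         w = h, h = w)
  array(EBImage::imageData(out), dim = c(h, w, dim(img)[3]))
}

#' Save / load a CycleGAN checkpoint
#'
#' The checkpoint is written in R's native serialisation alongside a JSON
#' sidecar recording the architecture configuration and completed
#' iterations.  `load_checkpoint()` restores a state whose inference output
#' is bit-identical to the saved one.
#'
#' @param state a `cyclegan_state`.
#' @param path file path for the checkpoint (`.rds`); the sidecar is
#'   written to `paste0(path, ".json")`.
#' @return `save_checkpoint()`: `path`, invisibly. `load_checkpoint()`: the
#'   restored `cyclegan_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "cyclegan_state"))
  saveRDS(state, path)
  sidecar <- list(
    iterations = state$iterations,
    generator = unclass(state$config$generator),
    discriminator = unclass(state$config$discriminator))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "cyclegan_state"))
    stop("not a cyclegan checkpoint: ", path)
  state
}

#' Export the recorded loss history as CSV
#'
#' @param state a `cyclegan_state`.
#' @param path output CSV path (columns: iteration, g_loss, dx_loss,
#'   dy_loss, fwd_cycle, rev_cycle).
#' @return `path`, invisibly.
#' @export
write_loss_history <- function(state, path) {
  utils::write.csv(state$loss_history, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cyclegan_state <- function(x, ...) {
  g <- x$config$generator
  cat("CycleGAN state\n")
  cat(sprintf("  generators: input %dx%d, %d base channels, %d residual blocks\n",
              g$input_size, g$input_size, g$base_channels,
              g$transformer_blocks))
  cat(sprintf("  iterations completed: %d\n", x$iterations))
  invisible(x)
}
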