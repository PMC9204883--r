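# ---------------------------------------------------------------------------
# Generator and discriminator architectures for the RGB <-> depth-colormap
# translation model.
# ---------------------------------------------------------------------------

#' Generator configuration
#'
#' The generator follows the standard encoder / transformer / decoder layout
#' for image translation: an initial 7x7 convolution plus two stride-2
#' convolutions that increase channels while reducing spatial size, a series
#' of residual blocks (default exactly 8), and two transpose convolutions
#' followed by a 7x7 output convolution that restore the input resolution.
#' Every layer is followed by instance normalisation and ReLU except the
#' output layer, which uses tanh so the full colour range is expressible.
#'
#' @param input_size spatial size in pixels of the (square) input raster;
#'   must be divisible by 4 so the two stride-2 encoder stages invert
#'   exactly. Default 512.
#' @param base_channels channel width after the first convolution; doubled
#'   at each encoder stage. Default 64 (reduce for quick experiments).
#' @param transformer_blocks number of residual blocks. Default 8.
#' @return a `generator_config` list.
#' @export
generator_config <- function(input_size = 512L, base_channels = 64L,
                             transformer_blocks = 8L) {
  input_size <- as.integer(input_size)
  if (input_size < 8L || input_size %% 4L != 0L)
    stop("input_size must be >= 8 and divisible by 4")
  if (transformer_blocks < 0L) stop("transformer_blocks must be >= 0")
  structure(list(input_size = input_size,
                 base_channels = as.integer(base_channels),
                 transformer_blocks = as.integer(transformer_blocks)),
            class = "generator_config")
}

#' Build a translation generator
#'
#' Constructs the parametric map from a 3-channel raster to a 3-channel
#' raster of identical size described in [generator_config()].  Weights are
#' drawn from the calling RNG state, so wrap in `set.seed()` for
#' reproducible initialisation.
#'
#' @param config a [generator_config()].
#' @return a `truss_generator` object.
#' @export
build_generator <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  ngf <- config$base_channels
  layers <- list(
    layer_conv(7L, 7L, 3L, ngf, 1L, 3L),
    layer_instnorm(ngf),
    layer_relu(),
    layer_conv(3L, 3L, ngf, 2L * ngf, 2L, 1L),
    layer_instnorm(2L * ngf),
    layer_relu(),
    layer_conv(3L, 3L, 2L * ngf, 4L * ngf, 2L, 1L),
    layer_instnorm(4L * ngf),
    layer_relu()
  )
  for (i in seq_len(config$transformer_blocks))
    layers <- c(layers, list(layer_resblock(4L * ngf)))
  layers <- c(layers, list(
    layer_convt(3L, 3L, 4L * ngf, 2L * ngf, 2L, 1L, 1L),
    layer_instnorm(2L * ngf),
    layer_relu(),
    layer_convt(3L, 3L, 2L * ngf, ngf, 2L, 1L, 1L),
    layer_instnorm(ngf),
    layer_relu(),
    layer_conv(7L, 7L, ngf, 3L, 1L, 3L),
    layer_tanh()
  ))
  structure(list(layers = layers, config = config),
            class = "truss_generator")
}

#' Apply a generator to a batch of images
#'
#' @param gen a `truss_generator`.
#' @param x numeric array `(H, W, 3)` or `(H, W, 3, N)` in the network's
#'   normalised range `[-1, 1]`.
#' @return array of the same shape as `x`.
#' @export
generator_apply <- function(gen, x) {
  d <- dim(x)
  squeeze <- length(d) == 3L
  if (squeeze) dim(x) <- c(d, 1L)
  if (dim(x)[3] != 3L) stop("generator input must have 3 channels")
  out <- net_forward(gen$layers, x)$out
  if (squeeze) dim(out) <- d
  out
}

#' Discriminator configuration
#'
#' A patch discriminator: a stack of stride-2 4x4 convolutions (leaky ReLU
#' 0.2, instance-normalised except the first), one stride-1 4x4
#' convolution, and a stride-1 4x4 output convolution producing a spatial
#' field of real/fake scores.  With the default three strided layers each
#' output unit has the conventional 70x70-pixel receptive field.
#'
#' @param base_channels channel width of the first layer. Default 64.
#' @param n_strided number of stride-2 layers. Default 3.
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(base_channels = 64L, n_strided = 3L) {
  if (n_strided < 1L) stop("n_strided must be >= 1")
  structure(list(base_channels = as.integer(base_channels),
                 n_strided = as.integer(n_strided)),
            class = "discriminator_config")
}

#' Build a patch discriminator
#'
#' @param config a [discriminator_config()].
#' @return a `truss_discriminator` object mapping a 3-channel raster to a
#'   spatial real/fake prediction field.
#' @export
build_discriminator <- function(config = discriminator_config()) {
  if (!inherits(config, "discriminator_config"))
    config <- do.call(discriminator_config, config)
  ndf <- config$base_channels
  cin <- 3L
  layers <- list()
  for (i in seq_len(config$n_strided)) {
    cout <- as.integer(ndf * min(2^(i - 1), 8))
    layers <- c(layers, list(layer_conv(4L, 4L, cin, cout, 2L, 1L)))
    if (i > 1L) layers <- c(layers, list(layer_instnorm(cout)))
    layers <- c(layers, list(layer_lrelu(0.2)))
    cin <- cout
  }
  cout <- as.integer(ndf * min(2^config$n_strided, 8))
  layers <- c(layers, list(layer_conv(4L, 4L, cin, cout, 1L, 1L),
                           layer_instnorm(cout),
                           layer_lrelu(0.2),
                           layer_conv(4L, 4L, cout, 1L, 1L, 1L)))
  structure(list(layers = layers, config = config),
            class = "truss_discriminator")
}

#' Spatial size of the discriminator's prediction field
#'
#' Pure layer arithmetic: each stride-2 4x4 convolution with padding 1 maps
#' size n to floor((n - 2) / 2) + 1; each of the two final stride-1 layers
#' maps n to n - 1.
#'
#' @param input_size input raster size in pixels.
#' @param n_strided number of stride-2 layers (see
#'   [discriminator_config()]).
#' @return integer field size (the field is square).
#' @export
discriminator_output_size <- function(input_size, n_strided = 3L) {
  n <- as.integer(input_size)
  for (i in seq_len(n_strided)) n <- (n + 2L - 4L) %/% 2L + 1L
  n <- n - 1L  # stride-1 4x4 pad-1 layer
  n <- n - 1L  # output layer, same geometry
  if (n < 1L) stop("input too small for this discriminator")
  n
}

#' @rdname build_discriminator
#' @param disc a `truss_discriminator`.
#' @param x array `(H, W, 3)` or `(H, W, 3, N)` in `[-1, 1]`.
#' @export
discriminator_apply <- function(disc, x) {
  d <- dim(x)
  squeeze <- length(d) == 3L
  if (squeeze) dim(x) <- c(d, 1L)
  out <- net_forward(disc$layers, x)$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
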