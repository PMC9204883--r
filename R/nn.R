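#' @useDynLib trussseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Compact convolutional-network engine.
#
# Networks are plain lists of layer descriptors; forward passes return the
# output together with per-layer caches, and backward passes consume those
# caches to produce analytic gradients for every parameter.  Tensors are
# numeric arrays in (H, W, C, N) order.  The engine implements exactly the
# pieces the translation model needs: strided convolution, transpose
# convolution, instance normalisation, ReLU / leaky ReLU / tanh, residual
# blocks, and Adam.
# ---------------------------------------------------------------------------

#' Rectified linear unit
#'
#' The scalar activation used throughout the generator: 0 for negative
#' inputs, the identity otherwise.  `relu_grad()` is its derivative (taken
#' as 1 at the origin, matching the subgradient convention of the forward
#' definition's `x >= 0` branch).
#'
#' @param v numeric vector or array.
#' @return `relu()`: `v` with negative entries replaced by 0. `relu_grad()`:
#'   the elementwise derivative, 0 where `v < 0` and 1 where `v >= 0`.
#' @examples
#' relu(c(-2, 0, 3.5))
#' relu_grad(c(-1, 2))
#' @export
relu <- function(v) {
  out <- v
  out[out < 0] <- 0
  out
}

#' @rdname relu
#' @export
relu_grad <- function(v) {
  ifelse(v < 0, 0, 1)
}

# Layer constructors.  Weight init: N(0, 0.02) as is conventional for GAN
# generators/discriminators; draws come from the calling RNG state so the
# whole model build is reproducible under set.seed().
layer_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad),
       w = array(stats::rnorm(kh * kw * cin * cout, sd = 0.02),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

layer_convt <- function(kh, kw, cin, cout, stride = 2L, pad = 1L,
                        outpad = 1L) {
  list(type = "convt", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad),
       outpad = as.integer(outpad),
       w = array(stats::rnorm(kh * kw * cout * cin, sd = 0.02),
                 dim = c(kh, kw, cout, cin)),
       b = numeric(cout))
}

layer_instnorm <- function(c, eps = 1e-5) {
  list(type = "instnorm", c = c, eps = eps, gamma = rep(1, c),
       beta = numeric(c))
}

layer_relu <- function() list(type = "relu")
layer_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
layer_tanh <- function() list(type = "tanh")

layer_resblock <- function(c) {
  list(type = "resblock",
       sub = list(layer_conv(3L, 3L, c, c, 1L, 1L),
                  layer_instnorm(c),
                  layer_relu(),
                  layer_conv(3L, 3L, c, c, 1L, 1L),
                  layer_instnorm(c)))
}

layer_forward <- function(l, x) {
  switch(l$type,
    conv = list(out = cpp_conv2d_fwd(x, l$w, l$b, l$kh, l$kw, l$stride,
                                     l$pad),
                cache = x),
    convt = list(out = cpp_convt2d_fwd(x, l$w, l$b, l$kh, l$kw, l$stride,
                                       l$pad, l$outpad),
                 cache = x),
    instnorm = instnorm_forward(l, x),
    relu = {
      out <- x
      out[which(out < 0)] <- 0  # which() drops NaN positions
      list(out = out, cache = !is.na(x) & x >= 0)
    },
    lrelu = {
      neg <- which(x < 0)
      out <- x
      out[neg] <- l$alpha * out[neg]
      list(out = out, cache = neg)
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = out)
    },
    resblock = {
      r <- net_forward(l$sub, x)
      list(out = x + r$out, cache = r$caches)
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, cache, dout) {
  switch(l$type,
    conv = {
      g <- cpp_conv2d_bwd(cache, l$w, dout, l$kh, l$kw, l$stride, l$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    convt = {
      g <- cpp_convt2d_bwd(cache, l$w, dout, l$kh, l$kw, l$stride, l$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    instnorm = instnorm_backward(l, cache, dout),
    relu = {
      dx <- dout
      dx[!cache] <- 0
      list(dx = dx, grads = NULL)
    },
    lrelu = {
      dx <- dout
      dx[cache] <- l$alpha * dx[cache]  # cache holds negative-input indices
      list(dx = dx, grads = NULL)
    },
    tanh = list(dx = dout * (1 - cache^2), grads = NULL),
    resblock = {
      r <- net_backward(l$sub, cache, dout)
      list(dx = dout + r$dx, grads = r$grads)
    },
    stop("unknown layer type: ", l$type))
}

# Instance normalisation: per-sample, per-channel standardisation with a
# learned affine (gamma, beta).  No running statistics: evaluation uses the
# same per-instance statistics as training, as is standard in image
# translation generators.
instnorm_forward <- function(l, x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  cn <- d[3] * d[4]
  xm <- x
  dim(xm) <- c(hw, cn)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = hw)
  sd <- sqrt(colMeans(xc^2) + l$eps)
  xhat <- xc / rep(sd, each = hw)
  gi <- rep(l$gamma, times = d[4])
  bi <- rep(l$beta, times = d[4])
  out <- xhat * rep(gi, each = hw) + rep(bi, each = hw)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, sd = sd, d = d))
}

instnorm_backward <- function(l, cache, dout) {
  d <- cache$d
  hw <- d[1] * d[2]
  dy <- dout
  dim(dy) <- c(hw, d[3] * d[4])
  xhat <- cache$xhat
  dgamma_cn <- colSums(dy * xhat)
  dbeta_cn <- colSums(dy)
  dgamma <- rowSums(matrix(dgamma_cn, d[3], d[4]))
  dbeta <- rowSums(matrix(dbeta_cn, d[3], d[4]))
  gi <- rep(rep(l$gamma, times = d[4]), each = hw)
  dxhat <- dy * gi
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(m1, each = hw) - xhat * rep(m2, each = hw)) /
    rep(cache$sd, each = hw)
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

net_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # keep NULL slots for parameter-free layers
  }
  list(dx = dout, grads = grads)
}

# Elementwise sum of two gradient structures (same shape as produced by
# net_backward); used when a network appears twice in the objective.
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (k in seq_along(a)) {
      r <- add_grads(a[[k]], b[[k]])
      if (!is.null(r)) a[[k]] <- r  # NULL slots (parameter-free layers) stay
    }
    return(a)
  }
  a + b
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv", "convt")) {
      list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    } else if (l$type == "instnorm") {
      list(mg = numeric(l$c), vg = numeric(l$c),
           mb = numeric(l$c), vb = numeric(l$c))
    } else if (l$type == "resblock") {
      adam_init(l$sub)
    } else {
      NULL
    }
  })
}

adam_update_param <- function(p, g, m, v, lr, b1, b2, eps, t) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step <- function(layers, grads, state, lr, b1 = 0.5, b2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    if (l$type %in% c("conv", "convt")) {
      u <- adam_update_param(l$w, g$w, s$mw, s$vw, lr, b1, b2, eps, t)
      l$w <- u$p; s$mw <- u$m; s$vw <- u$v
      u <- adam_update_param(l$b, g$b, s$mb, s$vb, lr, b1, b2, eps, t)
      l$b <- u$p; s$mb <- u$m; s$vb <- u$v
    } else if (l$type == "instnorm") {
      u <- adam_update_param(l$gamma, g$gamma, s$mg, s$vg, lr, b1, b2, eps, t)
      l$gamma <- u$p; s$mg <- u$m; s$vg <- u$v
      u <- adam_update_param(l$beta, g$beta, s$mb, s$vb, lr, b1, b2, eps, t)
      l$beta <- u$p; s$mb <- u$m; s$vb <- u$v
    } else if (l$type == "resblock") {
      u <- adam_step(l$sub, g, s, lr, b1, b2, eps, t)
      l$sub <- u$layers; s <- u$state
    }
    layers[[i]] <- l
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
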