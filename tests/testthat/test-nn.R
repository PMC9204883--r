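# Analytic gradients of the conv-net engine checked against central finite
# differences; these back every loss gradient the training loop uses.

ns <- asNamespace("trussseg")

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution gradients match finite differences", {
  set.seed(81)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  l <- ns$layer_conv(3L, 3L, 2L, 3L, 2L, 1L)
  out <- ns$cpp_conv2d_fwd(x, l$w, l$b, 3L, 3L, 2L, 1L)
  expect_identical(dim(out), c(3L, 3L, 3L, 2L))
  g <- ns$cpp_conv2d_bwd(x, l$w, out, 3L, 3L, 2L, 1L)  # dL/dy = y for L=sum(y^2)/2
  loss <- function(o) sum(o^2) / 2
  expect_lt(max(abs(g$dx - num_grad(function(v)
    loss(ns$cpp_conv2d_fwd(v, l$w, l$b, 3L, 3L, 2L, 1L)), x))), 1e-8)
  expect_lt(max(abs(g$dw - num_grad(function(v)
    loss(ns$cpp_conv2d_fwd(x, v, l$b, 3L, 3L, 2L, 1L)), l$w))), 1e-8)
  expect_lt(max(abs(g$db - num_grad(function(v)
    loss(ns$cpp_conv2d_fwd(x, l$w, v, 3L, 3L, 2L, 1L)), l$b))), 1e-8)
})

test_that("transpose-convolution doubles spatial size and its gradients check", {
  set.seed(82)
  l <- ns$layer_convt(3L, 3L, 3L, 2L, 2L, 1L, 1L)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  out <- ns$cpp_convt2d_fwd(x, l$w, l$b, 3L, 3L, 2L, 1L, 1L)
  expect_identical(dim(out), c(8L, 8L, 2L, 2L))
  g <- ns$cpp_convt2d_bwd(x, l$w, out, 3L, 3L, 2L, 1L)
  loss <- function(o) sum(o^2) / 2
  expect_lt(max(abs(g$dx - num_grad(function(v)
    loss(ns$cpp_convt2d_fwd(v, l$w, l$b, 3L, 3L, 2L, 1L, 1L)), x))), 1e-8)
  expect_lt(max(abs(g$dw - num_grad(function(v)
    loss(ns$cpp_convt2d_fwd(x, v, l$b, 3L, 3L, 2L, 1L, 1L)), l$w))), 1e-8)
})

test_that("instance-norm gradients match finite differences", {
  set.seed(83)
  l <- ns$layer_instnorm(2L)
  l$gamma <- runif(2, 0.5, 1.5)
  l$beta <- rnorm(2)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  fw <- ns$instnorm_forward(l, x)
  tgt <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- ns$instnorm_backward(l, fw$cache, fw$out - tgt)
  lossf <- function(o) sum((o - tgt)^2) / 2
  expect_lt(max(abs(bk$dx - num_grad(function(v)
    lossf(ns$instnorm_forward(l, v)$out), x))), 1e-6)
  expect_lt(max(abs(bk$grads$gamma - num_grad(function(v) {
    l2 <- l; l2$gamma <- v
    lossf(ns$instnorm_forward(l2, x)$out)
  }, l$gamma))), 1e-6)
  # per-instance statistics: each (channel, sample) slice is standardised
  expect_lt(max(abs(apply(fw$out, 3:4, mean) -
                      outer(l$beta, c(1, 1)))), 1e-6)
})

test_that("a full generator backward pass matches finite differences", {
  set.seed(84)
  gen <- build_generator(generator_config(16L, 4L, 1L))
  x <- array(runif(16 * 16 * 3) * 2 - 1, c(16, 16, 3, 1))
  fw <- ns$net_forward(gen$layers, x)
  bk <- ns$net_backward(gen$layers, fw$caches, fw$out / length(fw$out))
  lossf <- function(v) {
    o <- ns$net_forward(gen$layers, v)$out
    sum(o^2) / (2 * length(o))
  }
  idx <- sample(length(x), 12)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + 1e-5
    xm <- x; xm[i] <- xm[i] - 1e-5
    expect_lt(abs(bk$dx[i] - (lossf(xp) - lossf(xm)) / 2e-5), 1e-7)
  }
})

test_that("relu follows its piecewise definition and derivative", {
  expect_equal(relu(-2.0), 0.0)
  expect_equal(relu(3.5), 3.5)
  expect_equal(relu(0.0), 0.0)
  expect_equal(relu_grad(c(-1, -1e-9, 0, 2)), c(0, 0, 1, 1))
})
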