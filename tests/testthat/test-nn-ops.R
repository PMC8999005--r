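# Gradient checks of the hand-written network primitives against central
# finite differences, plus output-shape contracts.

test_that("valid convolution has the correct output dimensions", {
  set.seed(1)
  for (rep in 1:5) {
    h <- sample(3:6, 1); w <- sample(3:7, 1)
    c_in <- sample(1:3, 1); f <- sample(1:4, 1); n <- sample(1:3, 1)
    kh <- sample(2:min(3, h), 1); kw <- sample(2:min(3, w), 1)
    x <- array(rnorm(h * w * c_in * n), c(h, w, c_in, n))
    wt <- array(rnorm(kh * kw * c_in * f), c(kh, kw, c_in, f))
    y <- ns$nn_conv(x, wt, rnorm(f))
    expect_identical(dim(y), c(h - kh + 1L, w - kw + 1L, f, n))
    yt <- ns$nn_tconv(y, array(rnorm(kh * kw * f * c_in), c(kh, kw, f, c_in)))
    expect_identical(dim(yt), c(h, w, c_in, n))
  }
  expect_error(ns$nn_conv(array(0, c(1, 1, 1, 1)), array(0, c(2, 2, 1, 1))),
               "kernel")
})

test_that("convolution matches a naive quadruple loop", {
  set.seed(2)
  x <- array(rnorm(4 * 5 * 2 * 2), c(4, 5, 2, 2))
  wt <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  b <- rnorm(3)
  y <- ns$nn_conv(x, wt, b)
  for (n in 1:2) for (f in 1:3) for (i in 1:3) for (j in 1:4) {
    ref <- b[f]
    for (a in 1:2) for (bb in 1:2) for (cc in 1:2)
      ref <- ref + x[i + a - 1, j + bb - 1, cc, n] * wt[a, bb, cc, f]
    expect_equal(y[i, j, f, n], ref)
  }
})

test_that("conv backward matches finite differences", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  wt <- array(rnorm(2 * 2 * 2 * 3) * 0.5, c(2, 2, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  g <- ns$nn_conv_bwd(x, wt, dy)
  f_x <- function(xx) sum(ns$nn_conv(xx, wt, b) * dy)
  f_w <- function(ww) sum(ns$nn_conv(x, ww, b) * dy)
  f_b <- function(bb) sum(ns$nn_conv(x, wt, bb) * dy)
  expect_lt(max(abs(g$dx - num_grad(f_x, x))), 1e-6)
  expect_lt(max(abs(g$dw - num_grad(f_w, wt))), 1e-6)
  expect_lt(max(abs(g$db - num_grad(f_b, b))), 1e-6)
})

test_that("transposed conv backward matches finite differences and adjointness", {
  set.seed(4)
  x <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  wt <- array(rnorm(2 * 2 * 3 * 2) * 0.5, c(2, 2, 3, 2))
  dy <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  g <- ns$nn_tconv_bwd(x, wt, dy)
  expect_lt(max(abs(g$dx - num_grad(function(xx) sum(ns$nn_tconv(xx, wt) * dy), x))), 1e-6)
  expect_lt(max(abs(g$dw - num_grad(function(ww) sum(ns$nn_tconv(x, ww) * dy), wt))), 1e-6)
  # adjoint identity: <tconv(x, w), y> == <x, conv(y, w)> with flipped roles
  y <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  lhs <- sum(ns$nn_tconv(x, wt) * y)
  wt_swap <- aperm(wt, c(1, 2, 4, 3))
  rhs <- sum(x * ns$nn_conv(y, wt_swap))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("max pooling forward/backward are consistent", {
  set.seed(5)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  y <- ns$nn_maxpool(x)
  expect_identical(dim(y), c(4L, 4L, 2L, 2L))
  # every pooled value is the max of its window
  for (i in 1:4) for (j in 1:4)
    expect_equal(y[i, j, 1, 1], max(x[i:(i + 1), j:(j + 1), 1, 1]))
  dy <- array(rnorm(prod(dim(y))), dim(y))
  dx <- ns$nn_maxpool_bwd(x, y, dy)
  # smooth random input: no ties, so finite differences apply
  expect_lt(max(abs(dx - num_grad(function(xx) {
    sum(ns$nn_maxpool(xx) * dy)
  }, x))), 1e-6)
  # gradient mass is conserved even with ties
  xt <- array(1, c(3, 3, 1, 1))
  yt <- ns$nn_maxpool(xt)
  dyt <- array(1, dim(yt))
  expect_equal(sum(ns$nn_maxpool_bwd(xt, yt, dyt)), sum(dyt))
})

test_that("softmax rows and cross-entropy behave on known values", {
  z <- rbind(c(log(2), 0), c(0, 0))
  p <- ns$softmax_rows(z)
  expect_equal(p[1, ], c(2 / 3, 1 / 3))
  expect_equal(p[2, ], c(0.5, 0.5))
  expect_equal(rowSums(ns$softmax_rows(matrix(rnorm(12), 3))), rep(1, 3))
  # large logits do not overflow
  expect_equal(ns$softmax_rows(rbind(c(1000, 0)))[1, 1], 1)

  ce <- ns$softmax_ce(rbind(c(0, 0)), 1L)
  expect_equal(ce$loss, log(2))
  expect_equal(unname(ce$dlogits), rbind(c(0.5 - 1, 0.5)))
  g <- num_grad(function(zz) ns$softmax_ce(matrix(zz, 1), 1L)$loss, c(0.3, -0.2))
  expect_lt(max(abs(ns$softmax_ce(rbind(c(0.3, -0.2)), 1L)$dlogits - g)), 1e-6)
})

test_that("Adam updates follow the bias-corrected rule", {
  params <- list(w = c(1, 2))
  grads <- list(w = c(0.5, -0.5))
  st <- ns$adam_init(params)
  out <- ns$adam_step(params, grads, st, lr = 0.1)
  # after one step the bias-corrected update is lr * g / (|g| + eps) ~ lr*sign(g)
  expect_equal(out$params$w, c(1, 2) - 0.1 * c(1, -1), tolerance = 1e-6)
  expect_identical(out$state$t, 1L)
})
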