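# Minimal dense/conv network primitives on (H, W, C, N) arrays
# (height, width, channels, batch).  All backward passes are analytic and are
# verified against central finite differences in the test suite.

# reshape (H, W, C, N) -> matrix (H*W*N, C) for channel contraction
hw_to_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

# inverse of hw_to_mat given target dims (H, W, C, N); ncol(m) becomes C
mat_to_hw <- function(m, h, w, n) {
  aperm(array(m, c(h, w, n, ncol(m))), c(1, 2, 4, 3))
}

# zero-pad the two spatial dims by p on every side
nn_pad <- function(x, p = 1L) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

nn_pad_bwd <- function(dy, p = 1L) {
  d <- dim(dy)
  dy[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , , drop = FALSE]
}

# valid cross-correlation: x (H,W,C,N), w (kh,kw,C,F), b length F
# returns (H-kh+1, W-kw+1, F, N)
nn_conv <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)
  ho <- d[1] - k[1] + 1L; wo <- d[2] - k[2] + 1L
  if (ho < 1 || wo < 1) stop("convolution kernel larger than its input")
  acc <- matrix(0, ho * wo * d[4], k[4])
  for (a in seq_len(k[1])) for (bb in seq_len(k[2])) {
    slab <- x[a:(a + ho - 1L), bb:(bb + wo - 1L), , , drop = FALSE]
    acc <- acc + hw_to_mat(slab) %*% wslice(w, a, bb)
  }
  y <- mat_to_hw(acc, ho, wo, d[4])
  if (!is.null(b)) y <- sweep_bias(y, b)
  y
}

# kernel slice at offset (a, b) as a C x F matrix regardless of dims
wslice <- function(w, a, b) {
  k <- dim(w)
  matrix(w[a, b, , ], k[3], k[4])
}

# add per-channel bias to (H, W, F, N)
sweep_bias <- function(y, b) {
  d <- dim(y)
  y + array(rep(b, each = d[1] * d[2]), d)
}

nn_conv_bwd <- function(x, w, dy) {
  d <- dim(x); k <- dim(w); dd <- dim(dy)
  ho <- dd[1]; wo <- dd[2]
  dy_mat <- hw_to_mat(dy)                      # (ho*wo*N, F)
  dw <- array(0, dim(w))
  dx <- array(0, dim(x))
  for (a in seq_len(k[1])) for (bb in seq_len(k[2])) {
    idx_h <- a:(a + ho - 1L); idx_w <- bb:(bb + wo - 1L)
    slab <- x[idx_h, idx_w, , , drop = FALSE]
    dw[a, bb, , ] <- crossprod(hw_to_mat(slab), dy_mat)
    contrib <- dy_mat %*% t(wslice(w, a, bb))   # (ho*wo*N, C)
    dx[idx_h, idx_w, , ] <- dx[idx_h, idx_w, , , drop = FALSE] +
      mat_to_hw(contrib, ho, wo, d[4])
  }
  db <- apply(dy, 3, sum)
  list(dx = dx, dw = dw, db = db)
}

# transposed convolution (stride 1): x (H,W,C,N), w (kh,kw,C,F)
# returns (H+kh-1, W+kw-1, F, N); adjoint of nn_conv in its input
nn_tconv <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)
  ho <- d[1] + k[1] - 1L; wo <- d[2] + k[2] - 1L
  y <- array(0, c(ho, wo, k[4], d[4]))
  x_mat <- hw_to_mat(x)                        # (H*W*N, C)
  for (a in seq_len(k[1])) for (bb in seq_len(k[2])) {
    idx_h <- a:(a + d[1] - 1L); idx_w <- bb:(bb + d[2] - 1L)
    contrib <- x_mat %*% wslice(w, a, bb)       # (H*W*N, F)
    y[idx_h, idx_w, , ] <- y[idx_h, idx_w, , , drop = FALSE] +
      mat_to_hw(contrib, d[1], d[2], d[4])
  }
  if (!is.null(b)) y <- sweep_bias(y, b)
  y
}

nn_tconv_bwd <- function(x, w, dy) {
  d <- dim(x); k <- dim(w)
  x_mat <- hw_to_mat(x)
  dw <- array(0, dim(w))
  dx_mat <- matrix(0, nrow(x_mat), d[3])
  for (a in seq_len(k[1])) for (bb in seq_len(k[2])) {
    idx_h <- a:(a + d[1] - 1L); idx_w <- bb:(bb + d[2] - 1L)
    dy_slab <- hw_to_mat(dy[idx_h, idx_w, , , drop = FALSE])  # (H*W*N, F)
    dw[a, bb, , ] <- crossprod(x_mat, dy_slab)
    dx_mat <- dx_mat + dy_slab %*% t(wslice(w, a, bb))
  }
  list(dx = mat_to_hw(dx_mat, d[1], d[2], d[4]),
       dw = dw, db = apply(dy, 3, sum))
}

# stride-1 valid max pooling over kh x kw windows
nn_maxpool <- function(x, kh = 2L, kw = 2L) {
  d <- dim(x)
  ho <- d[1] - kh + 1L; wo <- d[2] - kw + 1L
  if (ho < 1 || wo < 1) stop("pooling kernel larger than its input")
  y <- NULL
  for (a in seq_len(kh)) for (bb in seq_len(kw)) {
    slab <- x[a:(a + ho - 1L), bb:(bb + wo - 1L), , , drop = FALSE]
    y <- if (is.null(y)) slab else pmax(y, slab)
  }
  y
}

# gradient of max pooling; ties share the gradient equally
nn_maxpool_bwd <- function(x, y, dy, kh = 2L, kw = 2L) {
  d <- dim(x); dd <- dim(y)
  ho <- dd[1]; wo <- dd[2]
  cnt <- array(0, dd)
  for (a in seq_len(kh)) for (bb in seq_len(kw))
    cnt <- cnt + (x[a:(a + ho - 1L), bb:(bb + wo - 1L), , , drop = FALSE] == y)
  g <- dy / cnt
  dx <- array(0, d)
  for (a in seq_len(kh)) for (bb in seq_len(kw)) {
    idx_h <- a:(a + ho - 1L); idx_w <- bb:(bb + wo - 1L)
    dx[idx_h, idx_w, , ] <- dx[idx_h, idx_w, , , drop = FALSE] +
      g * (x[idx_h, idx_w, , , drop = FALSE] == y)
  }
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(x, dy) dy * (x > 0)

# row-wise softmax of a logits matrix (N x C)
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy -sum_n sum_c y log p over one-hot labels (class in {0,1}
# mapped to columns 2/1: column 1 = P(associated)).  Returns loss and the
# gradient w.r.t. the logits (p - y), plus the probabilities.
softmax_ce <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  y <- matrix(c(labels, 1 - labels), ncol = 2)
  pt <- p[cbind(seq_len(n), ifelse(labels == 1, 1L, 2L))]
  clamped <- pt < 1e-12
  loss <- -sum(log(pmax(pt, 1e-12)))
  list(loss = loss, dlogits = p - y, probs = p, n_clamped = sum(clamped))
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Glorot-style uniform init scaled by fan-in/fan-out
glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  if (length(dims) == 1L) return(stats::runif(dims, -lim, lim))
  array(stats::runif(prod(dims), -lim, lim), dims)
}
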