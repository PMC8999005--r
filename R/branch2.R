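# Attribute branch: embed a drug-disease pair as the pair's rows of the three
# heterogeneous networks and encode the embedding with a convolutional
# autoencoder (CAE).  The encoder has two hidden layers (2x2 conv, ring
# zero-padding, ReLU, stride-1 2x2 max-pool; each layer preserves the spatial
# shape), the decoder three 2x2 transposed-conv layers followed by a fixed
# center crop back to the input shape.  The bottleneck map, flattened, feeds
# a softmax head.

#' Build the pairwise attribute embedding tensor
#'
#' For drug `i` and disease `j`, stacks row `i` and row `n_drugs + j` of each
#' of the three heterogeneous networks into a `2 x (n_drugs + n_diseases) x 3`
#' array: slice `[1, , m]` is the drug's row of network `m` (its similarities
#' to all drugs and associations with all diseases), slice `[2, , m]` the
#' disease's row.
#'
#' @param nets list of the three heterogeneous network matrices
#'   (see [hetero_network()]).
#' @param i drug index; `j` disease index.
#' @param j disease index.
#' @return numeric array of shape `(2, n_drugs + n_diseases, 3)`.
#' @export
build_attribute_embedding <- function(nets, i, j) {
  nr <- attr(nets[[1]], "n_drugs")
  n_nodes <- nrow(nets[[1]])
  if (i < 1 || i > nr) stop("drug index out of range: ", i)
  if (j < 1 || j > n_nodes - nr) stop("disease index out of range: ", j)
  p <- array(0, c(2L, n_nodes, 3L))
  for (m in 1:3) {
    p[1, , m] <- nets[[m]][i, ]
    p[2, , m] <- nets[[m]][nr + j, ]
  }
  p
}

# zero the pair's own association entries so the branch cannot read the label
# it is asked to predict (drug row at the disease's position and vice versa)
mask_pair_entries <- function(p, i, j, nr) {
  p[1, nr + j, ] <- 0
  p[2, i, ] <- 0
  p
}

#' Mean squared reconstruction loss of the autoencoder
#'
#' `(1 / n) * sum_n ||P_n - Phat_n||_F^2`, the squared Frobenius norm summed
#' over all tensor entries, averaged over the batch.
#'
#' @param p_batch,phat_batch arrays of identical shape whose last dimension
#'   indexes the batch.
#' @export
reconstruction_loss <- function(p_batch, phat_batch) {
  if (!identical(dim(p_batch), dim(phat_batch)))
    stop("input and reconstruction shapes differ")
  nb <- dim(p_batch)[length(dim(p_batch))]
  if (is.na(nb) || nb < 1) stop("empty batch")
  sum((p_batch - phat_batch)^2) / nb
}

# ---- CAE parameters -------------------------------------------------------

# enc_channels: channels after each encoder conv; dec_channels: channels after
# the first two decoder tconvs (the third maps back to 3 input channels)
cae_init <- function(enc_channels = c(8L, 16L), dec_channels = c(8L, 4L),
                     kernel = c(2L, 2L)) {
  kh <- kernel[1]; kw <- kernel[2]
  p <- list(
    encW1 = glorot(c(kh, kw, 3L, enc_channels[1]), 3 * kh * kw, enc_channels[1]),
    encb1 = numeric(enc_channels[1]),
    encW2 = glorot(c(kh, kw, enc_channels[1], enc_channels[2]),
                   enc_channels[1] * kh * kw, enc_channels[2]),
    encb2 = numeric(enc_channels[2]),
    decW1 = glorot(c(kh, kw, enc_channels[2], dec_channels[1]),
                   enc_channels[2] * kh * kw, dec_channels[1]),
    decb1 = numeric(dec_channels[1]),
    decW2 = glorot(c(kh, kw, dec_channels[1], dec_channels[2]),
                   dec_channels[1] * kh * kw, dec_channels[2]),
    decb2 = numeric(dec_channels[2]),
    decW3 = glorot(c(kh, kw, dec_channels[2], 3L), dec_channels[2] * kh * kw, 3L),
    decb3 = numeric(3L))
  attr(p, "kernel") <- kernel
  p
}

# crop a (H', W', C, N) decoder output back to (h, w, C, N): one ring from the
# top/left, remainder from the bottom/right (deterministic)
cae_crop <- function(x, h, w) {
  d <- dim(x)
  if (d[1] < h || d[2] < w)
    stop("decoder output smaller than the encoder input; invalid CAE config")
  x[1L + seq_len(h), 1L + seq_len(w), , , drop = FALSE]
}

cae_crop_bwd <- function(dy, d_full) {
  dd <- dim(dy)
  dx <- array(0, d_full)
  dx[1L + seq_len(dd[1]), 1L + seq_len(dd[2]), , ] <- dy
  dx
}

#' Encode pairwise attribute embeddings with the CAE encoder
#'
#' Two hidden layers, each a ring-zero-padded 2x2 convolution with ReLU
#' followed by a stride-1 2x2 max-pool, so each layer preserves the
#' `2 x (n_drugs + n_diseases)` spatial shape while growing channels.
#'
#' @param p_batch array `(2, n_nodes, 3, batch)` (a single `(2, n_nodes, 3)`
#'   embedding is promoted to a batch of one).
#' @param params CAE parameter list from the fitted model.
#' @return list with `code` (the final feature map,
#'   `(2, n_nodes, channels, batch)`) and the intermediate maps used for
#'   backpropagation.
#' @export
cae_encode <- function(p_batch, params) {
  if (length(dim(p_batch)) == 3L)
    p_batch <- array(p_batch, c(dim(p_batch), 1L))
  x1 <- nn_pad(p_batch, 1L)
  z1 <- nn_conv(x1, params$encW1, params$encb1)
  a1 <- relu(z1)
  m1 <- nn_maxpool(a1, 2L, 2L)
  x2 <- nn_pad(m1, 1L)
  z2 <- nn_conv(x2, params$encW2, params$encb2)
  a2 <- relu(z2)
  m2 <- nn_maxpool(a2, 2L, 2L)
  list(code = m2, x1 = x1, z1 = z1, a1 = a1, m1 = m1,
       x2 = x2, z2 = z2, a2 = a2, input = p_batch)
}

# backward of the encoder; dcode matches dim(code).  Returns grads + dinput.
cae_encode_bwd <- function(enc, params, dcode, grads) {
  da2 <- nn_maxpool_bwd(enc$a2, enc$code, dcode, 2L, 2L)
  dz2 <- relu_bwd(enc$z2, da2)
  cb2 <- nn_conv_bwd(enc$x2, params$encW2, dz2)
  grads$encW2 <- grads$encW2 + cb2$dw; grads$encb2 <- grads$encb2 + cb2$db
  dm1 <- nn_pad_bwd(cb2$dx, 1L)
  da1 <- nn_maxpool_bwd(enc$a1, enc$m1, dm1, 2L, 2L)
  dz1 <- relu_bwd(enc$z1, da1)
  cb1 <- nn_conv_bwd(enc$x1, params$encW1, dz1)
  grads$encW1 <- grads$encW1 + cb1$dw; grads$encb1 <- grads$encb1 + cb1$db
  list(grads = grads, dinput = nn_pad_bwd(cb1$dx, 1L))
}

#' Decode a CAE code back to the attribute embedding space
#'
#' Three stride-1 2x2 transposed-convolution layers (ReLU on the first two,
#' linear output) followed by a fixed center crop to the encoder input shape.
#'
#' @param code bottleneck feature map from [cae_encode()].
#' @param params CAE parameter list.
#' @param out_hw target spatial shape, `c(2, n_nodes)`.
#' @return list with `phat` (the reconstruction, same shape as the encoder
#'   input) and intermediates for backpropagation.
#' @export
cae_decode <- function(code, params, out_hw) {
  t1 <- nn_tconv(code, params$decW1, params$decb1)
  a1 <- relu(t1)
  t2 <- nn_tconv(a1, params$decW2, params$decb2)
  a2 <- relu(t2)
  t3 <- nn_tconv(a2, params$decW3, params$decb3)
  phat <- cae_crop(t3, out_hw[1], out_hw[2])
  list(phat = phat, t1 = t1, a1 = a1, t2 = t2, a2 = a2, t3 = t3, code = code)
}

cae_decode_bwd <- function(dec, params, dphat, grads) {
  dt3 <- cae_crop_bwd(dphat, dim(dec$t3))
  tb3 <- nn_tconv_bwd(dec$a2, params$decW3, dt3)
  grads$decW3 <- grads$decW3 + tb3$dw; grads$decb3 <- grads$decb3 + tb3$db
  dt2 <- relu_bwd(dec$t2, tb3$dx)
  tb2 <- nn_tconv_bwd(dec$a1, params$decW2, dt2)
  grads$decW2 <- grads$decW2 + tb2$dw; grads$decb2 <- grads$decb2 + tb2$db
  dt1 <- relu_bwd(dec$t1, tb2$dx)
  tb1 <- nn_tconv_bwd(dec$code, params$decW1, dt1)
  grads$decW1 <- grads$decW1 + tb1$dw; grads$decb1 <- grads$decb1 + tb1$db
  list(grads = grads, dcode = tb1$dx)
}

#' Softmax association score of the attribute branch
#'
#' @param code flattened bottleneck code vector.
#' @param w,b fully connected weights (2 x `length(code)`) and bias.
#' @return probability pair `(P(associated), P(not associated))`.
#' @export
branch2_score <- function(code, w, b) {
  as.vector(softmax_rows(matrix(w %*% as.vector(code) + b, nrow = 1)))
}

# one autoencoder loss + gradient pass over a batch
cae_loss_grad <- function(params, p_batch) {
  enc <- cae_encode(p_batch, params)
  dec <- cae_decode(enc$code, params, dim(p_batch)[1:2])
  nb <- dim(p_batch)[4]
  loss <- sum((p_batch - dec$phat)^2) / nb
  dphat <- 2 * (dec$phat - p_batch) / nb
  grads <- zero_grads(params)
  db <- cae_decode_bwd(dec, params, dphat, grads)
  eb <- cae_encode_bwd(enc, params, db$dcode, db$grads)
  list(loss = loss, grads = eb$grads)
}

# stage 1: pretrain the autoencoder on all training embeddings
cae_pretrain <- function(params, p_all, epochs = 100L, batch_size = 32L,
                         lr = 1e-3, verbose = FALSE) {
  st <- adam_init(params)
  n <- dim(p_all)[4]
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      lg <- cae_loss_grad(params, p_all[, , , idx, drop = FALSE])
      tot <- tot + lg$loss * length(idx)
      upd <- adam_step(params, lg$grads, st, lr = lr)
      params <- upd$params; st <- upd$state
    }
    hist[ep] <- tot / n
    if (verbose && ep %% 20L == 0L)
      message(sprintf("  CAE epoch %d: loss_auto %.5f", ep, hist[ep]))
  }
  list(params = params, history = hist)
}

# stage 2: train the classifier head with encoder fine-tuning on loss_PA
b2_train_head <- function(params, p_all, labels, epochs = 100L,
                          batch_size = 32L, lr = 1e-3, verbose = FALSE) {
  code_dim <- prod(dim(cae_encode(p_all[, , , 1, drop = FALSE], params)$code)[1:3])
  params$headW <- glorot(c(2L, code_dim), code_dim, 2L)
  params$headb <- numeric(2L)
  st <- adam_init(params)
  n <- dim(p_all)[4]
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      pb <- p_all[, , , idx, drop = FALSE]
      enc <- cae_encode(pb, params)
      zmat <- matrix(enc$code, ncol = length(idx))
      logits <- t(params$headW %*% zmat + params$headb)
      ce <- softmax_ce(logits, labels[idx])
      tot <- tot + ce$loss
      grads <- zero_grads(params)
      grads$headW <- grads$headW + t(ce$dlogits) %*% t(zmat)
      grads$headb <- grads$headb + colSums(ce$dlogits)
      dcode <- array(t(params$headW) %*% t(ce$dlogits), dim(enc$code))
      eb <- cae_encode_bwd(enc, params, dcode, grads)
      upd <- adam_step(params, eb$grads, st, lr = lr)
      params <- upd$params; st <- upd$state
    }
    hist[ep] <- tot / n
    if (verbose && ep %% 20L == 0L)
      message(sprintf("  branch 2 epoch %d: mean CE %.4f", ep, hist[ep]))
  }
  list(params = params, history = hist)
}

# score pairs: returns P(associated) from the attribute branch
b2_score_pairs <- function(params, p_all, chunk = 256L) {
  n <- dim(p_all)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    enc <- cae_encode(p_all[, , , idx, drop = FALSE], params)
    zmat <- matrix(enc$code, ncol = length(idx))
    logits <- t(params$headW %*% zmat + params$headb)
    out[idx] <- softmax_rows(logits)[, 1]
  }
  out
}

# build the (2, n_nodes, 3, n_pairs) embedding stack for a pair list, with
# per-pair label masking
b2_embeddings <- function(nets, pairs, mask = TRUE) {
  nr <- attr(nets[[1]], "n_drugs")
  n_nodes <- nrow(nets[[1]])
  n <- nrow(pairs)
  out <- array(0, c(2L, n_nodes, 3L, n))
  for (m in 1:3) {
    drow <- t(nets[[m]][pairs[, 1], , drop = FALSE])      # n_nodes x n
    jrow <- t(nets[[m]][nr + pairs[, 2], , drop = FALSE])
    out[1, , m, ] <- drow
    out[2, , m, ] <- jrow
  }
  if (mask) {
    for (n_i in seq_len(n)) {
      out[1, nr + pairs[n_i, 2], , n_i] <- 0
      out[2, pairs[n_i, 1], , n_i] <- 0
    }
  }
  out
}
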