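# Topology branch: encode the meta-path neighbor topology of a drug-disease
# pair.  Neighbor attribute vectors are mean-aggregated per node/order/type,
# projected to an N_f-dimensional space by fully connected ReLU layers,
# fused across orders by neighbor-scale-level attention and across neighbor
# types by neighbor-topology-level attention; the six per-network node
# representations form a 2 x 3*N_f pair matrix scored by a small CNN with a
# softmax head.

#' Mean-aggregate a set of neighbor attribute vectors
#'
#' @param vectors nonempty list of numeric vectors of equal length (the
#'   attribute rows of a node's retained neighbors).
#' @return the element-wise arithmetic mean.
#' @export
mean_aggregate <- function(vectors) {
  if (!length(vectors)) stop("cannot aggregate an empty neighbor list")
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L) stop("attribute vectors differ in length")
  Reduce(`+`, vectors) / length(vectors)
}

#' Fully connected ReLU projection
#'
#' Projects an aggregated neighbor attribute vector into the low-dimensional
#' neighbor feature space: `ReLU(W %*% h + b)`.
#'
#' @param h numeric input vector.
#' @param w weight matrix (`n_f` rows, `length(h)` columns).
#' @param b bias vector of length `n_f`.
#' @export
project_fc <- function(h, w, b) {
  if (any(!is.finite(h))) stop("non-finite input to projection")
  as.vector(relu(w %*% h + b))
}

# shared attention core: inputs as columns of an n_f x n matrix per branch.
# ulist: list of n_f x n matrices (one per branch being weighted);
# scores s_t = h . tanh(W u_t + b), alpha = softmax over branches,
# out = sum_t alpha_t * u_t.
attn_forward <- function(ulist, w, b, h) {
  kk <- length(ulist)
  n <- ncol(ulist[[1]])
  acts <- lapply(ulist, function(u) tanh(w %*% u + b))
  s <- do.call(rbind, lapply(acts, function(a) colSums(h * a)))  # kk x n
  smax <- apply(s, 2, max)
  e <- exp(s - rep(smax, each = kk))
  alpha <- e / rep(colSums(e), each = kk)
  out <- matrix(0, nrow(ulist[[1]]), n)
  for (t in seq_len(kk)) out <- out + ulist[[t]] * rep(alpha[t, ], each = nrow(out))
  list(out = out, alpha = alpha, acts = acts)
}

attn_bwd <- function(ulist, w, b, h, cache, g) {
  kk <- length(ulist)
  alpha <- cache$alpha
  dalpha <- do.call(rbind, lapply(ulist, function(u) colSums(g * u)))  # kk x n
  wsum <- colSums(alpha * dalpha)
  ds <- alpha * (dalpha - rep(wsum, each = kk))                        # kk x n
  dw <- matrix(0, nrow(w), ncol(w)); db <- numeric(length(b)); dh <- numeric(length(h))
  dulist <- vector("list", kk)
  for (t in seq_len(kk)) {
    a <- cache$acts[[t]]
    dh <- dh + as.vector(a %*% ds[t, ])
    dz <- (h %o% ds[t, ]) * (1 - a^2)
    dw <- dw + tcrossprod(dz, ulist[[t]])
    db <- db + rowSums(dz)
    dulist[[t]] <- g * rep(alpha[t, ], each = nrow(g)) + crossprod(w, dz)
  }
  list(dulist = dulist, dw = dw, db = db, dh = dh)
}

#' Neighbor-scale-level attention
#'
#' Fuses a node's order-1..K neighbor feature vectors of one type into a
#' single representation with learned softmax weights
#' `alpha_k = softmax(h . tanh(W u_k + b))`.
#'
#' @param features list of K numeric vectors (one per order).
#' @param params list with elements `w` (matrix), `b`, `h` (vectors).
#' @return list with `out` (weighted combination) and `alpha` (the K weights,
#'   summing to 1).
#' @export
scale_attention <- function(features, params) {
  res <- attn_forward(lapply(features, function(u) matrix(u, ncol = 1)),
                      params$w, params$b, params$h)
  list(out = as.vector(res$out), alpha = as.vector(res$alpha))
}

#' Neighbor-topology-level attention
#'
#' Fuses the drug-type and disease-type neighbor topology representations of
#' a node with a two-way learned softmax weighting.
#'
#' @param u_r,u_d the two same-length representations.
#' @param params list with elements `w`, `b`, `h`.
#' @return list with `out` and `alpha` (length 2, summing to 1; drug first).
#' @export
topology_attention <- function(u_r, u_d, params) {
  scale_attention(list(u_r, u_d), params)
}

#' Assemble the pair feature matrix of the topology branch
#'
#' @param u_drug,u_disease lists of three `n_f`-vectors (one per
#'   heterogeneous network, in network order).
#' @return a `2 x 3*n_f` matrix: drug row on top, disease row below.
#' @export
build_pair_matrix <- function(u_drug, u_disease) {
  if (length(u_drug) != 3L || length(u_disease) != 3L)
    stop("need one representation per heterogeneous network (3 each)")
  lens <- c(lengths(u_drug), lengths(u_disease))
  if (length(unique(lens)) != 1L)
    stop("representation dimensions differ: ", paste(lens, collapse = ", "))
  rbind(unlist(u_drug, use.names = FALSE), unlist(u_disease, use.names = FALSE))
}

#' CNN encoding of a pair feature matrix
#'
#' Zero-pads the `2 x 3*n_f` pair matrix by one ring, applies `n_filters`
#' convolution filters (ReLU) and a stride-1 max-pooling, and flattens the
#' pooled maps into the topology code vector.
#'
#' @param s pair feature matrix from [build_pair_matrix()].
#' @param conv_w filter array `(kh, kw, 1, n_filters)`.
#' @param conv_b filter bias vector.
#' @param pool pooling kernel, default `c(2, 2)`.
#' @return numeric code vector.
#' @export
cnn_encode <- function(s, conv_w, conv_b, pool = c(2, 2)) {
  x <- array(s, c(nrow(s), ncol(s), 1, 1))
  z <- relu(nn_conv(nn_pad(x, 1L), conv_w, conv_b))
  as.vector(nn_maxpool(z, pool[1], pool[2]))
}

#' Softmax association score of the topology branch
#'
#' @param z code vector from [cnn_encode()].
#' @param w,b fully connected weights (2 x `length(z)`) and bias (length 2).
#' @return probability pair `(P(associated), P(not associated))`.
#' @export
branch1_score <- function(z, w, b) {
  as.vector(softmax_rows(matrix(w %*% z + b, nrow = 1)))
}

# ---- vectorized training machinery ---------------------------------------

# Precompute mean-aggregated neighbor attribute matrices for every node.
# properties: list of 3 drug property matrices (rows = drugs); disease_sim:
# the D matrix whose rows are disease attribute vectors; nsets_list: one
# neighbor_sets object per heterogeneous network.  Returns
# feats[[m]]$hr[[k]] (attrdim_m x n_nodes) and $hd[[k]] (n_dis x n_nodes);
# empty neighbor lists aggregate to the zero vector.
b1_features <- function(properties, disease_sim, nsets_list) {
  agg <- function(attr_mat, idx_lists) {
    out <- matrix(0, ncol(attr_mat), length(idx_lists))
    for (v in seq_along(idx_lists)) {
      idx <- idx_lists[[v]]
      if (length(idx))
        out[, v] <- colMeans(attr_mat[idx, , drop = FALSE])
    }
    out
  }
  lapply(seq_len(3), function(m) {
    tm <- properties[[m]]
    nsets <- nsets_list[[m]]
    per_k <- lapply(seq_len(nsets$k_max), function(k) {
      drug_nb <- c(nsets$drug[[k]]$same, nsets$disease[[k]]$cross)   # drug-type
      dis_nb  <- c(nsets$drug[[k]]$cross, nsets$disease[[k]]$same)   # disease-type
      list(hr = agg(tm, drug_nb), hd = agg(disease_sim, dis_nb))
    })
    list(hr = lapply(per_k, `[[`, "hr"), hd = lapply(per_k, `[[`, "hd"))
  })
}

b1_init <- function(attr_dims, n_dis, n_f, kk, n_filters = 16L, kernel = c(2L, 2L)) {
  p <- list()
  for (m in 1:3) for (k in seq_len(kk)) {
    p[[sprintf("WR.%d.%d", m, k)]] <- glorot(c(n_f, attr_dims[m]), attr_dims[m], n_f)
    p[[sprintf("bR.%d.%d", m, k)]] <- numeric(n_f)
    p[[sprintf("WD.%d.%d", m, k)]] <- glorot(c(n_f, n_dis), n_dis, n_f)
    p[[sprintf("bD.%d.%d", m, k)]] <- numeric(n_f)
  }
  for (ct in c("r", "d")) for (mech in c("sc", "tp")) {
    p[[paste0(mech, "W.", ct)]] <- glorot(c(n_f, n_f), n_f, n_f)
    p[[paste0(mech, "b.", ct)]] <- numeric(n_f)
    p[[paste0(mech, "h.", ct)]] <- glorot(n_f, n_f, 1)
  }
  zlen <- n_filters * (4L - kernel[1] + 1L - 1L) * (3L * n_f + 2L - kernel[2] + 1L - 1L)
  p[["convW"]] <- glorot(c(kernel[1], kernel[2], 1L, n_filters),
                         prod(kernel), n_filters)
  p[["convb"]] <- numeric(n_filters)
  p[["headW"]] <- glorot(c(2L, zlen), zlen, 2L)
  p[["headb"]] <- numeric(2L)
  p
}

# node-level forward: final per-network node representations for all nodes.
# Returns u[[m]] (n_f x n_nodes) and caches for backward.
b1_nodes_forward <- function(params, feats, nr, kk, n_f) {
  n_nodes <- ncol(feats[[1]]$hr[[1]])
  is_drug <- seq_len(n_nodes) <= nr
  cols <- list(r = which(is_drug), d = which(!is_drug))
  u <- vector("list", 3)
  cache <- vector("list", 3)
  for (m in 1:3) {
    zR <- uR <- zD <- uD <- vector("list", kk)
    for (k in seq_len(kk)) {
      zR[[k]] <- params[[sprintf("WR.%d.%d", m, k)]] %*% feats[[m]]$hr[[k]] +
        params[[sprintf("bR.%d.%d", m, k)]]
      uR[[k]] <- relu(zR[[k]])
      zD[[k]] <- params[[sprintf("WD.%d.%d", m, k)]] %*% feats[[m]]$hd[[k]] +
        params[[sprintf("bD.%d.%d", m, k)]]
      uD[[k]] <- relu(zD[[k]])
    }
    um <- matrix(0, n_f, n_nodes)
    mcache <- list(zR = zR, uR = uR, zD = zD, uD = uD, sc = list(), tp = list())
    for (ct in c("r", "d")) {
      idx <- cols[[ct]]
      if (!length(idx)) next
      uRk <- lapply(uR, function(x) x[, idx, drop = FALSE])
      uDk <- lapply(uD, function(x) x[, idx, drop = FALSE])
      scR <- attn_forward(uRk, params[[paste0("scW.", ct)]],
                          params[[paste0("scb.", ct)]], params[[paste0("sch.", ct)]])
      scD <- attn_forward(uDk, params[[paste0("scW.", ct)]],
                          params[[paste0("scb.", ct)]], params[[paste0("sch.", ct)]])
      tp <- attn_forward(list(scR$out, scD$out), params[[paste0("tpW.", ct)]],
                         params[[paste0("tpb.", ct)]], params[[paste0("tph.", ct)]])
      um[, idx] <- tp$out
      mcache$sc[[ct]] <- list(R = scR, D = scD, uRk = uRk, uDk = uDk)
      mcache$tp[[ct]] <- tp
    }
    u[[m]] <- um
    cache[[m]] <- mcache
  }
  list(u = u, cache = cache, cols = cols)
}

# backward through the node-level stack given du[[m]] (n_f x n_nodes)
b1_nodes_bwd <- function(params, feats, nodes, du, nr, kk, n_f, grads) {
  cols <- nodes$cols
  for (m in 1:3) {
    mc <- nodes$cache[[m]]
    duR <- lapply(seq_len(kk), function(k) matrix(0, n_f, ncol(du[[m]])))
    duD <- lapply(seq_len(kk), function(k) matrix(0, n_f, ncol(du[[m]])))
    for (ct in c("r", "d")) {
      idx <- cols[[ct]]
      if (!length(idx)) next
      g <- du[[m]][, idx, drop = FALSE]
      sc <- mc$sc[[ct]]
      tpb <- attn_bwd(list(sc$R$out, sc$D$out), params[[paste0("tpW.", ct)]],
                      params[[paste0("tpb.", ct)]], params[[paste0("tph.", ct)]],
                      mc$tp[[ct]], g)
      grads[[paste0("tpW.", ct)]] <- grads[[paste0("tpW.", ct)]] + tpb$dw
      grads[[paste0("tpb.", ct)]] <- grads[[paste0("tpb.", ct)]] + tpb$db
      grads[[paste0("tph.", ct)]] <- grads[[paste0("tph.", ct)]] + tpb$dh
      scRb <- attn_bwd(sc$uRk, params[[paste0("scW.", ct)]],
                       params[[paste0("scb.", ct)]], params[[paste0("sch.", ct)]],
                       sc$R, tpb$dulist[[1]])
      scDb <- attn_bwd(sc$uDk, params[[paste0("scW.", ct)]],
                       params[[paste0("scb.", ct)]], params[[paste0("sch.", ct)]],
                       sc$D, tpb$dulist[[2]])
      grads[[paste0("scW.", ct)]] <- grads[[paste0("scW.", ct)]] + scRb$dw + scDb$dw
      grads[[paste0("scb.", ct)]] <- grads[[paste0("scb.", ct)]] + scRb$db + scDb$db
      grads[[paste0("sch.", ct)]] <- grads[[paste0("sch.", ct)]] + scRb$dh + scDb$dh
      for (k in seq_len(kk)) {
        duR[[k]][, idx] <- duR[[k]][, idx, drop = FALSE] + scRb$dulist[[k]]
        duD[[k]][, idx] <- duD[[k]][, idx, drop = FALSE] + scDb$dulist[[k]]
      }
    }
    for (k in seq_len(kk)) {
      dzR <- relu_bwd(mc$zR[[k]], duR[[k]])
      dzD <- relu_bwd(mc$zD[[k]], duD[[k]])
      grads[[sprintf("WR.%d.%d", m, k)]] <- grads[[sprintf("WR.%d.%d", m, k)]] +
        tcrossprod(dzR, feats[[m]]$hr[[k]])
      grads[[sprintf("bR.%d.%d", m, k)]] <- grads[[sprintf("bR.%d.%d", m, k)]] +
        rowSums(dzR)
      grads[[sprintf("WD.%d.%d", m, k)]] <- grads[[sprintf("WD.%d.%d", m, k)]] +
        tcrossprod(dzD, feats[[m]]$hd[[k]])
      grads[[sprintf("bD.%d.%d", m, k)]] <- grads[[sprintf("bD.%d.%d", m, k)]] +
        rowSums(dzD)
    }
  }
  grads
}

# pair-level forward: logits (B x 2) for pairs (matrix with columns i, j)
b1_pairs_forward <- function(params, nodes, pairs, nr, n_f, pool = c(2L, 2L)) {
  b <- nrow(pairs)
  u_all <- rbind(nodes$u[[1]], nodes$u[[2]], nodes$u[[3]])    # 3*n_f x n_nodes
  s <- array(0, c(2L, 3L * n_f, 1L, b))
  s[1, , 1, ] <- u_all[, pairs[, 1], drop = FALSE]
  s[2, , 1, ] <- u_all[, nr + pairs[, 2], drop = FALSE]
  sp <- nn_pad(s, 1L)
  zpre <- nn_conv(sp, params$convW, params$convb)
  zact <- relu(zpre)
  pl <- nn_maxpool(zact, pool[1], pool[2])
  zmat <- matrix(pl, ncol = b)
  logits <- t(params$headW %*% zmat + params$headb)
  list(logits = logits, s = s, sp = sp, zpre = zpre, zact = zact,
       pl = pl, zmat = zmat)
}

b1_pairs_bwd <- function(params, nodes, cache, pairs, dlogits, nr, n_f,
                         pool = c(2L, 2L), grads) {
  b <- nrow(pairs)
  grads$headW <- grads$headW + t(dlogits) %*% t(cache$zmat)
  grads$headb <- grads$headb + colSums(dlogits)
  dz <- t(params$headW) %*% t(dlogits)
  dpl <- array(dz, dim(cache$pl))
  dzact <- nn_maxpool_bwd(cache$zact, cache$pl, dpl, pool[1], pool[2])
  dzpre <- relu_bwd(cache$zpre, dzact)
  cb <- nn_conv_bwd(cache$sp, params$convW, dzpre)
  grads$convW <- grads$convW + cb$dw
  grads$convb <- grads$convb + cb$db
  ds <- nn_pad_bwd(cb$dx, 1L)
  n_nodes <- ncol(nodes$u[[1]])
  ds1 <- matrix(ds[1, , 1, ], 3L * n_f, b)     # drug-row gradients per pair
  ds2 <- matrix(ds[2, , 1, ], 3L * n_f, b)     # disease-row gradients
  # accumulate per-node gradients: sum pair columns that hit the same node
  acc <- function(dmat, node_idx) {
    g <- rowsum(t(dmat), group = node_idx)     # unique-node x 3*n_f
    out <- matrix(0, 3L * n_f, n_nodes)
    out[, as.integer(rownames(g))] <- t(g)
    out
  }
  du_all <- acc(ds1, pairs[, 1]) + acc(ds2, nr + pairs[, 2])
  du <- lapply(1:3, function(m) du_all[(m - 1L) * n_f + seq_len(n_f), , drop = FALSE])
  list(grads = grads, du = du)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# one full forward + backward over a set of pairs; returns loss and grads
b1_loss_grad <- function(params, feats, pairs, labels, nr, kk, n_f,
                         pool = c(2L, 2L)) {
  nodes <- b1_nodes_forward(params, feats, nr, kk, n_f)
  pc <- b1_pairs_forward(params, nodes, pairs, nr, n_f, pool)
  ce <- softmax_ce(pc$logits, labels)
  grads <- zero_grads(params)
  pb <- b1_pairs_bwd(params, nodes, pc, pairs, ce$dlogits, nr, n_f, pool, grads)
  grads <- b1_nodes_bwd(params, feats, nodes, pb$du, nr, kk, n_f, pb$grads)
  list(loss = ce$loss, grads = grads, probs = ce$probs)
}

# minibatch Adam training of branch 1
b1_train <- function(params, feats, pairs, labels, nr, kk, n_f,
                     epochs = 100L, batch_size = 32L, lr = 1e-3,
                     pool = c(2L, 2L), verbose = FALSE) {
  st <- adam_init(params)
  n <- nrow(pairs)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      lg <- b1_loss_grad(params, feats, pairs[idx, , drop = FALSE],
                         labels[idx], nr, kk, n_f, pool)
      tot <- tot + lg$loss
      upd <- adam_step(params, lg$grads, st, lr = lr)
      params <- upd$params; st <- upd$state
    }
    hist[ep] <- tot / n
    if (verbose && ep %% 10L == 0L)
      message(sprintf("  branch 1 epoch %d: mean CE %.4f", ep, hist[ep]))
  }
  list(params = params, history = hist)
}

# score pairs with trained branch-1 parameters; returns P(associated)
b1_score_pairs <- function(params, feats, pairs, nr, kk, n_f,
                           pool = c(2L, 2L), chunk = 512L) {
  nodes <- b1_nodes_forward(params, feats, nr, kk, n_f)
  n <- nrow(pairs)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    pc <- b1_pairs_forward(params, nodes, pairs[idx, , drop = FALSE], nr, n_f, pool)
    out[idx] <- softmax_rows(pc$logits)[, 1]
  }
  out
}
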