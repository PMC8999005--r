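test_that("mean aggregation averages neighbor attribute vectors", {
  expect_equal(mean_aggregate(list(c(2, 4), c(4, 8), c(0, 0))), c(2, 4))
  expect_equal(mean_aggregate(list(c(1, 2, 3))), c(1, 2, 3))
  expect_error(mean_aggregate(list()), "empty")
  expect_error(mean_aggregate(list(c(1, 2), c(1, 2, 3))), "length")
})

test_that("fully connected projection applies ReLU(W h + b)", {
  w <- rbind(c(1, -1), c(0.5, 0.5))
  expect_equal(project_fc(c(1, 2), w, c(0, 0)), c(0, 1.5))     # -1 clipped to 0
  expect_equal(project_fc(c(1, 2), w, c(2, -2)), c(1, 0))
  expect_error(project_fc(c(1, NA), w, c(0, 0)), "finite")
})

test_that("attention mechanisms produce softmax weights and convex mixes", {
  set.seed(10)
  n_f <- 4
  params <- list(w = matrix(rnorm(n_f * n_f), n_f), b = rnorm(n_f), h = rnorm(n_f))
  u1 <- rnorm(n_f); u2 <- rnorm(n_f)
  res <- scale_attention(list(u1, u2), params)
  expect_equal(sum(res$alpha), 1)
  expect_true(all(res$alpha > 0))
  expect_equal(res$out, res$alpha[1] * u1 + res$alpha[2] * u2)

  # identical inputs get equal weights and are returned unchanged
  same <- scale_attention(list(u1, u1), params)
  expect_equal(same$alpha, c(0.5, 0.5))
  expect_equal(same$out, u1)

  # a single branch passes through with weight 1
  one <- scale_attention(list(u1), params)
  expect_equal(one$alpha, 1)
  expect_equal(one$out, u1)

  # attention scores ln 2 and 0 give softmax weights 2/3, 1/3
  expect_equal(ns$softmax_rows(rbind(c(log(2), 0)))[1, ], c(2 / 3, 1 / 3))

  tp <- topology_attention(u1, u2, params)
  expect_equal(tp$out, res$out)
})

test_that("pair matrix stacks three per-network representations per row", {
  s <- build_pair_matrix(list(c(1, 1), c(2, 2), c(3, 3)),
                         list(c(4, 4), c(5, 5), c(6, 6)))
  expect_identical(dim(s), c(2L, 6L))
  expect_equal(s[1, ], c(1, 1, 2, 2, 3, 3))
  expect_equal(s[2, ], c(4, 4, 5, 5, 6, 6))
  expect_error(build_pair_matrix(list(1, 2), list(3, 4, 5)), "3")
  expect_error(build_pair_matrix(list(1, 2, c(3, 4)), list(5, 6, 7)), "differ")
})

test_that("CNN encoding has the documented code length", {
  set.seed(11)
  n_f <- 4L; n_filters <- 16L
  s <- matrix(rnorm(2 * 3 * n_f), 2)
  conv_w <- array(rnorm(2 * 2 * 1 * n_filters), c(2, 2, 1, n_filters))
  z <- cnn_encode(s, conv_w, rnorm(n_filters))
  # padded to 4 x (3*n_f + 2); conv 2x2 -> 3 x (3*n_f + 1); pool -> 2 x 3*n_f
  expect_length(z, n_filters * 2 * 3 * n_f)
  expect_length(z, 384L)
  # zero input with zero bias encodes to zeros
  z0 <- cnn_encode(matrix(0, 2, 12), conv_w, numeric(n_filters))
  expect_equal(z0, rep(0, 384))

  p <- branch1_score(z, matrix(rnorm(2 * length(z)) * 0.05, 2), rnorm(2))
  expect_equal(sum(p), 1)
  expect_true(all(p > 0 & p < 1))
})

test_that("full branch-1 gradient matches finite differences", {
  set.seed(12)
  sim <- tiny_dataset()
  dsim <- dag_similarity(sim$dags)
  nets <- ns$dd_networks(sim$assoc, sim$properties, dsim)
  nsets <- lapply(nets, neighbor_sets, k_max = 2L, n_keep = c(4L, 8L))
  feats <- ns$b1_features(sim$properties, dsim, nsets)
  n_f <- 3L
  params <- ns$b1_init(vapply(sim$properties, ncol, 0L), ncol(sim$assoc),
                       n_f, 2L, n_filters = 2L)
  pairs <- cbind(c(1L, 2L, 3L), c(2L, 5L, 7L))
  labels <- c(1L, 0L, 1L)
  lg <- ns$b1_loss_grad(params, feats, pairs, labels, nrow(sim$assoc), 2L, n_f)
  expect_true(is.finite(lg$loss))
  loss_fn <- function(p) ns$b1_loss_grad(p, feats, pairs, labels,
                                         nrow(sim$assoc), 2L, n_f)$loss
  for (nm in c("WR.1.1", "WD.2.2", "scW.r", "sch.d", "tpW.r", "tpb.d",
               "convW", "convb", "headW", "headb")) {
    f <- function(v) { p <- params; p[[nm]][] <- v; loss_fn(p) }
    g_num <- num_grad(f, as.vector(params[[nm]]), eps = 1e-5)
    g_ana <- as.vector(lg$grads[[nm]])
    denom <- max(abs(g_num), abs(g_ana), 1e-8)
    expect_lt(max(abs(g_num - g_ana)) / denom, 1e-4)
  }
})

test_that("branch-1 training is deterministic given a seed and reduces loss", {
  sim <- tiny_dataset()
  dsim <- dag_similarity(sim$dags)
  nets <- ns$dd_networks(sim$assoc, sim$properties, dsim)
  nsets <- lapply(nets, neighbor_sets, k_max = 2L, n_keep = c(4L, 8L))
  feats <- ns$b1_features(sim$properties, dsim, nsets)
  pos <- which(sim$assoc == 1, arr.ind = TRUE)[1:10, ]
  neg <- which(sim$assoc == 0, arr.ind = TRUE)[1:10, ]
  pairs <- rbind(pos, neg); labels <- rep(c(1L, 0L), each = 10)
  run <- function() {
    set.seed(99)
    params <- ns$b1_init(vapply(sim$properties, ncol, 0L), ncol(sim$assoc), 6L, 2L,
                         n_filters = 4L)
    ns$b1_train(params, feats, pairs, labels, nrow(sim$assoc), 2L, 6L,
                epochs = 8L, batch_size = 8L)
  }
  a <- run(); b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_lt(a$history[8], a$history[1])
  sc <- ns$b1_score_pairs(a$params, feats, pairs, nrow(sim$assoc), 2L, 6L)
  expect_true(all(sc >= 0 & sc <= 1))
})
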