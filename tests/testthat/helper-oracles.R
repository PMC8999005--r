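# Independent oracles and small fixture builders used across the suite.
# These deliberately use naive loops/recursion so they share no code paths
# with the package implementation they check.

ns <- asNamespace("ddpred")

# central finite-difference gradient of scalar f at x (vector or array)
num_grad <- function(f, x, eps = 1e-6) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# explicit enumeration of every walk of exactly k steps from a global node
# index over the nonzero edges of u (self-loops excluded); returns the count
# of walks ending at each global node
brute_walk_counts <- function(u, start_global, k) {
  adj <- u > 0
  diag(adj) <- FALSE
  counts <- rep(0, nrow(u))
  rec <- function(v, steps) {
    if (steps == 0L) {
      counts[v] <<- counts[v] + 1
      return(invisible(NULL))
    }
    for (w in which(adj[v, ])) rec(w, steps - 1L)
  }
  rec(start_global, k)
  counts
}

# pairwise-comparison AUC: concordant pairs + half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# explicit threshold-loop step-curve AUPR
aupr_oracle <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0; area <- 0
  for (th in thresholds) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1); fp <- sum(labels[sel] == 0)
    recall <- tp / sum(labels == 1)
    area <- area + (recall - prev_recall) * tp / (tp + fp)
    prev_recall <- recall
  }
  area
}

topk_oracle <- function(scores, labels, k) {
  ord <- order(-scores, seq_along(scores))
  sum(labels[ord][seq_len(min(k, length(ord)))]) / sum(labels)
}

# brute-force per-pair cosine loop
cosine_oracle <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(x[i, ]^2)); nj <- sqrt(sum(x[j, ]^2))
    s[i, j] <- if (i == j) 1 else if (ni == 0 || nj == 0) 0
               else sum(x[i, ] * x[j, ]) / (ni * nj)
  }
  s
}

# small random heterogeneous network for property tests
random_hetero <- function(nr, nd, p_edge = 0.3) {
  r <- matrix(0, nr, nr)
  upper <- upper.tri(r)
  r[upper] <- ifelse(runif(sum(upper)) < p_edge, runif(sum(upper)), 0)
  r <- r + t(r); diag(r) <- 1
  d <- matrix(0, nd, nd)
  upper <- upper.tri(d)
  d[upper] <- ifelse(runif(sum(upper)) < p_edge, runif(sum(upper)), 0)
  d <- d + t(d); diag(d) <- 1
  a <- matrix(rbinom(nr * nd, 1, p_edge), nr, nd)
  hetero_network(r, a, d)
}

# tiny complete dataset used by several end-to-end tests
tiny_dataset <- function(seed = 3) {
  simulate_dd_data(n_drugs = 14, n_diseases = 10, n_features = c(12, 15, 18),
                   rank = 2, density = 0.2, noise = 0.05, seed = seed)
}

tiny_control <- function(...) {
  args <- list(n_f = 12, n_neighbors = c(4L, 8L), epochs = 12L,
               epochs_cae = 12L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(dd_control, args)
}
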