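#' Control parameters for model fitting
#'
#' Collects and validates every tunable of the two-branch predictor.
#'
#' @param n_f dimension of the neighbor topology representations.
#' @param k_max largest meta-path order.
#' @param n_neighbors retained neighbors per type at each order
#'   (length `k_max`).
#' @param n_filters,kernel convolution filters and kernel of the topology
#'   branch CNN (pooling is fixed at stride-1 2x2).
#' @param enc_channels,dec_channels channel widths of the CAE encoder's two
#'   conv layers and the first two decoder tconv layers.
#' @param lambda mixing weight of the topology-branch score in `[0, 1]`.
#' @param lr Adam learning rate (all losses).
#' @param epochs training epochs per branch classifier.
#' @param epochs_cae autoencoder pretraining epochs.
#' @param batch_size minibatch size.
#' @param neg_ratio sampled training negatives per positive.
#' @param n_folds cross-validation fold count.
#' @param verbose print training progress.
#' @return validated named list of class `"dd_control"`.
#' @export
dd_control <- function(n_f = 32L, k_max = 2L, n_neighbors = c(10L, 20L),
                       n_filters = 16L, kernel = c(2L, 2L),
                       enc_channels = c(4L, 8L), dec_channels = c(4L, 2L),
                       lambda = 0.5, lr = 1e-3, epochs = 15L, epochs_cae = 8L,
                       batch_size = 32L, neg_ratio = 1, n_folds = 5L,
                       verbose = FALSE) {
  if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]")
  if (length(n_neighbors) != k_max) stop("`n_neighbors` must have `k_max` entries")
  if (any(n_neighbors < 1)) stop("`n_neighbors` entries must be >= 1")
  if (n_f < 1 || n_filters < 1 || any(kernel < 1)) stop("network sizes must be >= 1")
  if (lr <= 0) stop("`lr` must be positive")
  if (epochs < 1 || epochs_cae < 1 || batch_size < 1) stop("training lengths must be >= 1")
  if (neg_ratio <= 0) stop("`neg_ratio` must be positive")
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  structure(list(n_f = as.integer(n_f), k_max = as.integer(k_max),
                 n_neighbors = as.integer(n_neighbors),
                 n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 lambda = lambda, lr = lr, epochs = as.integer(epochs),
                 epochs_cae = as.integer(epochs_cae),
                 batch_size = as.integer(batch_size), neg_ratio = neg_ratio,
                 n_folds = as.integer(n_folds), verbose = isTRUE(verbose)),
            class = "dd_control")
}

# build the three heterogeneous networks from raw inputs
dd_networks <- function(assoc, properties, disease_sim) {
  lapply(properties, function(tm) {
    hetero_network(cosine_similarity(tm), assoc, disease_sim)
  })
}

#' Fit the two-branch drug-disease association predictor
#'
#' Builds the three drug-disease heterogeneous networks (cosine drug
#' similarities over the three property views, DAG-based disease similarity),
#' then trains the two scoring branches on the given (or sampled) training
#' pairs: the topology branch on meta-path neighbor sets with scale- and
#' topology-level attention and a CNN pair encoder, and the attribute branch
#' on CAE-encoded pairwise network rows.  Both branch classifiers minimize
#' cross-entropy with Adam; the autoencoder is pretrained on its
#' reconstruction loss first.
#'
#' @param assoc binary association matrix (drugs x diseases).  In
#'   cross-validation pass the training-fold matrix (test positives zeroed).
#' @param properties list of three binary drug property matrices.
#' @param disease_sim precomputed disease similarity matrix, or `NULL` to
#'   compute it from `disease_dag`.
#' @param disease_dag disease DAG collection (see [read_dag()]); used when
#'   `disease_sim` is `NULL`.
#' @param decay DAG semantic decay factor (used only with `disease_dag`).
#' @param train_pairs optional integer matrix of training pairs (columns
#'   drug, disease) with `train_labels`; by default all known associations
#'   plus `neg_ratio` sampled unknown pairs per positive.
#' @param train_labels binary labels for `train_pairs`.
#' @param control a [dd_control()] list.
#' @param seed integer seed making the fit reproducible.
#' @param branches train `"both"` (default) or a single branch.
#' @return an object of class `"ddpred"` with `predict`, `print`, `summary`,
#'   `coef` and `plot` methods.
#' @export
ddpred <- function(assoc, properties, disease_sim = NULL, disease_dag = NULL,
                   decay = 0.5, train_pairs = NULL, train_labels = NULL,
                   control = dd_control(), seed = NULL,
                   branches = c("both", "topology", "attribute")) {
  branches <- match.arg(branches)
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  # sub-seeds drawn up front so each stage is reproducible independently of
  # which branches are trained
  sub_seed <- sample.int(.Machine$integer.max, 3L)

  if (is.null(disease_sim)) {
    if (is.null(disease_dag)) stop("supply `disease_sim` or `disease_dag`")
    disease_sim <- dag_similarity(disease_dag, decay = decay,
                                  diseases = colnames(assoc))
  }
  diag(disease_sim) <- 1
  nets <- dd_networks(assoc, properties, disease_sim)
  nr <- nrow(assoc); nd <- ncol(assoc)

  if (is.null(train_pairs)) {
    set.seed(sub_seed[1])
    pos <- which(assoc == 1, arr.ind = TRUE)
    neg <- which(assoc == 0, arr.ind = TRUE)
    n_neg <- min(round(control$neg_ratio * nrow(pos)), nrow(neg))
    neg <- neg[sample.int(nrow(neg), n_neg), , drop = FALSE]
    train_pairs <- rbind(pos, neg)
    train_labels <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  }
  storage.mode(train_pairs) <- "integer"

  nsets <- lapply(nets, neighbor_sets, k_max = control$k_max,
                  n_keep = control$n_neighbors)
  fit <- list(call = cl, control = control, nets = nets, nsets = nsets,
              assoc = assoc, disease_sim = disease_sim, n_drugs = nr,
              n_diseases = nd, train_pairs = train_pairs,
              train_labels = train_labels, branches = branches,
              seeds = sub_seed)

  if (branches %in% c("both", "topology")) {
    set.seed(sub_seed[2])
    feats <- b1_features(properties, disease_sim, nsets)
    p1 <- b1_init(vapply(properties, ncol, integer(1)), nd, control$n_f,
                  control$k_max, control$n_filters, control$kernel)
    tr1 <- b1_train(p1, feats, train_pairs, train_labels, nr, control$k_max,
                    control$n_f, epochs = control$epochs,
                    batch_size = control$batch_size, lr = control$lr,
                    verbose = control$verbose)
    fit$branch1 <- list(params = tr1$params, feats = feats, history = tr1$history)
  }
  if (branches %in% c("both", "attribute")) {
    set.seed(sub_seed[3])
    p_all <- b2_embeddings(nets, train_pairs)
    p2 <- cae_init(control$enc_channels, control$dec_channels, control$kernel)
    pre <- cae_pretrain(p2, p_all, epochs = control$epochs_cae,
                        batch_size = control$batch_size, lr = control$lr,
                        verbose = control$verbose)
    tr2 <- b2_train_head(pre$params, p_all, train_labels,
                         epochs = control$epochs, batch_size = control$batch_size,
                         lr = control$lr, verbose = control$verbose)
    fit$branch2 <- list(params = tr2$params, history_auto = pre$history,
                        history = tr2$history)
  }
  class(fit) <- "ddpred"
  fit
}

#' Score drug-disease pairs with a fitted model
#'
#' @param object a fitted `"ddpred"` model.
#' @param pairs integer matrix of pairs to score (columns drug, disease);
#'   default: every pair.
#' @param lambda mixing weight override; defaults to the fitted control's
#'   value.  With a single trained branch the combined score is that branch's
#'   score.
#' @param ... unused.
#' @return data.frame with columns `drug`, `disease`, `score_nt` (topology),
#'   `score_pa` (attribute) and `score` (the lambda combination).
#' @export
predict.ddpred <- function(object, pairs = NULL, lambda = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(drug = seq_len(object$n_drugs),
                                   disease = seq_len(object$n_diseases)))
  }
  storage.mode(pairs) <- "integer"
  lambda <- lambda %||% object$control$lambda
  ctl <- object$control
  score_nt <- score_pa <- rep(NA_real_, nrow(pairs))
  if (!is.null(object$branch1))
    score_nt <- b1_score_pairs(object$branch1$params, object$branch1$feats,
                               pairs, object$n_drugs, ctl$k_max, ctl$n_f)
  if (!is.null(object$branch2)) {
    p_all <- b2_embeddings(object$nets, pairs)
    score_pa <- b2_score_pairs(object$branch2$params, p_all)
  }
  score <- if (is.null(object$branch2)) score_nt
           else if (is.null(object$branch1)) score_pa
           else combine_scores(score_nt, score_pa, lambda)
  data.frame(drug = pairs[, 1], disease = pairs[, 2],
             score_nt = score_nt, score_pa = score_pa, score = score)
}

#' @export
print.ddpred <- function(x, ...) {
  cat("Two-branch drug-disease association predictor\n")
  cat(sprintf("  %d drugs, %d diseases, %d known associations\n",
              x$n_drugs, x$n_diseases, sum(x$assoc)))
  cat(sprintf("  trained branches: %s; lambda = %.2f; n_f = %d; K = %d\n",
              x$branches, x$control$lambda, x$control$n_f, x$control$k_max))
  cat(sprintf("  training pairs: %d (%d positive)\n",
              nrow(x$train_pairs), sum(x$train_labels)))
  invisible(x)
}

#' @export
summary.ddpred <- function(object, ...) {
  print(object)
  if (!is.null(object$branch1))
    cat(sprintf("  topology branch final mean CE: %.4f (%d epochs)\n",
                utils::tail(object$branch1$history, 1),
                length(object$branch1$history)))
  if (!is.null(object$branch2)) {
    cat(sprintf("  CAE final loss_auto: %.4f (%d epochs)\n",
                utils::tail(object$branch2$history_auto, 1),
                length(object$branch2$history_auto)))
    cat(sprintf("  attribute branch final mean CE: %.4f (%d epochs)\n",
                utils::tail(object$branch2$history, 1),
                length(object$branch2$history)))
  }
  invisible(object)
}

#' @export
coef.ddpred <- function(object, ...) {
  list(topology = object$branch1$params, attribute = object$branch2$params)
}

#' @export
plot.ddpred <- function(x, ...) {
  hists <- list()
  if (!is.null(x$branch1)) hists$`topology CE` <- x$branch1$history
  if (!is.null(x$branch2)) {
    hists$`CAE reconstruction` <- x$branch2$history_auto
    hists$`attribute CE` <- x$branch2$history
  }
  old <- graphics::par(mfrow = c(1, length(hists)))
  on.exit(graphics::par(old))
  for (nm in names(hists))
    graphics::plot(hists[[nm]], type = "l", xlab = "epoch", ylab = "loss",
                   main = nm, ...)
  invisible(x)
}

#' Rank novel disease candidates per drug
#'
#' Scores every unknown (drug, disease) pair with the fitted model and
#' returns, per drug, the top candidates by combined score (known
#' associations never appear; ties are ordered by disease index).
#'
#' @param object a fitted `"ddpred"` model.
#' @param top number of candidates kept per drug.
#' @param lambda optional mixing weight override.
#' @return data.frame with columns `drug`, `rank`, `disease`, `score`,
#'   sorted by drug then rank.
#' @export
rank_candidates <- function(object, top = 30L, lambda = NULL) {
  unknown <- which(object$assoc == 0, arr.ind = TRUE)
  colnames(unknown) <- c("drug", "disease")
  sc <- predict(object, unknown, lambda = lambda)
  out <- lapply(seq_len(object$n_drugs), function(i) {
    rows <- sc[sc$drug == i, ]
    rows <- rows[order(-rows$score, rows$disease), ]
    rows <- rows[seq_len(min(top, nrow(rows))), ]
    if (!nrow(rows)) return(NULL)
    data.frame(drug = i, rank = seq_len(nrow(rows)),
               disease = rows$disease, score = rows$score)
  })
  do.call(rbind, out)
}
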