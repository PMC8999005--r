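#' Cross-entropy loss over probability pairs
#'
#' `-sum_n sum_c y_nc log p_nc` with one-hot labels; the column order of
#' `probs` is `(P(associated), P(not associated))`.  A zero probability at the
#' true class is clamped at `1e-12` and reported via a warning.
#'
#' @param probs numeric matrix (`n x 2`) of probability pairs, or a single
#'   pair as a length-2 vector.
#' @param labels binary vector (1 = associated).
#' @return the summed loss (additive over samples).
#' @export
cross_entropy <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  n <- nrow(probs)
  if (length(labels) != n) stop("labels must match the number of score pairs")
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-8))
    stop("each row of `probs` must be a probability pair")
  pt <- probs[cbind(seq_len(n), ifelse(labels == 1, 1L, 2L))]
  if (any(pt < 1e-12))
    warning(sum(pt < 1e-12), " zero probability(ies) at the true class clamped at 1e-12")
  -sum(log(pmax(pt, 1e-12)))
}

#' Combine the two branch scores
#'
#' `score = lambda * score_topology + (1 - lambda) * score_attribute`.
#'
#' @param score_nt,score_pa the `P(associated)` scores of the topology and
#'   attribute branches (vectors of equal length).
#' @param lambda mixing weight in `[0, 1]`.
#' @export
combine_scores <- function(score_nt, score_pa, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single number in [0, 1]")
  lambda * score_nt + (1 - lambda) * score_pa
}

#' Ranking metrics: AUC, AUPR, curves and top-k recall
#'
#' Builds the ROC curve (TPR vs FPR over all score thresholds) and integrates
#' it with the trapezoidal rule for the AUC; builds the precision-recall step
#' curve and sums `precision * delta-recall` for the AUPR; computes top-k
#' recall (the fraction of all positives ranked in the top k) for each
#' requested k.  Tied scores are grouped into a single threshold, so tied
#' positive/negative pairs contribute 1/2 to the AUC.
#'
#' @param scores numeric score vector (higher = more likely associated).
#' @param labels binary labels (1 = positive).
#' @param top_k integer vector of list lengths for top-k recall.
#' @param context optional name (e.g. a drug id) used in error messages.
#' @return list with `auc`, `aupr`, `roc` (data.frame threshold/fpr/tpr),
#'   `pr` (data.frame threshold/recall/precision), `top_k` (named vector),
#'   `n_pos`, `n_neg`.
#' @export
compute_metrics <- function(scores, labels, top_k = integer(0), context = NULL) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("need at least one positive and one negative label",
         if (!is.null(context)) paste0(" for ", context) else "")
  ord <- order(-scores, seq_along(scores))
  s <- scores[ord]; y <- labels[ord]
  # group tied scores into single thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  thr <- s[last]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  rec <- tp / npos
  prec <- tp / (tp + fp)
  aupr <- sum(diff(c(0, rec)) * prec)
  tk <- vapply(top_k, function(k) sum(y[seq_len(min(k, length(y)))]) / npos,
               numeric(1))
  names(tk) <- top_k
  list(auc = auc, aupr = aupr,
       roc = data.frame(threshold = thr, fpr = fpr[-1], tpr = tpr[-1]),
       pr = data.frame(threshold = thr, recall = rec, precision = prec),
       top_k = tk, n_pos = npos, n_neg = nneg)
}

#' Split known associations into cross-validation folds
#'
#' Positives (known associations) are partitioned into `n_folds` test sets;
#' each fold trains on the other folds' positives plus a seeded random sample
#' of unknown pairs (`neg_ratio` negatives per training positive) and tests on
#' the held-out positives plus every unknown pair not used as a training
#' negative in that fold.
#'
#' @param assoc binary association matrix (drugs x diseases).
#' @param n_folds number of folds (`>= 2`).
#' @param neg_ratio training negatives per training positive.
#' @return list of folds, each with integer pair matrices (columns `drug`,
#'   `disease`): `train_pos`, `train_neg`, `test_pos`, `test_neg`.
#' @export
make_folds <- function(assoc, n_folds = 5L, neg_ratio = 1) {
  check_binary_matrix(assoc, "association matrix")
  pos <- which(assoc == 1, arr.ind = TRUE)
  neg <- which(assoc == 0, arr.ind = TRUE)
  colnames(pos) <- colnames(neg) <- c("drug", "disease")
  npos <- nrow(pos)
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  if (npos < n_folds) stop("fewer positives (", npos, ") than folds (", n_folds, ")")
  fold_id <- sample(rep_len(seq_len(n_folds), npos))
  lapply(seq_len(n_folds), function(f) {
    test_pos <- pos[fold_id == f, , drop = FALSE]
    train_pos <- pos[fold_id != f, , drop = FALSE]
    n_neg_train <- min(round(neg_ratio * nrow(train_pos)), nrow(neg))
    neg_idx <- sample.int(nrow(neg), n_neg_train)
    list(train_pos = train_pos,
         train_neg = neg[neg_idx, , drop = FALSE],
         test_pos = test_pos,
         test_neg = neg[-neg_idx, , drop = FALSE])
  })
}
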