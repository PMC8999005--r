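#' Per-drug k-fold cross-validation of the predictor
#'
#' Partitions the known associations into folds; in each fold the model is
#' fitted on the training positives (the heterogeneous networks are rebuilt
#' from the training association matrix, with that fold's test positives
#' removed) plus sampled training negatives, and evaluated on the held-out
#' positives together with every unknown pair not used as a training
#' negative.  Reports pooled per-fold AUC/AUPR (averaged over folds), the
#' per-drug evaluation (per-drug metrics per fold, averaged over
#' folds then over drugs) and per-drug top-k recalls.
#'
#' @inheritParams ddpred
#' @param top_k list lengths for per-drug top-k recall.
#' @param seed integer seed controlling the fold split, negative sampling and
#'   all weight initialization.
#' @return object of class `"dd_cv"`: list with `fold_metrics` (data.frame),
#'   `mean_auc`, `mean_aupr`, `prevalence` (mean test-pool positive rate),
#'   `per_drug` (data.frame of per-drug fold-averaged AUC/AUPR),
#'   `per_drug_mean_auc`, `per_drug_mean_aupr`, `top_k` (named mean recalls),
#'   `scores` (per-fold test score tables) and `control`.
#' @export
dd_cv <- function(assoc, properties, disease_sim = NULL, disease_dag = NULL,
                  decay = 0.5, control = dd_control(), top_k = c(10L, 20L, 30L),
                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, control$n_folds + 1L)
  set.seed(fold_seeds[control$n_folds + 1L])
  folds <- make_folds(assoc, control$n_folds, control$neg_ratio)
  if (is.null(disease_sim)) {
    if (is.null(disease_dag)) stop("supply `disease_sim` or `disease_dag`")
    disease_sim <- dag_similarity(disease_dag, decay = decay,
                                  diseases = colnames(assoc))
  }

  fold_metrics <- data.frame(fold = seq_len(control$n_folds),
                             auc = NA_real_, aupr = NA_real_,
                             prevalence = NA_real_)
  scores <- vector("list", control$n_folds)
  drug_rows <- list()

  for (f in seq_len(control$n_folds)) {
    fold <- folds[[f]]
    a_train <- assoc
    a_train[fold$test_pos] <- 0
    train_pairs <- rbind(fold$train_pos, fold$train_neg)
    train_labels <- rep(c(1L, 0L), c(nrow(fold$train_pos), nrow(fold$train_neg)))
    if (control$verbose)
      message(sprintf("fold %d/%d: %d train pairs", f, control$n_folds,
                      nrow(train_pairs)))
    fit <- ddpred(a_train, properties, disease_sim = disease_sim,
                  train_pairs = train_pairs, train_labels = train_labels,
                  control = control, seed = fold_seeds[f])
    test_pairs <- rbind(fold$test_pos, fold$test_neg)
    test_labels <- rep(c(1L, 0L), c(nrow(fold$test_pos), nrow(fold$test_neg)))
    pred <- predict(fit, test_pairs)
    m <- compute_metrics(pred$score, test_labels)
    fold_metrics$auc[f] <- m$auc
    fold_metrics$aupr[f] <- m$aupr
    fold_metrics$prevalence[f] <- mean(test_labels)
    pred$label <- test_labels
    pred$fold <- f
    scores[[f]] <- pred

    # per-drug metrics within this fold (drugs with >= 1 test positive)
    for (i in unique(fold$test_pos[, 1])) {
      sel <- pred$drug == i
      if (sum(pred$label[sel] == 1) < 1 || sum(pred$label[sel] == 0) < 1) next
      dm <- compute_metrics(pred$score[sel], pred$label[sel], top_k = top_k,
                            context = paste0("drug ", i))
      row <- data.frame(drug = i, fold = f, auc = dm$auc, aupr = dm$aupr)
      row[paste0("top", top_k)] <- as.list(unname(dm$top_k))
      drug_rows[[length(drug_rows) + 1L]] <- row
    }
  }

  drug_tab <- do.call(rbind, drug_rows)
  tk_cols <- match(paste0("top", top_k), names(drug_tab))
  per_drug <- do.call(rbind, lapply(split(drug_tab, drug_tab$drug), function(d) {
    data.frame(drug = d$drug[1], n_folds = nrow(d), auc = mean(d$auc),
               aupr = mean(d$aupr))
  }))
  top_k_mean <- colMeans(drug_tab[, tk_cols, drop = FALSE])
  names(top_k_mean) <- paste0("top", top_k)

  structure(list(fold_metrics = fold_metrics,
                 mean_auc = mean(fold_metrics$auc),
                 mean_aupr = mean(fold_metrics$aupr),
                 prevalence = mean(fold_metrics$prevalence),
                 per_drug = per_drug,
                 per_drug_mean_auc = mean(per_drug$auc),
                 per_drug_mean_aupr = mean(per_drug$aupr),
                 top_k = top_k_mean,
                 scores = do.call(rbind, scores),
                 control = control, seed = seed),
            class = "dd_cv")
}

#' @export
print.dd_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (pooled test pairs per fold)\n",
              nrow(x$fold_metrics)))
  cat(sprintf("  mean AUC  %.4f   mean AUPR %.4f   (positive prevalence %.4f)\n",
              x$mean_auc, x$mean_aupr, x$prevalence))
  cat(sprintf("  per-drug mean AUC %.4f, AUPR %.4f over %d evaluable drugs\n",
              x$per_drug_mean_auc, x$per_drug_mean_aupr, nrow(x$per_drug)))
  if (length(x$top_k))
    cat("  per-drug mean recall:",
        paste(sprintf("%s %.3f", names(x$top_k), x$top_k), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dd_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$fold_metrics, row.names = FALSE)
  invisible(object)
}

# compact, serializable metrics view (used by the CLI and for determinism
# comparisons)
cv_metrics_list <- function(x) {
  list(mean_auc = x$mean_auc, mean_aupr = x$mean_aupr,
       prevalence = x$prevalence,
       per_drug_mean_auc = x$per_drug_mean_auc,
       per_drug_mean_aupr = x$per_drug_mean_aupr,
       top_k = as.list(x$top_k),
       fold_auc = x$fold_metrics$auc, fold_aupr = x$fold_metrics$aupr)
}
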