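test_that("cross-entropy matches hand values and clamps zero probabilities", {
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), log(2))
  expect_equal(cross_entropy(rbind(c(0.5, 0.5), c(0.5, 0.5)), c(1L, 0L)),
               2 * log(2))
  expect_equal(cross_entropy(c(0.8, 0.2), 0L), -log(0.2))
  expect_equal(cross_entropy(c(1, 0), 1L), 0)
  expect_warning(l <- cross_entropy(c(0, 1), 1L), "clamped")
  expect_equal(l, -log(1e-12))
  expect_error(cross_entropy(c(0.7, 0.7), 1L), "probability")
  expect_error(cross_entropy(rbind(c(.5, .5)), c(1L, 0L)), "match")
})

test_that("score combination is the convex lambda mixture", {
  expect_equal(combine_scores(0.8, 0.4, 0.5), 0.6)
  expect_equal(combine_scores(c(0.8, 0.2), c(0.4, 0.6), 1), c(0.8, 0.2))
  expect_equal(combine_scores(c(0.8, 0.2), c(0.4, 0.6), 0), c(0.4, 0.6))
  expect_error(combine_scores(0.5, 0.5, 1.5), "lambda")
  expect_error(combine_scores(0.5, 0.5, -0.1), "lambda")
})

test_that("AUC/AUPR match hand-computed values on small examples", {
  # scores 4 > 3 > 2 > 1 with labels 1,0,1,0: AUC = 3/4
  m <- compute_metrics(c(4, 3, 2, 1), c(1, 0, 1, 0))
  expect_equal(m$auc, 0.75)
  # precision at the two positives: 1/1 and 2/3; each covers recall 1/2
  expect_equal(m$aupr, 0.5 * 1 + 0.5 * (2 / 3))
  # perfect and reversed rankings
  expect_equal(compute_metrics(c(3, 2, 1), c(1, 1, 0))$auc, 1)
  expect_equal(compute_metrics(c(1, 2, 3), c(1, 1, 0))$auc, 0)
  # all-tied scores give AUC 1/2
  expect_equal(compute_metrics(rep(1, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)
  expect_error(compute_metrics(1:3, c(1, 1, 1), context = "drug 7"), "drug 7")
})

test_that("metrics match independent oracles on 100 random score vectors", {
  set.seed(303)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[n] <- 0
    scores <- if (rep %% 3 == 0) sample(round(runif(n), 1)) else runif(n)
    k <- sample(3:10, 1)
    m <- compute_metrics(scores, labels, top_k = k)
    expect_lt(abs(m$auc - auc_oracle(scores, labels)), 1e-10)
    expect_lt(abs(m$aupr - aupr_oracle(scores, labels)), 1e-10)
    expect_lt(abs(unname(m$top_k) - topk_oracle(scores, labels, k)), 1e-10)
  }
})

test_that("fold construction partitions positives and excludes train negatives", {
  sim <- tiny_dataset()
  set.seed(5)
  folds <- make_folds(sim$assoc, n_folds = 5L, neg_ratio = 1)
  pos <- which(sim$assoc == 1, arr.ind = TRUE)
  key <- function(p) paste(p[, 1], p[, 2])
  all_test_pos <- do.call(rbind, lapply(folds, `[[`, "test_pos"))
  expect_setequal(key(all_test_pos), key(pos))         # each positive tested once
  expect_equal(nrow(all_test_pos), nrow(pos))
  for (f in folds) {
    expect_setequal(c(key(f$test_pos), key(f$train_pos)), key(pos))
    expect_length(intersect(key(f$train_neg), key(f$test_neg)), 0)
    expect_length(intersect(key(f$train_neg), key(pos)), 0)
    expect_equal(nrow(f$train_neg), nrow(f$train_pos))  # neg_ratio = 1
  }
  set.seed(5)
  folds2 <- make_folds(sim$assoc, n_folds = 5L, neg_ratio = 1)
  expect_identical(folds, folds2)
  expect_error(make_folds(sim$assoc, n_folds = 1L), "n_folds")
})

test_that("fitting, prediction and candidate ranking satisfy their contracts", {
  sim <- tiny_dataset()
  fit <- ddpred(sim$assoc, sim$properties, disease_dag = sim$dags,
                control = tiny_control(), seed = 31)
  expect_s3_class(fit, "ddpred")
  expect_output(print(fit), "predictor")
  expect_output(summary(fit), "CE")
  expect_named(coef(fit), c("topology", "attribute"))

  pred <- predict(fit)
  expect_equal(nrow(pred), nrow(sim$assoc) * ncol(sim$assoc))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(pred$score,
               combine_scores(pred$score_nt, pred$score_pa, fit$control$lambda))
  # lambda override changes the mixture, not the branch scores
  p1 <- predict(fit, lambda = 1)
  expect_equal(p1$score, p1$score_nt)
  expect_equal(p1$score_nt, pred$score_nt)

  rc <- rank_candidates(fit, top = 3L)
  expect_true(all(rc$rank %in% 1:3))
  known <- paste(which(sim$assoc == 1, arr.ind = TRUE)[, 1],
                 which(sim$assoc == 1, arr.ind = TRUE)[, 2])
  expect_length(intersect(paste(rc$drug, rc$disease), known), 0)
  for (i in unique(rc$drug)) {
    s <- rc$score[rc$drug == i]
    expect_true(all(diff(s) <= 0))                      # sorted by score
  }
})

test_that("single-branch fits are reproduced inside the two-branch fit", {
  sim <- tiny_dataset()
  ctl <- tiny_control()
  both <- ddpred(sim$assoc, sim$properties, disease_dag = sim$dags,
                 control = ctl, seed = 41)
  topo <- ddpred(sim$assoc, sim$properties, disease_dag = sim$dags,
                 control = ctl, seed = 41, branches = "topology")
  attr_ <- ddpred(sim$assoc, sim$properties, disease_dag = sim$dags,
                  control = ctl, seed = 41, branches = "attribute")
  expect_identical(both$branch1$params, topo$branch1$params)
  expect_identical(both$branch2$params, attr_$branch2$params)
  pairs <- cbind(c(1L, 4L, 9L), c(2L, 6L, 10L))
  expect_identical(predict(both, pairs, lambda = 1)$score,
                   predict(topo, pairs)$score)
  expect_identical(predict(both, pairs, lambda = 0)$score,
                   predict(attr_, pairs)$score)
})
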