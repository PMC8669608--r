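test_that("confusion-matrix rates follow the closed forms", {
  r <- metrics(c(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_equal(r$acc_pct, 100)
  expect_equal(r$tpr, 1); expect_equal(r$fpr, 0)
  expect_equal(r$precision, 1); expect_equal(r$fscore, 1)
  expect_length(r$undefined, 0)

  r <- metrics(c(TP = 50, FP = 0, TN = 0, FN = 50))
  expect_equal(r$tpr, 0.5)
  expect_equal(r$precision, 1)
  expect_equal(r$fscore, 2 / 3)

  r <- metrics(c(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_true(is.nan(r$precision))
  expect_true("precision" %in% r$undefined)

  expect_error(metrics(c(TP = -1, FP = 0, TN = 0, FN = 0)), "non-negative")
})

test_that("auROC matches rank and pair-enumeration definitions", {
  lab <- c(1, 1, -1, -1)
  expect_equal(auroc(c(4, 3, 2, 1), lab), 1)
  sc <- c(4, 1.5, 2, 1)                      # one inversion
  expect_equal(auroc(sc, lab), brute_auroc(sc, lab))
  expect_equal(auroc(sc, lab), 0.75)

  # invariance under strictly monotone transforms
  set.seed(2)
  sc <- rnorm(50); lab <- sample(c(1, -1), 50, replace = TRUE)
  expect_equal(auroc(sc, lab), auroc(exp(sc), lab))
  expect_equal(auroc(sc, lab), brute_auroc(sc, lab))

  # chance level on label-independent scores
  set.seed(3)
  lab <- rep(c(1, -1), 1000)
  expect_lt(abs(auroc(rnorm(2000), lab) - 0.5), 0.03)
  expect_error(auroc(1:5, rep(1, 5)), "both classes")
})

test_that("auROC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- rnorm(200)
  lab <- ifelse(sc + rnorm(200) > 0, 1, -1)
  expect_equal(auroc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("stratified cross-validation partitions and reproduces", {
  set.seed(9)
  vals <- cbind(f = c(rnorm(5, 5), rnorm(5, -5)))
  m <- feature_matrix(vals, rep(c(1, -1), each = 5))
  r <- cross_validate(m, bagging_svm_config(T = 1, bootstrap = FALSE),
                      folds = 5, seed = 1)
  expect_equal(r$folds$n_test, rep(2, 5))
  expect_equal(sum(r$counts), 10)            # each sample tested once
  expect_equal(r$metrics$acc, 1)             # separable

  r2 <- cross_validate(m, bagging_svm_config(T = 1, bootstrap = FALSE),
                       folds = 5, seed = 1)
  expect_identical(r$counts, r2$counts)
  expect_error(cross_validate(m, bagging_svm_config(), folds = 6, seed = 1),
               "fewer samples than folds")
})

test_that("holdout split is stratified, disjoint and reproducible", {
  d <- protein_dataset(sprintf("s%03d", 1:100),
                       replicate(100, random_seq(20)),
                       rep(c(1, -1), each = 50))
  sp <- holdout_split(d, 0.2, seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$test$label == 1), 10)
  expect_equal(sum(sp$train$label == 1), 40)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- holdout_split(d, 0.2, seed = 3)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(holdout_split(d, 1.2), "test_fraction")
})

test_that("sweeps return one row per setting", {
  m <- toy_matrix(n = 60, signal = 2, noise = 2, effect = 3, seed = 12)
  sC <- sweep_axis(m, "C", c(1, 10, 100, 1000), folds = 3, seed = 1)
  expect_equal(nrow(sC), 4)
  sK <- sweep_axis(m, "kernel", c("linear", "poly2", "rbf"), folds = 3,
                   seed = 1)
  expect_equal(nrow(sK), 3)
  expect_true(all(sK$acc >= 0 & sK$acc <= 1))
  expect_error(sweep_axis(m, "C", numeric(0)), "non-empty")
})

test_that("label permutation drives CV accuracy to the majority rate", {
  d <- generate_sequences(synthetic_config(n_pos = 500, n_neg = 500,
                                           seed = 17))
  m <- hybrid_encode(d, parts = c("cc", "gaac"))
  set.seed(17)
  m_perm <- feature_matrix(m$values, sample(m$labels))
  r <- cross_validate(m_perm, bagging_svm_config(T = 3), folds = 5,
                      seed = 2)
  expect_lt(abs(r$metrics$acc - 0.5), 0.03)
})
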