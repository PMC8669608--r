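test_that("boosted-stump selection keeps separating features, drops constants", {
  y <- rep(c(1, -1), each = 10)
  vals <- cbind(c1 = y * 0.5 + 3,          # perfect separator
                c2 = rep(1, 20), c3 = rep(0, 20))
  m <- feature_matrix(vals, y)
  r <- adaboost_select(m, n_estimators = 10)
  expect_true("c1" %in% r$descriptor)
  expect_false(any(c("c2", "c3") %in% r$descriptor))

  all_const <- feature_matrix(cbind(a = rep(1, 20), b = rep(2, 20)), y)
  expect_equal(nrow(adaboost_select(all_const, 10)), 0)

  expect_error(adaboost_select(feature_matrix(vals, rep(1, 20)), 10),
               "both classes")
})

test_that("boosted-stump selection recovers planted informative columns", {
  m <- toy_matrix(n = 200, signal = 5, noise = 45, effect = 2, seed = 42)
  r <- adaboost_select(m, n_estimators = 100)
  hits <- sum(sprintf("sig%d", 1:5) %in% r$descriptor)
  expect_gte(hits, 4)
  # determinism
  r2 <- adaboost_select(m, n_estimators = 100)
  expect_identical(r$descriptor, r2$descriptor)
  expect_identical(r$score, r2$score)
})

test_that("pearson relevance behaves at the extremes", {
  y <- rep(c(1, -1), each = 500)
  set.seed(5)
  vals <- cbind(same = y, neg = -y, noise = rnorm(1000),
                const = rep(2, 1000))
  m <- feature_matrix(vals, y)
  r <- pearson_relevance(m)
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["neg"]), 1)
  expect_lt(r["noise"], 0.1)
  expect_equal(unname(r["const"]), 0)
})

test_that("pairwise distance scores match a hand-computed toy", {
  e1 <- c(1, 0, 0, 0)
  e2 <- c(0, 1, 0, 0)
  vals <- cbind(a = e1, b = e2, c = e1)          # c duplicates a
  m <- feature_matrix(vals, c(1, -1, 1, -1))
  r <- distance_redundancy(m)
  # duplicate pair contributes 0; oracle recomputes each pair by loops
  emax <- sqrt(2)
  pab <- brute_pair_distance(e1, e2, emax)
  expect_equal(unname(r["a"]), mean(c(pab, 0)), tolerance = 1e-12)
  expect_equal(unname(r["b"]), mean(c(pab, pab)), tolerance = 1e-12)
  expect_equal(unname(r["c"]), mean(c(0, pab)), tolerance = 1e-12)
  # orthogonal unit columns: cosine distance 1, Tanimoto 0, Euclid max
  expect_equal(pab, 1)

  single <- feature_matrix(cbind(only = e1), c(1, -1, 1, -1))
  expect_equal(unname(distance_redundancy(single)), 1)
})

test_that("MRMD defers exact duplicates below fresh information", {
  set.seed(8)
  y <- rep(c(1, -1), each = 30)
  inf <- y + rnorm(60, sd = 0.3)
  vals <- cbind(inf_a = inf, inf_b = inf, noise = rnorm(60))
  m <- feature_matrix(vals, y)
  r <- mrmd_select(m, k_grid = 1:3)
  full <- attr(r, "params")$full_ranking
  pos <- match(c("inf_a", "inf_b", "noise"), full)
  # exactly one duplicate outranks the noise column
  expect_equal(sum(pos[1:2] < pos[3]), 1)
  # the selected subset never holds both duplicates before covering signal
  expect_false(all(c("inf_a", "inf_b") %in% r$descriptor) &&
                 nrow(r) == 2)

  one <- feature_matrix(cbind(only = inf), y)
  expect_equal(mrmd_select(one, k_grid = 1)$descriptor, "only")
})

test_that("MRMD subset keeps accuracy within a point of the full set", {
  m <- toy_matrix(n = 200, signal = 4, noise = 16, effect = 2, seed = 9)
  r <- mrmd_select(m, seed = 2)
  expect_lte(nrow(r), ncol(m$values))
  cfg <- bagging_svm_config(T = 1, bootstrap = FALSE)
  acc_full <- cross_validate(m, cfg, seed = 3)$metrics$acc
  acc_sub <- cross_validate(
    feature_matrix(m$values[, r$descriptor, drop = FALSE], m$labels),
    cfg, seed = 3)$metrics$acc
  expect_gte(acc_sub, acc_full - 0.01)
})

test_that("rank fusion preserves a unanimous ordering", {
  set.seed(4)
  y <- rep(c(1, -1), each = 40)
  # strength strictly decreasing a > b > c for every ranker
  vals <- cbind(a = y + rnorm(80, sd = 0.1),
                b = y + rnorm(80, sd = 0.8),
                c = rnorm(80))
  m <- feature_matrix(vals, y)
  r <- mrmd2_rank(m, rankers = c("anova_f", "pearson", "mic_proxy"))
  expect_equal(r$descriptor, c("a", "b", "c"))
  expect_equal(sum(r$score), 1, tolerance = 1e-9)

  expect_error(mrmd2_rank(m, rankers = character(0)), "at least one")
  expect_error(mrmd2_rank(m, rankers = "bogus"), "unknown ranker")
})

test_that("two-node PageRank matches the closed-form solution", {
  # single list ranks a above b: one edge b -> a; a is dangling
  W <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  pr <- pagerank(W, damping = 0.85)
  # stationary equations with a dangling (teleporting) top node:
  #   a = .075 + .85 * (b + a/2);  b = .075 + .85 * (a/2)
  sol <- solve(matrix(c(1 - 0.85 / 2, -0.85,
                        -0.85 / 2, 1), 2, 2, byrow = TRUE),
               c(0.075, 0.075))
  expect_equal(unname(pr), sol, tolerance = 1e-8)
  expect_gt(pr["a"], pr["b"])
})

test_that("PageRank agrees with the igraph oracle and is permutation-fair", {
  skip_if_not_installed("igraph")
  set.seed(21)
  n <- 8
  W <- matrix(rpois(n * n, 1), n, n)
  diag(W) <- 0
  dimnames(W) <- list(letters[1:n], letters[1:n])
  pr <- pagerank(W, damping = 0.85)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE)
  pr_ig <- igraph::page_rank(g, damping = 0.85)$vector
  expect_equal(unname(pr), unname(pr_ig), tolerance = 1e-6)
  expect_equal(sum(pr), 1, tolerance = 1e-9)

  perm <- sample(n)
  pr_p <- pagerank(W[perm, perm], damping = 0.85)
  expect_equal(pr_p[letters[1:n]], pr[letters[1:n]], tolerance = 1e-8)
})

test_that("accuracy-vs-top-k curve is well-formed", {
  m <- toy_matrix(n = 120, signal = 3, noise = 9, effect = 2, seed = 6)
  r <- mrmd2_rank(m, rankers = c("anova_f", "pearson"))
  curve <- accuracy_vs_topk(m, r, k_grid = c(1, 3, 6, 12), seed = 2)
  expect_equal(curve$k, c(1, 3, 6, 12))
  # k = all features equals plain CV on the full matrix
  plain <- cross_validate(m, bagging_svm_config(T = 1, bootstrap = FALSE),
                          seed = 2)$metrics$acc
  expect_equal(curve$acc[curve$k == 12], plain)
  # with enough features to cover the planted signal, beats k = 1
  expect_gt(curve$acc[curve$k == 6], curve$acc[curve$k == 1])
  expect_error(accuracy_vs_topk(m, r, k_grid = 99), "exceeds")
})

test_that("selectors cannot conjure signal from pure noise", {
  set.seed(33)
  n <- 300
  y <- rep(c(1, -1), each = n / 2)
  vals <- matrix(rnorm(n * 30), n, 30,
                 dimnames = list(NULL, sprintf("f%02d", 1:30)))
  m <- feature_matrix(vals, y)
  r <- mrmd_select(m, seed = 1)
  acc <- cross_validate(
    feature_matrix(m$values[, r$descriptor, drop = FALSE], m$labels),
    bagging_svm_config(T = 1, bootstrap = FALSE), seed = 5)$metrics$acc
  expect_lt(acc, 0.5 + 0.1)   # majority rate plus sampling noise
})
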