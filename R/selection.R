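# Feature selection: boosted-stump (AdaBoost) importance for the gapped
# k-mer space, MRMD relevance/distance ranking, and MRMD2.0-style PageRank
# fusion of several ranker lists.

#' Construct a ranked feature list
#'
#' @param descriptor character vector of feature descriptors (no
#'   duplicates).
#' @param score numeric scores, non-increasing in list order.
#' @param method tag (`"adaboost"`, `"mrmd"`, `"mrmd2"`).
#' @param params named list snapshot of the selection parameters.
#' @return A `ranked_features` data frame with columns `descriptor`,
#'   `score`, `rank`.
#' @export
ranked_features <- function(descriptor, score, method, params = list()) {
  if (anyDuplicated(descriptor)) stop("duplicate descriptors in ranking")
  if (is.unsorted(rev(score))) stop("scores must be non-increasing")
  structure(
    data.frame(descriptor = as.character(descriptor), score = score,
               rank = seq_along(descriptor), stringsAsFactors = FALSE),
    method = method, params = params,
    class = c("ranked_features", "data.frame"))
}

# Stable ordering used by every selector: score descending, then
# descriptor name ascending.
order_by_score <- function(descriptor, score)
  order(-score, descriptor, method = "radix")

check_binary_labels <- function(m) {
  if (anyNA(m$labels)) stop("all samples must be labeled")
  if (length(unique(m$labels)) < 2)
    stop("both classes must be present")
}

#' Boosted-stump feature selection
#'
#' Fits a discrete AdaBoost ensemble of depth-1 decision stumps to the
#' labeled feature matrix and retains the features with importance
#' strictly greater than zero (importance = total stump weight alpha
#' accumulated by the feature across boosting rounds), ordered by
#' importance.  This is the subset-reduction step applied to the 16,000-
#' dimensional monoDiKGap space before it enters a hybrid descriptor set.
#' The procedure is deterministic; `seed` is recorded in the parameter
#' snapshot for provenance only.
#'
#' @param m a labeled [feature_matrix()] with both classes present and at
#'   least two samples per class.
#' @param n_estimators boosting rounds (default 100).
#' @param seed recorded in the params snapshot.
#' @return A [ranked_features()] (possibly empty when no feature is
#'   informative, e.g. an all-constant matrix).
#' @export
adaboost_select <- function(m, n_estimators = 100L, seed = 1L) {
  check_binary_labels(m)
  if (min(table(m$labels)) < 2) stop("need >= 2 samples per class")
  fit <- ada_stump_boost(m$values, m$labels, as.integer(n_estimators))
  imp <- fit$importance
  keep <- which(imp > 0)
  ord <- keep[order_by_score(colnames(m$values)[keep], imp[keep])]
  ranked_features(colnames(m$values)[ord], imp[ord], "adaboost",
                  list(n_estimators = n_estimators, seed = seed,
                       stumps = fit$stumps))
}

#' Pearson relevance of features to the class label
#'
#' Absolute Pearson correlation between each feature column and the +1/-1
#' label vector; constant columns score 0 by convention.
#'
#' @param m a labeled [feature_matrix()].
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
pearson_relevance <- function(m) {
  check_binary_labels(m)
  sds <- apply(m$values, 2, stats::sd)
  r <- rep(0, ncol(m$values))
  ok <- sds > 0
  if (any(ok))
    r[ok] <- abs(as.vector(stats::cor(m$values[, ok, drop = FALSE],
                                      m$labels)))
  stats::setNames(r, colnames(m$values))
}

# Pairwise feature distance matrix: the mean of (i) Euclidean distance
# min-max normalized over all pairs, (ii) cosine distance 1 - cos, and
# (iii) 1 - Tanimoto coefficient.  Identical columns score exactly 0.
pair_distances <- function(values) {
  d <- ncol(values)
  dots <- crossprod(values)                       # t(X) %*% X
  sq <- diag(dots)
  eucl2 <- outer(sq, sq, "+") - 2 * dots
  eucl <- sqrt(pmax(eucl2, 0))
  emax <- max(eucl)
  eucl_n <- if (emax > 0) eucl / emax else eucl
  norms <- sqrt(sq)
  np <- outer(norms, norms)
  cosd <- 1 - ifelse(np > 0, dots / np, 0)
  tani_den <- outer(sq, sq, "+") - dots
  tani <- ifelse(abs(tani_den) > 0, dots / tani_den, 1)
  p <- (eucl_n + cosd + (1 - tani)) / 3
  diag(p) <- 0
  dimnames(p) <- list(colnames(values), colnames(values))
  p
}

#' Mean feature-to-feature distance (non-redundancy) scores
#'
#' For each feature, the mean over all other features of a per-pair
#' distance that averages three measures: min-max-normalized Euclidean
#' distance, cosine distance (1 - cosine similarity), and 1 - Tanimoto
#' coefficient.  Higher means less redundant.  A single-feature matrix
#' scores 1 (maximally non-redundant) by convention.
#'
#' @param m a [feature_matrix()].
#' @return Named numeric vector of non-redundancy scores.
#' @export
distance_redundancy <- function(m) {
  d <- ncol(m$values)
  if (d < 2)
    return(stats::setNames(rep(1, d), colnames(m$values)))
  p <- pair_distances(m$values)
  stats::setNames(rowSums(p) / (d - 1), colnames(m$values))
}

minmax <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
}

#' MRMD feature ranking and subset selection
#'
#' Ranks features by combining label relevance (absolute Pearson
#' correlation, min-max normalized) with non-redundancy (pairwise feature
#' distance).  The ranking is greedy: the first feature maximizes
#' `w_r * relevance + w_d * mean distance to all other features`; each
#' subsequent feature maximizes the same score with the distance term
#' recomputed against the already-ranked set, so that a feature gets no
#' redundancy credit for information already covered.  A candidate whose
#' distance to the ranked set is numerically zero (an exact duplicate)
#' carries no new information and is deferred to the end of the ranking.
#' The returned subset is the top-k of this ranking, with k chosen over
#' `k_grid` to maximize stratified 5-fold CV accuracy of a linear SVM
#' (ties: smallest k).
#'
#' @param m a labeled [feature_matrix()].
#' @param w_r,w_d relevance / distance weights (default 1 and 1).
#' @param k_grid candidate subset sizes; default a coarse grid up to the
#'   feature count.
#' @param folds,seed,C cross-validation folds, RNG seed, SVM penalty for
#'   the subset-size search.
#' @return A [ranked_features()] of the selected subset; the full curve of
#'   (k, CV accuracy) is in `attr(, "params")$k_curve`.
#' @export
mrmd_select <- function(m, w_r = 1, w_d = 1, k_grid = NULL,
                        folds = 5L, seed = 1L, C = 1) {
  check_binary_labels(m)
  d <- ncol(m$values)
  desc <- colnames(m$values)
  rel <- minmax(pearson_relevance(m))
  if (d == 1) {
    ranking <- desc
    scores <- w_r * rel + w_d
  } else {
    p <- pair_distances(m$values)
    remaining <- seq_len(d)
    ranking <- integer(0)
    scores <- numeric(0)
    deferred <- integer(0)
    while (length(remaining) > 0) {
      dist_term <- if (length(ranking) == 0)
        rowSums(p[remaining, , drop = FALSE]) / (d - 1)
      else
        rowMeans(p[remaining, ranking, drop = FALSE])
      dup <- length(ranking) > 0 &
        apply(p[remaining, ranking, drop = FALSE], 1,
              function(z) any(z < 1e-12))
      sc <- w_r * rel[remaining] + w_d * dist_term
      cand <- if (all(dup)) seq_along(remaining) else which(!dup)
      pick <- cand[order_by_score(desc[remaining][cand], sc[cand])[1]]
      if (dup[pick]) deferred <- c(deferred, remaining[pick])
      else {
        ranking <- c(ranking, remaining[pick])
        scores <- c(scores, sc[pick])
      }
      remaining <- remaining[-pick]
    }
    # the greedy objective need not decrease monotonically (the distance
    # term is recomputed each step); report the running minimum so the
    # list carries non-increasing scores
    scores <- cummin(scores)
    # exact duplicates go last, with score below every ranked feature
    if (length(deferred) > 0) {
      floor_score <- min(scores) - 1
      ranking <- c(ranking, deferred)
      scores <- c(scores, rep(floor_score, length(deferred)))
    }
    ranking <- desc[ranking]
  }
  if (is.null(k_grid))
    k_grid <- unique(pmin(c(1, 2, 3, 5, 8, 12, 17, 25, 50, 100, 200, 400, d), d))
  k_grid <- sort(unique(k_grid))
  if (any(k_grid > d)) stop("k_grid exceeds feature count")
  acc <- vapply(k_grid, function(k) {
    sub <- subset_features(m, cols = ranking[seq_len(k)])
    cross_validate(sub, bagging_svm_config(T = 1L, C = C, kernel = "linear",
                                           bootstrap = FALSE),
                   folds = folds, seed = seed)$metrics$acc
  }, 0)
  k_best <- k_grid[which.max(acc)]
  keep <- seq_len(k_best)
  ranked_features(ranking[keep], scores[keep], "mrmd",
                  list(w_r = w_r, w_d = w_d, k = k_best, seed = seed,
                       k_curve = data.frame(k = k_grid, acc = acc),
                       full_ranking = ranking))
}

# ---- rankers for MRMD2.0-style fusion -------------------------------------

bin_values <- function(x, bins = 5L) {
  r <- range(x)
  if (r[2] <= r[1]) return(rep(1L, length(x)))
  b <- findInterval(x, seq(r[1], r[2], length.out = bins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(b)
}

mi_disc <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

rank_scores <- list(
  anova_f = function(m) {
    y <- m$labels
    apply(m$values, 2, function(x) {
      if (stats::sd(x) == 0) return(0)
      summary(stats::aov(x ~ factor(y)))[[1]]$`F value`[1]
    })
  },
  chi2 = function(m) {
    y <- factor(m$labels)
    apply(m$values, 2, function(x) {
      b <- bin_values(x)
      if (length(unique(b)) < 2) return(0)
      suppressWarnings(stats::chisq.test(table(b, y))$statistic)
    })
  },
  pearson = function(m) pearson_relevance(m),
  mic_proxy = function(m) {
    y <- m$labels
    apply(m$values, 2, function(x) mi_disc(bin_values(x), y))
  },
  lasso = function(m) {
    y <- factor(m$labels)
    d <- ncol(m$values)
    if (d < 2) return(stats::setNames(rep(1, d), colnames(m$values)))
    fit <- glmnet::glmnet(m$values, y, family = "binomial")
    entry <- apply(fit$beta != 0, 1, function(z)
      if (any(z)) which(z)[1] else length(fit$lambda) + 1L)
    # earlier path entry = stronger; fall back on |cor| among never-entered
    sc <- max(entry) + 1 - entry
    tie <- pearson_relevance(m)
    sc + tie / (max(tie) + 1)   # |cor| breaks path-entry ties
  },
  mrmr = function(m) {
    d <- ncol(m$values)
    bx <- apply(m$values, 2, bin_values)
    rel <- apply(bx, 2, mi_disc, b = m$labels)
    if (d == 1) return(stats::setNames(rel, colnames(m$values)))
    selected <- integer(0)
    simsum <- rep(0, d)
    sc_out <- rep(NA_real_, d)
    for (step in seq_len(d)) {
      remaining <- setdiff(seq_len(d), selected)
      obj <- rel[remaining] -
        (if (step == 1) 0 else simsum[remaining] / (step - 1))
      pick <- remaining[order_by_score(colnames(m$values)[remaining], obj)[1]]
      sc_out[pick] <- d - step + 1   # rank-derived score
      selected <- c(selected, pick)
      if (step < d) {
        rest <- setdiff(seq_len(d), selected)
        simsum[rest] <- simsum[rest] +
          vapply(rest, function(j) mi_disc(bx[, j], bx[, pick]), 0)
      }
    }
    stats::setNames(sc_out, colnames(m$values))
  },
  relevance = function(m) {
    rel <- minmax(pearson_relevance(m))
    red <- minmax(distance_redundancy(m))
    rel + red
  }
)

ranker_ordering <- function(m, ranker) {
  sc <- rank_scores[[ranker]](m)
  colnames(m$values)[order_by_score(colnames(m$values), as.numeric(sc))]
}

#' PageRank over a rank-fusion dominance graph
#'
#' Power iteration on the column-stochastic transition matrix of a
#' directed graph whose edge u -> v (weight accumulated across ranker
#' lists) says "v outranks u"; dangling nodes redistribute uniformly.
#' Iterates until the L1 change is below `tol`.
#'
#' @param W square non-negative weight matrix, `W[u, v]` = total weight of
#'   edge u -> v; dimnames name the nodes.
#' @param damping damping factor (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   iteration count.
#' @return Named numeric vector of PageRank scores summing to 1.
#' @export
pagerank <- function(W, damping = 0.85, tol = 1e-9, max_iter = 1000L) {
  n <- nrow(W)
  if (n != ncol(W)) stop("W must be square")
  out_w <- rowSums(W)
  dangling <- out_w == 0
  M <- W
  M[!dangling, ] <- W[!dangling, , drop = FALSE] / out_w[!dangling]
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- (1 - damping) / n +
      damping * (as.vector(crossprod(M, x)) + sum(x[dangling]) / n)
    if (sum(abs(x_new - x)) < tol)
      return(stats::setNames(x_new, rownames(W)))
    x <- x_new
  }
  stop("PageRank did not converge within ", max_iter, " iterations")
}

#' MRMD2.0-style rank fusion of multiple feature rankers
#'
#' Runs each requested ranker to obtain a full feature ordering, builds a
#' directed dominance graph (for every ranker list, an edge of weight 1
#' from each lower-ranked feature to every feature ranked above it,
#' accumulated across rankers), scores nodes by PageRank, and returns the
#' features ordered by score.
#'
#' Available rankers: `anova_f` (one-way F statistic), `chi2` (chi-square
#' on equal-width-binned features), `pearson` (absolute correlation),
#' `mic_proxy` (a binned mutual-information estimator, labeled as a proxy
#' for MIC), `lasso` (order of entry along the glmnet regularization
#' path), `mrmr` (greedy mutual-information minimum-redundancy), and
#' `relevance` (the MRMD combined relevance + distance score).
#'
#' @param m a labeled [feature_matrix()] with >= 2 features.
#' @param rankers non-empty subset of the available ranker names.
#' @param damping PageRank damping factor (default 0.85).
#' @param seed recorded in the params snapshot (the rankers are
#'   deterministic).
#' @return A [ranked_features()] over all features, scores = PageRank.
#' @export
mrmd2_rank <- function(m, rankers = names(rank_scores), damping = 0.85,
                       seed = 1L) {
  check_binary_labels(m)
  if (length(rankers) == 0) stop("at least one ranker required")
  unknown <- setdiff(rankers, names(rank_scores))
  if (length(unknown))
    stop("unknown ranker(s): ", paste(unknown, collapse = ", "))
  if (ncol(m$values) < 2) stop("need >= 2 features")
  desc <- colnames(m$values)
  d <- length(desc)
  W <- matrix(0, d, d, dimnames = list(desc, desc))
  for (r in rankers) {
    o <- match(ranker_ordering(m, r), desc)
    for (i in 2:d)
      W[o[i], o[seq_len(i - 1)]] <- W[o[i], o[seq_len(i - 1)]] + 1
  }
  pr <- pagerank(W, damping = damping)
  ord <- order_by_score(desc, pr)
  ranked_features(desc[ord], as.numeric(pr[ord]), "mrmd2",
                  list(rankers = rankers, damping = damping, seed = seed))
}

#' Cross-validated accuracy as a function of top-k features
#'
#' For each k in `k_grid`, stratified CV accuracy of the configured
#' classifier using the top-k features of `ranking`.
#'
#' @param m a labeled [feature_matrix()].
#' @param ranking a [ranked_features()] covering features of `m`.
#' @param config a model configuration (see [bagging_svm_config()] /
#'   [baseline_config()]); default a single linear SVM, C = 1.
#' @param k_grid subset sizes (each <= feature count).
#' @param folds,seed CV controls.
#' @return Data frame with columns `k` and `acc`, ordered by `k`.
#' @export
accuracy_vs_topk <- function(m, ranking,
                             config = bagging_svm_config(T = 1L, C = 1,
                                                         kernel = "linear",
                                                         bootstrap = FALSE),
                             k_grid = NULL, folds = 5L, seed = 1L) {
  stopifnot(inherits(ranking, "ranked_features"))
  if (!all(ranking$descriptor %in% colnames(m$values)))
    stop("ranking contains descriptors absent from the matrix")
  if (is.null(k_grid))
    k_grid <- unique(pmin(c(1, 2, 3, 5, 8, 12, 17, 25, 50, nrow(ranking)),
                          nrow(ranking)))
  k_grid <- sort(unique(k_grid))
  if (any(k_grid > nrow(ranking))) stop("k exceeds ranked feature count")
  acc <- vapply(k_grid, function(k) {
    sub <- subset_features(m, cols = ranking$descriptor[seq_len(k)])
    cross_validate(sub, config, folds = folds, seed = seed)$metrics$acc
  }, 0)
  data.frame(k = k_grid, acc = acc)
}
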