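# Bagging ensemble of SVM base learners with majority voting, plus thin
# KNN / random-forest / single-SVM baselines sharing the same predict
# contract: predict(model, feature_matrix) -> list(class, score, ...).

#' Bootstrap sample indices
#'
#' `n` draws with replacement from `1..n`, reproducible under `seed`.
#'
#' @param n sample count (>= 1).
#' @param seed RNG seed.
#' @return Integer vector of length `n`.
#' @export
bootstrap_indices <- function(n, seed) {
  if (n < 1) stop("n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(n, n, replace = TRUE)
}

# save/restore the global RNG state so model fitting does not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(list = ".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

svm_kernel_args <- function(kernel) {
  switch(kernel,
         linear = list(kernel = "linear"),
         poly2 = list(kernel = "polynomial", degree = 2L),
         rbf = list(kernel = "radial"),
         stop("unknown kernel: ", kernel))
}

# fit one SVM; y as factor with levels c("1","-1")
fit_svm <- function(x, y, C, kernel) {
  args <- c(list(x = x, y = factor(y, levels = c("1", "-1")),
                 cost = C, scale = FALSE), svm_kernel_args(kernel))
  do.call(e1071::svm, args)
}

# decision values oriented so that positive => class +1 (libsvm orders the
# decision column by appearance of classes in the training data, so the
# orientation must be read off the column name)
svm_decision <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  pos_first <- strsplit(colnames(dv)[1], "/")[[1]][1] == "1"
  if (pos_first) as.vector(dv) else -as.vector(dv)
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_standardizer <- function(x, st)
  sweep(sweep(x, 2, st$center), 2, st$scale, "/")

#' Train a bagging ensemble of SVMs
#'
#' Trains `T` SVM base learners, learner t on a bootstrap resample of the
#' training set drawn with `bootstrap_indices(n, seed + t)` (resample size
#' = training size).  Features are standardized with training-set mean and
#' standard deviation before fitting (linear SVMs at fixed C are
#' scale-sensitive); disable with `standardize = FALSE`.  With
#' `bootstrap = FALSE` every learner sees the full training set (useful as
#' a plain single SVM when `T = 1`).
#'
#' @param m a labeled [feature_matrix()] with both classes present.
#' @param T number of base learners (default 12).
#' @param C SVM penalty (default 1).
#' @param kernel `"linear"`, `"poly2"` (degree-2 polynomial) or `"rbf"`.
#' @param seed base RNG seed; learner t uses `seed + t`.
#' @param standardize standardize features with training statistics?
#' @param bootstrap draw bootstrap resamples (default `TRUE`)?
#' @return A `bagging_svm` model.
#' @export
train_bagging_svm <- function(m, T = 12L, C = 1, kernel = "linear",
                              seed = 1L, standardize = TRUE,
                              bootstrap = TRUE) {
  check_binary_labels(m)
  if (T < 1) stop("T must be >= 1")
  n <- nrow(m$values)
  st <- if (standardize) standardizer(m$values)
        else list(center = rep(0, ncol(m$values)),
                  scale = rep(1, ncol(m$values)))
  x <- apply_standardizer(m$values, st)
  learners <- vector("list", T)
  for (t in seq_len(T)) {
    idx <- if (bootstrap) {
      ii <- bootstrap_indices(n, seed + t)
      tries <- 0L
      # a bootstrap resample must contain both classes
      while (length(unique(m$labels[ii])) < 2 && tries < 100L) {
        tries <- tries + 1L
        ii <- bootstrap_indices(n, seed + t + 7919L * tries)
      }
      ii
    } else seq_len(n)
    learners[[t]] <- fit_svm(x[idx, , drop = FALSE], m$labels[idx],
                             C = C, kernel = kernel)
  }
  structure(list(learners = learners, T = T, C = C, kernel = kernel,
                 seed = seed, bootstrap = bootstrap,
                 standardize = standardize, st = st,
                 descriptors = colnames(m$values)),
            class = "bagging_svm")
}

check_descriptors <- function(model_desc, new_desc) {
  missing <- setdiff(model_desc, new_desc)
  extra <- setdiff(new_desc, model_desc)
  if (length(missing) || length(extra))
    stop("feature mismatch; missing: [",
         paste(utils::head(missing, 5), collapse = ", "),
         "], extra: [", paste(utils::head(extra, 5), collapse = ", "), "]")
}

#' Predict with a bagging-SVM ensemble
#'
#' Majority vote over the base learners; an even split is broken by the
#' sign of the mean decision value, with an exactly-zero mean assigned to
#' the negative class.  The per-sample score is the mean decision value.
#'
#' @param object a `bagging_svm` model.
#' @param newdata a [feature_matrix()] or numeric matrix whose columns
#'   match the training descriptors (any order; extra or missing columns
#'   are an error).
#' @param ... unused.
#' @return List with `class` (+1/-1), `score` (mean decision value) and
#'   `votes` (n x T matrix of per-learner votes).
#' @export
predict.bagging_svm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  if (nrow(x) == 0)
    return(list(class = numeric(0), score = numeric(0),
                votes = matrix(0, 0, object$T)))
  check_descriptors(object$descriptors, colnames(x))
  x <- apply_standardizer(x[, object$descriptors, drop = FALSE], object$st)
  dv <- vapply(object$learners, svm_decision, numeric(nrow(x)), x = x)
  dv <- matrix(dv, nrow = nrow(x))
  votes <- ifelse(dv > 0, 1, -1)
  vote_sum <- rowSums(votes)
  score <- rowMeans(dv)
  cls <- ifelse(vote_sum > 0, 1,
                ifelse(vote_sum < 0, -1, ifelse(score > 0, 1, -1)))
  list(class = cls, score = score, votes = votes)
}

#' Train a baseline classifier (KNN, random forest, or single SVM)
#'
#' Thin adapters over off-the-shelf learners with the same predict
#' contract as the bagging ensemble.  KNN defaults to k = 3; the random
#' forest uses its package defaults; `"svm"` is a single SVM on the full
#' training set.  Features are standardized with training statistics for
#' KNN and SVM.
#'
#' @param m a labeled [feature_matrix()].
#' @param algo `"knn"`, `"rf"` or `"svm"`.
#' @param k KNN neighbour count (default 3).
#' @param C,kernel SVM parameters.
#' @param ntree random-forest tree count.
#' @param seed RNG seed (random forest).
#' @return A `baseline_model`.
#' @export
baseline <- function(m, algo = c("knn", "rf", "svm"), k = 3L, C = 1,
                     kernel = "linear", ntree = 500L, seed = 1L) {
  algo <- match.arg(algo)
  check_binary_labels(m)
  st <- standardizer(m$values)
  fit <- switch(algo,
    knn = list(x = apply_standardizer(m$values, st), y = m$labels, k = k),
    rf = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      randomForest::randomForest(m$values,
                                 factor(m$labels, levels = c("1", "-1")),
                                 ntree = ntree)
    },
    svm = fit_svm(apply_standardizer(m$values, st), m$labels,
                  C = C, kernel = kernel))
  structure(list(algo = algo, fit = fit, st = st, k = k,
                 descriptors = colnames(m$values)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  if (nrow(x) == 0) return(list(class = numeric(0), score = numeric(0)))
  check_descriptors(object$descriptors, colnames(x))
  x <- x[, object$descriptors, drop = FALSE]
  switch(object$algo,
    knn = {
      xs <- apply_standardizer(x, object$st)
      p <- class::knn(object$fit$x, xs,
                      factor(object$fit$y, levels = c("1", "-1")),
                      k = object$fit$k, prob = TRUE)
      cls <- ifelse(p == "1", 1, -1)
      frac_win <- attr(p, "prob")           # fraction voting for winner
      score <- ifelse(cls == 1, frac_win, 1 - frac_win) - 0.5
      list(class = cls, score = score)
    },
    rf = {
      pr <- unname(stats::predict(object$fit, x, type = "prob")[, "1"])
      list(class = ifelse(pr > 0.5, 1, -1), score = pr - 0.5)
    },
    svm = {
      xs <- apply_standardizer(x, object$st)
      dv <- svm_decision(object$fit, xs)
      list(class = ifelse(dv > 0, 1, -1), score = dv)
    })
}

#' Model configurations for cross-validation and sweeps
#'
#' Lightweight descriptions of a classifier, consumed by
#' [cross_validate()], [sweep_axis()] and [full_pipeline()].
#' `bagging_svm_config(T = 1, bootstrap = FALSE)` is a plain single SVM.
#'
#' @param T,C,kernel,standardize,bootstrap see [train_bagging_svm()].
#' @param select optional per-fold selection hook:
#'   `function(train_fm) -> character vector of descriptors` applied to
#'   the training fold before fitting (the test fold is subset to the same
#'   descriptors at prediction time).
#' @return A `model_config`.
#' @export
bagging_svm_config <- function(T = 12L, C = 1, kernel = "linear",
                               standardize = TRUE, bootstrap = TRUE,
                               select = NULL) {
  structure(list(model = "bagging_svm", T = T, C = C, kernel = kernel,
                 standardize = standardize, bootstrap = bootstrap,
                 select = select),
            class = "model_config")
}

#' @rdname bagging_svm_config
#' @param algo,k,ntree see [baseline()].
#' @export
baseline_config <- function(algo = c("knn", "rf", "svm"), k = 3L, C = 1,
                            kernel = "linear", ntree = 500L, select = NULL) {
  algo <- match.arg(algo)
  structure(list(model = "baseline", algo = algo, k = k, C = C,
                 kernel = kernel, ntree = ntree, select = select),
            class = "model_config")
}

# instantiate a config on a training fold; returns an object whose
# predict() subsets newdata to the descriptors used in training
train_config <- function(config, train_fm, seed) {
  if (!is.null(config$select)) {
    keep <- config$select(train_fm)
    train_fm <- subset_features(train_fm, cols = keep)
  }
  model <- if (config$model == "bagging_svm")
    train_bagging_svm(train_fm, T = config$T, C = config$C,
                      kernel = config$kernel, seed = seed,
                      standardize = config$standardize,
                      bootstrap = config$bootstrap)
  else
    baseline(train_fm, algo = config$algo, k = config$k, C = config$C,
             kernel = config$kernel, ntree = config$ntree, seed = seed)
  structure(list(model = model, descriptors = colnames(train_fm$values)),
            class = "fitted_config")
}

#' @export
predict.fitted_config <- function(object, newdata, ...) {
  fm <- if (inherits(newdata, "feature_matrix")) newdata else
    feature_matrix(as.matrix(newdata))
  sub <- subset_features(fm, cols = object$descriptors)
  stats::predict(object$model, sub)
}
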