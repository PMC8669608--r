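# Evaluation: confusion-matrix rates, rank-based auROC, stratified k-fold
# cross-validation, stratified holdout split, and parameter sweeps.

#' Confusion counts from predictions
#'
#' @param predicted,actual numeric vectors of +1/-1 classes.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  c(TP = sum(predicted == 1 & actual == 1),
    FP = sum(predicted == 1 & actual == -1),
    TN = sum(predicted == -1 & actual == -1),
    FN = sum(predicted == -1 & actual == 1))
}

#' Confusion-matrix rates
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), precision = TP/(TP+FP),
#' recall = TPR, F-score = 2*precision*recall/(precision+recall),
#' ACC = (TP+TN)/(TP+FP+TN+FN).  A zero-denominator ratio is reported as
#' `NaN` and listed in `undefined`, never silently set to 0.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN` (non-negative).
#' @return List of rates plus `acc_pct` (accuracy in percent) and
#'   `undefined` (names of undefined rates).
#' @export
metrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  rt <- function(num, den) if (den == 0) NaN else num / den
  tpr <- rt(counts["TP"], counts["TP"] + counts["FN"])
  fpr <- rt(counts["FP"], counts["FP"] + counts["TN"])
  precision <- rt(counts["TP"], counts["TP"] + counts["FP"])
  recall <- tpr
  fscore <- if (is.nan(precision) || is.nan(recall) ||
                precision + recall == 0) NaN
            else 2 * precision * recall / (precision + recall)
  acc <- rt(counts["TP"] + counts["TN"], sum(counts))
  out <- list(counts = counts,
              tpr = unname(tpr), fpr = unname(fpr),
              precision = unname(precision), recall = unname(recall),
              fscore = unname(fscore), acc = unname(acc),
              acc_pct = unname(acc) * 100)
  out$undefined <- names(Filter(function(z) length(z) == 1 && is.nan(z),
                                out[c("tpr", "fpr", "precision", "recall",
                                      "fscore", "acc")]))
  out
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with tied scores averaged: the probability that a
#' random positive outscores a random negative.  Invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores per-sample real-valued scores (larger = more positive).
#' @param labels +1/-1 labels; both classes must be present.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0) stop("both classes required for auROC")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds
stratified_folds <- function(labels, folds, seed, stratified = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assign <- integer(length(labels))
  groups <- if (stratified) split(seq_along(labels), labels)
            else list(seq_along(labels))
  for (g in groups) {
    if (stratified && length(g) < folds)
      stop("a class has fewer samples than folds")
    assign[sample(g)] <- rep_len(seq_len(folds), length(g))
  }
  assign
}

evaluation_report <- function(counts, scores, labels, fold_table = NULL,
                              aggregate = "pooled", fold_metrics = NULL) {
  rep <- metrics(counts)
  if (identical(aggregate, "mean") && !is.null(fold_metrics)) {
    for (f in c("tpr", "fpr", "precision", "recall", "fscore", "acc"))
      rep[[f]] <- mean(vapply(fold_metrics, `[[`, 0, f), na.rm = TRUE)
    rep$acc_pct <- rep$acc * 100
  }
  list(counts = rep$counts, metrics = rep,
       auroc = auroc(scores, labels),
       folds = fold_table, aggregate = aggregate)
}

#' Stratified k-fold cross-validation
#'
#' Splits the samples into `folds` stratified folds (each sample tested
#' exactly once), trains the configured model on each training fold
#' (including any per-fold selection hook in the config), and reports
#' metrics on the pooled confusion counts (`aggregate = "mean"` averages
#' fold-level rates instead; pooled counts are always reported).
#'
#' @param m a labeled [feature_matrix()]; each class needs >= `folds`
#'   samples.
#' @param config a [bagging_svm_config()] / [baseline_config()], or a
#'   function `function(train_fm, seed)` returning a fitted object with a
#'   `predict(object, fm)` method.
#' @param folds number of folds (default 5).
#' @param seed controls fold assignment and model seeds.
#' @param stratified stratify folds by class (default `TRUE`)?
#' @param aggregate `"pooled"` (default) or `"mean"`.
#' @return An evaluation report: `counts`, `metrics`, `auroc`, `folds`
#'   (per-fold breakdown).
#' @export
cross_validate <- function(m, config, folds = 5L, seed = 1L,
                           stratified = TRUE, aggregate = "pooled") {
  check_binary_labels(m)
  fold_of <- stratified_folds(m$labels, folds, seed, stratified)
  pred <- numeric(nrow(m$values))
  score <- numeric(nrow(m$values))
  fold_rows <- list()
  fold_mets <- list()
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train_fm <- subset_features(m, rows = which(fold_of != f))
    fit <- if (is.function(config)) config(train_fm, seed + f)
           else train_config(config, train_fm, seed = seed + f)
    p <- stats::predict(fit, subset_features(m, rows = test))
    pred[test] <- p$class
    score[test] <- p$score
    cnt <- confusion_counts(p$class, m$labels[test])
    fold_mets[[f]] <- metrics(cnt)
    fold_rows[[f]] <- data.frame(fold = f, n_test = length(test),
                                 acc = fold_mets[[f]]$acc)
  }
  evaluation_report(confusion_counts(pred, m$labels), score, m$labels,
                    fold_table = do.call(rbind, fold_rows),
                    aggregate = aggregate, fold_metrics = fold_mets)
}

#' Stratified holdout split
#'
#' Splits a dataset or feature matrix into disjoint train/test parts,
#' stratified by label; per-class test sizes are within one sample of the
#' exact fraction.
#'
#' @param x a [protein_dataset()] or [feature_matrix()].
#' @param test_fraction fraction held out (default 0.2).
#' @param seed RNG seed.
#' @param stratified stratify by label (default `TRUE`)?
#' @return List with `train` and `test` of the same class as `x`.
#' @export
holdout_split <- function(x, test_fraction = 0.2, seed = 1L,
                          stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  labels <- if (inherits(x, "feature_matrix")) x$labels else x$label
  n <- length(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  test_idx <- unlist(lapply(groups, function(g) {
    k <- round(length(g) * test_fraction)
    if (k == 0 || k == length(g))
      stop("class too small for the requested split")
    sample(g, k)
  }))
  take <- function(rows) {
    if (inherits(x, "feature_matrix")) subset_features(x, rows = rows)
    else protein_dataset(x$id[rows], x$sequence[rows], x$label[rows],
                         provenance = attr(x, "provenance"))
  }
  list(train = take(setdiff(seq_len(n), test_idx)), test = take(sort(test_idx)))
}

#' Parameter sweep over one axis
#'
#' Evaluates the bagging-SVM by stratified CV while varying one setting
#' (`kernel`, `C`, `T`, or `topk`) and holding the others at the defaults
#' (linear kernel, C = 1, T = 12).  `axis = "topk"` requires a
#' [ranked_features()] and sweeps the number of top-ranked features.
#'
#' @param m a labeled [feature_matrix()].
#' @param axis `"kernel"`, `"C"`, `"T"` or `"topk"`.
#' @param grid non-empty vector of settings for the axis.
#' @param ranking [ranked_features()], required for `axis = "topk"`.
#' @param T,C,kernel defaults for the non-swept settings.
#' @param folds,seed CV controls.
#' @return Data frame, one row per setting, with accuracy and the other
#'   pooled rates; full reports in `attr(, "reports")`.
#' @export
sweep_axis <- function(m, axis = c("kernel", "C", "T", "topk"), grid,
                       ranking = NULL, T = 12L, C = 1, kernel = "linear",
                       folds = 5L, seed = 1L) {
  axis <- match.arg(axis)
  if (length(grid) == 0) stop("grid must be non-empty")
  reports <- lapply(grid, function(g) {
    mm <- m
    cfg <- bagging_svm_config(T = T, C = C, kernel = kernel)
    if (axis == "kernel") cfg$kernel <- as.character(g)
    if (axis == "C") cfg$C <- as.numeric(g)
    if (axis == "T") cfg$T <- as.integer(g)
    if (axis == "topk") {
      if (is.null(ranking)) stop("axis 'topk' requires a ranking")
      if (g > nrow(ranking)) stop("k exceeds ranked feature count")
      mm <- subset_features(m, cols = ranking$descriptor[seq_len(g)])
    }
    cross_validate(mm, cfg, folds = folds, seed = seed)
  })
  out <- data.frame(
    setting = as.character(grid),
    acc = vapply(reports, function(r) r$metrics$acc, 0),
    tpr = vapply(reports, function(r) r$metrics$tpr, 0),
    fpr = vapply(reports, function(r) r$metrics$fpr, 0),
    precision = vapply(reports, function(r) r$metrics$precision, 0),
    fscore = vapply(reports, function(r) r$metrics$fscore, 0),
    auroc = vapply(reports, function(r) r$auroc, 0),
    stringsAsFactors = FALSE)
  names(out)[1] <- axis
  attr(out, "reports") <- reports
  out
}
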