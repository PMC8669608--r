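# End-to-end recipe: validate -> encode hybrid descriptors -> per-fold
# boosted-stump + MRMD selection -> bagging-SVM -> CV and holdout reports.

# selection hook used inside each training fold: boosted-stump subset of
# the monoDiKGap block, then MRMD over (subset + CC + GAAC)
pipeline_selector <- function(gap_descriptors, adaboost_rounds, mrmd_k_grid,
                              seed) {
  force(gap_descriptors)
  function(train_fm) {
    gap_fm <- subset_features(train_fm,
                              cols = intersect(colnames(train_fm$values),
                                               gap_descriptors))
    sel <- adaboost_select(gap_fm, n_estimators = adaboost_rounds,
                           seed = seed)
    other <- setdiff(colnames(train_fm$values), gap_descriptors)
    cand <- c(sel$descriptor, other)
    if (length(cand) == 0) return(other)
    mr <- mrmd_select(subset_features(train_fm, cols = cand),
                      k_grid = mrmd_k_grid, seed = seed)
    mr$descriptor
  }
}

#' Run the full druggability-prediction recipe
#'
#' Validates the dataset, encodes the full hybrid descriptor space
#' (monoDiKGap(kgap) + CC + GAAC), and evaluates a bagging-SVM ensemble
#' two ways: stratified `folds`-fold cross-validation and a stratified
#' holdout split.  Feature selection (boosted-stump reduction of the
#' gapped k-mer block followed by MRMD over the hybrid) is performed
#' inside every training fold — never on data used for testing — so the
#' reported accuracies carry no selection bias.
#'
#' @param d a labeled [protein_dataset()].
#' @param identity_threshold optional greedy identity-reduction threshold
#'   in (0, 1]; `NULL` (default) skips the filter.
#' @param kgap,lg encoder parameters (defaults 2 and 2).
#' @param T,C,kernel bagging-SVM parameters (defaults 12, 1, linear).
#' @param adaboost_rounds boosting rounds for the gapped k-mer reduction.
#' @param mrmd_k_grid optional subset-size grid for [mrmd_select()].
#' @param folds,test_fraction,seed evaluation controls.
#' @return List with `cv` and `holdout` evaluation reports, the selected
#'   holdout descriptors, and a `config` snapshot.
#' @export
full_pipeline <- function(d, identity_threshold = NULL, kgap = 2L, lg = 2L,
                          T = 12L, C = 1, kernel = "linear",
                          adaboost_rounds = 100L, mrmd_k_grid = NULL,
                          folds = 5L, test_fraction = 0.2, seed = 1L) {
  v <- validate_records(d)
  d <- v$dataset
  if (!is.null(identity_threshold))
    d <- greedy_identity_filter(d, identity_threshold)
  m <- hybrid_encode(d, kgap = kgap, lg = lg)
  gap_desc <- enumerate_monodikgap(kgap)
  cfg <- bagging_svm_config(
    T = T, C = C, kernel = kernel,
    select = pipeline_selector(gap_desc, adaboost_rounds, mrmd_k_grid, seed))

  cv <- cross_validate(m, cfg, folds = folds, seed = seed)

  split <- holdout_split(m, test_fraction = test_fraction, seed = seed)
  fit <- train_config(cfg, split$train, seed = seed)
  p <- stats::predict(fit, split$test)
  holdout <- evaluation_report(confusion_counts(p$class, split$test$labels),
                               p$score, split$test$labels)

  list(cv = cv, holdout = holdout,
       selected = fit$descriptors,
       rejected = v$rejected,
       config = list(kgap = kgap, lg = lg, T = T, C = C, kernel = kernel,
                     adaboost_rounds = adaboost_rounds, folds = folds,
                     test_fraction = test_fraction, seed = seed,
                     identity_threshold = identity_threshold))
}

#' Write a machine-readable provenance record
#'
#' Every CLI run records its inputs, parameters, seed and package version
#' so the run can be replayed exactly.
#'
#' @param path output JSON file.
#' @param subcommand the pipeline stage executed.
#' @param params named list of parameters (must be JSON-representable).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, subcommand, params) {
  rec <- list(subcommand = subcommand,
              params = params,
              package = "drughybrid",
              version = as.character(utils::packageVersion("drughybrid")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an evaluation report (from [cross_validate()] or
#'   [full_pipeline()]).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  to_list <- function(r) list(
    counts = as.list(r$counts),
    tpr = r$metrics$tpr, fpr = r$metrics$fpr,
    precision = r$metrics$precision, recall = r$metrics$recall,
    fscore = r$metrics$fscore, acc = r$metrics$acc,
    acc_pct = r$metrics$acc_pct, auroc = r$auroc,
    undefined = r$metrics$undefined,
    folds = r$folds)
  out <- if (!is.null(report$cv))
    list(cv = to_list(report$cv), holdout = to_list(report$holdout),
         config = report$config)
  else to_list(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "string")
  invisible(path)
}
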