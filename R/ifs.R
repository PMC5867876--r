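# Incremental forward selection: nested candidate sets F1 c F2 c ... built
# by walking down the MCFS ranking, each evaluated by stratified k-fold
# cross-validated classification, scored primarily by MCC. One fold
# assignment is shared across all candidate sets so curve differences
# reflect the features, not fold noise.

#' Nested candidate feature sets from a ranking
#'
#' @param ranking a `feature_ranking` from [rank_features()] (or any
#'   data.frame with a `gene_id` column in rank order).
#' @return list of character vectors; element i holds the top-i genes.
#' @export
build_candidate_sets <- function(ranking) {
  genes <- as.character(ranking$gene_id)
  abort_if(length(genes) == 0L, "empty ranking")
  lapply(seq_along(genes), function(i) genes[seq_len(i)])
}

#' Classifier specification for candidate evaluation
#'
#' `"ranger"` is the random-forest evaluator used throughout;
#' `"majority"` always predicts the training majority class (a calibration
#' baseline).
#'
#' @param name `"ranger"` or `"majority"`.
#' @param num_trees number of forest trees.
#' @param mtry features per split; `NULL` for the ranger default
#'   (floor(sqrt(p))).
#' @param seed integer seed for the forest.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(name = "ranger", num_trees = 500L, mtry = NULL,
                            seed = 1L) {
  abort_if(!name %in% c("ranger", "majority"),
           "unsupported classifier: ", name)
  structure(list(name = name, num_trees = as.integer(num_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

.fit_predict <- function(clf, x_train, y_train, x_test, fold_seed) {
  if (clf$name == "majority") {
    tab <- table(y_train)
    maj <- names(tab)[which.max(tab)]
    return(factor(rep(maj, nrow(x_test)), levels = levels(y_train)))
  }
  df <- data.frame(x_train, check.names = FALSE)
  df$.class <- y_train
  # the surrounding with_seed pins R's global RNG too: forest vote ties
  # (possible with an even tree count) are broken through it at prediction
  # time
  with_seed(fold_seed, {
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = df,
      num.trees = clf$num_trees,
      mtry = if (is.null(clf$mtry)) NULL else min(clf$mtry, ncol(x_train)),
      seed = fold_seed, num.threads = 1L, verbose = FALSE)
    predict(fit, data.frame(x_test, check.names = FALSE),
            num.threads = 1L)$predictions
  })
}

#' Cross-validated evaluation of one candidate feature set
#'
#' Trains on out-of-fold cells restricted to `features`, predicts each
#' fold, and reports per-fold MCC, per-class recalls, sensitivity/
#' specificity for `positive_class`, and accuracy, plus their means.
#'
#' @param m an imputed [expression_matrix()].
#' @param features character vector of gene ids.
#' @param clf a [classifier_spec()].
#' @param folds fold assignment from [stratified_folds()].
#' @param positive_class class treated as positive for sensitivity/
#'   specificity; defaults to the minority class.
#' @return list with `per_fold` (data.frame) and `mean` (named numeric).
#' @export
evaluate_candidate <- function(m, features, clf, folds,
                               positive_class = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  missing_feats <- setdiff(features, gene_ids(m))
  abort_if(length(missing_feats) > 0,
           "features not in matrix: ", paste(missing_feats, collapse = ", "))
  y <- droplevels(m$labels)
  if (is.null(positive_class)) {
    positive_class <- names(which.min(table(y)))
  }
  X <- m$values[, features, drop = FALSE]
  rows <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    abort_if(nlevels(droplevels(y[tr])) < 2L,
             "degenerate fold: training data for fold ", f,
             " contains a single class")
    pred <- .fit_predict(clf, X[tr, , drop = FALSE], y[tr],
                         X[!tr, , drop = FALSE],
                         derive_seed(clf$seed, 5L, f))
    cc <- confusion_counts(y[!tr], pred, levels(y))
    bm <- basic_metrics(cc, positive_class)
    fold_mcc <- withCallingHandlers(
      mcc_labels(y[!tr], pred, levels(y)),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(fold = f, mcc = fold_mcc, sensitivity = bm[["sensitivity"]],
               specificity = bm[["specificity"]], accuracy = bm[["accuracy"]])
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("mcc", "sensitivity", "specificity",
                                    "accuracy")]))
}

#' Run incremental forward selection
#'
#' Evaluates every nested candidate set against a single shared stratified
#' fold assignment and selects the set maximizing mean cross-validated MCC;
#' MCC ties resolve to the smaller feature count (parsimony).
#'
#' @param m an imputed [expression_matrix()].
#' @param ranking a `feature_ranking` from [rank_features()].
#' @param clf a [classifier_spec()]; default 500-tree random forest.
#' @param n_folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param positive_class see [evaluate_candidate()].
#' @return an `ifs_result` list: `curve` (data.frame `i`, `mcc`,
#'   `sensitivity`, `specificity`, `accuracy`), `optimal_index`,
#'   `optimal_features`, `folds`.
#' @export
run_ifs <- function(m, ranking, clf = classifier_spec(), n_folds = 10L,
                    seed = 1L, positive_class = NULL) {
  sets <- build_candidate_sets(ranking)
  folds <- stratified_folds(m$labels, n_folds, seed)
  curve <- do.call(rbind, lapply(seq_along(sets), function(i) {
    ev <- evaluate_candidate(m, sets[[i]], clf, folds, positive_class)
    data.frame(i = i, mcc = ev$mean[["mcc"]],
               sensitivity = ev$mean[["sensitivity"]],
               specificity = ev$mean[["specificity"]],
               accuracy = ev$mean[["accuracy"]])
  }))
  opt <- which.max(curve$mcc)  # first maximum -> smallest i on ties
  structure(list(curve = curve, optimal_index = opt,
                 optimal_features = sets[[opt]], folds = folds),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("<ifs_result> ", nrow(x$curve), " candidate sets; optimum i* = ",
      x$optimal_index, " (mean CV MCC = ",
      sprintf("%.4f", x$curve$mcc[x$optimal_index]), ")\n", sep = "")
  invisible(x)
}

#' Write an IFS curve as TSV
#'
#' @param result an `ifs_result` from [run_ifs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(result, path) {
  utils::write.table(result$curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
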