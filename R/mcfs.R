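# Monte Carlo feature selection: s random projections of m features, t
# decision trees per projection (each on its own stratified train/test
# split), relative importance accumulated per feature as
#
#   RI_g = sum over trees tau of (wAcc_tau)^u *
#          sum over nodes of tau splitting on g of
#            IG(node) * (n_node / n_tree)^v
#
# with wAcc the mean per-class accuracy of the tree on its held-out cells
# and IG the base-2 information gain of the split.

#' Parameters for Monte Carlo feature selection
#'
#' @param d total number of features (genes).
#' @param s number of random feature subsets (projections).
#' @param t trees per subset, each on a fresh stratified train/test split.
#' @param m features per subset; default `max(ceiling(0.05 * d), 2)`.
#' @param u exponent on the per-tree weighted accuracy.
#' @param v exponent on the node sample fraction.
#' @param train_fraction fraction of cells used to grow each tree.
#' @param min_split minimum node size still eligible for splitting.
#' @param seed integer seed; per-tree seeds are derived deterministically
#'   from (seed, subset, tree), so results are independent of execution
#'   order.
#' @return an `mcfs_params` list.
#' @export
mcfs_params <- function(d, s = 1000L, t = 5L, m = max(ceiling(0.05 * d), 2L),
                        u = 1, v = 1, train_fraction = 0.66, min_split = 2L,
                        seed = 1L) {
  abort_if(m < 1 || m > d, "m must satisfy 1 <= m <= d (m=", m, ", d=", d, ")")
  abort_if(s < 1 || t < 1, "s and t must be >= 1")
  abort_if(train_fraction <= 0 || train_fraction >= 1,
           "train_fraction must be in (0, 1)")
  abort_if(!is.finite(u) || !is.finite(v), "u and v must be finite")
  structure(list(d = as.integer(d), s = as.integer(s), t = as.integer(t),
                 m = as.integer(m), u = u, v = v,
                 train_fraction = train_fraction,
                 min_split = as.integer(min_split), seed = as.integer(seed)),
            class = "mcfs_params")
}

#' Draw random feature projections
#'
#' @param d total feature count.
#' @param m subset size (uniform sampling without replacement).
#' @param s number of subsets.
#' @param seed integer seed.
#' @return list of `s` integer vectors of length `m`.
#' @export
sample_projections <- function(d, m, s, seed = 1L) {
  abort_if(m > d, "m (", m, ") exceeds d (", d, ")")
  lapply(seq_len(s), function(i) {
    with_seed(derive_seed(seed, 1L, i), sort(sample.int(d, m)))
  })
}

#' Weighted (class-balanced) accuracy
#'
#' Unweighted mean over classes of per-class accuracy (recall); classes
#' absent from `truth` are excluded. Insensitive to class imbalance.
#'
#' @param predicted,truth label vectors of equal length.
#' @return value in \[0, 1\].
#' @export
weighted_accuracy <- function(predicted, truth) {
  abort_if(length(predicted) != length(truth), "length mismatch")
  abort_if(length(truth) == 0L, "empty input")
  truth <- as.character(truth); predicted <- as.character(predicted)
  mean(vapply(unique(truth), function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1)))
}

.entropy_bits <- function(labels) {
  if (length(labels) == 0L) return(0)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon information gain of a binary split, in bits
#'
#' @param parent_labels labels at the node.
#' @param left_labels,right_labels labels of the two children; together they
#'   must re-form `parent_labels` as a multiset.
#' @return non-negative gain in bits.
#' @export
information_gain <- function(parent_labels, left_labels, right_labels) {
  child <- c(as.character(left_labels), as.character(right_labels))
  abort_if(!identical(sort(as.character(parent_labels)), sort(child)),
           "left and right do not partition the parent")
  n <- length(parent_labels)
  .entropy_bits(parent_labels) -
    length(left_labels) / n * .entropy_bits(left_labels) -
    length(right_labels) / n * .entropy_bits(right_labels)
}

#' Rank features by Monte Carlo relative importance
#'
#' Builds `s * t` projection trees and accumulates each feature's RI from
#' the splits it appears in, weighted by the owning tree's held-out
#' weighted accuracy (see module header). Features never drawn into any
#' projection score 0. Ties in RI resolve to the lower original column
#' index.
#'
#' @param m an imputed [expression_matrix()] (no missing values, >= 2
#'   classes).
#' @param params an [mcfs_params()].
#' @param resample optional `function(labels, seed)` returning
#'   `list(train=, test=)` index vectors, replacing the default
#'   [stratified_split()]; intended for custom resampling designs.
#' @return a `feature_ranking` data.frame with columns `rank`, `gene_id`,
#'   `ri`, ordered by descending RI.
#' @export
rank_features <- function(m, params, resample = NULL) {
  stopifnot(inherits(m, "expression_matrix"), inherits(params, "mcfs_params"))
  abort_if(any(m$missing_mask), "matrix must be imputed before ranking")
  abort_if(nlevels(droplevels(m$labels)) < 2L,
           "degenerate labels: need >= 2 classes")
  d <- ncol(m$values)
  abort_if(params$d != d, "params$d (", params$d, ") != number of genes (", d, ")")
  if (is.null(resample)) {
    resample <- function(labels, seed)
      stratified_split(labels, params$train_fraction, seed)
  }
  y <- as.integer(droplevels(m$labels)) - 1L
  n_class <- max(y) + 1L
  subsets <- sample_projections(d, params$m, params$s, params$seed)
  ri <- numeric(d)
  for (si in seq_len(params$s)) {
    feats <- subsets[[si]]
    Xs <- m$values[, feats, drop = FALSE]
    for (ti in seq_len(params$t)) {
      sp <- resample(m$labels, derive_seed(params$seed, 2L, si, ti))
      tree <- build_tree_cpp(Xs[sp$train, , drop = FALSE], y[sp$train],
                             n_class, params$min_split)
      pred <- predict_tree_cpp(tree, Xs[sp$test, , drop = FALSE])
      wacc <- weighted_accuracy(pred, y[sp$test])
      internal <- which(tree$feature >= 0L)
      if (length(internal) == 0L) next
      contrib <- tree$gain[internal] *
        (tree$n_node[internal] / tree$n_tree)^params$v
      w <- wacc^params$u
      for (k in seq_along(internal)) {
        g <- feats[tree$feature[internal[k]] + 1L]
        ri[g] <- ri[g] + w * contrib[k]
      }
    }
  }
  ord <- order(-ri, seq_len(d))
  out <- data.frame(rank = seq_len(d), gene_id = gene_ids(m)[ord],
                    ri = ri[ord], stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Permutation-based RI significance cutoff
#'
#' Re-runs [rank_features()] on `n_perm` label-permuted copies of the data
#' and returns the requested quantile of the per-permutation maximum RI.
#' Genes whose observed RI exceeds the cutoff are reported as significant.
#'
#' @param m an imputed [expression_matrix()].
#' @param params an [mcfs_params()].
#' @param n_perm number of label permutations (>= 1).
#' @param quantile_level quantile of the null maxima used as threshold.
#' @return list with `threshold`, `null_max` (per-permutation maxima), and
#'   `significant` (gene ids above threshold, from the observed ranking).
#' @export
ri_cutoff <- function(m, params, n_perm = 20L, quantile_level = 0.95) {
  abort_if(n_perm < 1, "n_perm must be >= 1")
  null_max <- vapply(seq_len(n_perm), function(b) {
    perm <- with_seed(derive_seed(params$seed, 3L, b),
                      sample.int(length(m$labels)))
    mp <- expression_matrix(m$values, m$labels[perm], m$missing_mask)
    pp <- params
    pp$seed <- derive_seed(params$seed, 4L, b)
    max(rank_features(mp, pp)$ri)
  }, numeric(1))
  thr <- as.numeric(quantile(null_max, quantile_level))
  obs <- rank_features(m, params)
  list(threshold = thr, null_max = null_max,
       significant = obs$gene_id[obs$ri > thr])
}

#' Write a feature ranking as TSV
#'
#' Columns `rank`, `gene_id`, `ri`; MCFS parameters echoed as a JSON header
#' comment line.
#'
#' @param ranking a `feature_ranking` from [rank_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  params <- attr(ranking, "params")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(paste0("# params: ", jsonlite::toJSON(unclass(params),
                                                     auto_unbox = TRUE)), con)
  }
  utils::write.table(as.data.frame(ranking), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
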