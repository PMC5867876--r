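# Shared fixtures: tiny matrices built in code, a CSV writer, and the
# brute-force minimal-reduct oracle used to check the Johnson heuristic.

make_matrix <- function(values, labels, genes = NULL, cells = NULL) {
  values <- as.matrix(values)
  if (!is.null(genes)) colnames(values) <- genes
  if (!is.null(cells)) rownames(values) <- cells
  expression_matrix(values, labels)
}

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random small decision system over integer-coded attributes
random_decision_system <- function(n_obj, n_attr, n_vals = 2L, seed = 1L) {
  set.seed(seed)
  vals <- matrix(sample.int(n_vals, n_obj * n_attr, replace = TRUE),
                 n_obj, n_attr,
                 dimnames = list(paste0("o", seq_len(n_obj)),
                                 paste0("a", seq_len(n_attr))))
  labels <- sample(c("A", "B"), n_obj, replace = TRUE)
  if (length(unique(labels)) == 1L) labels[1] <- setdiff(c("A", "B"), labels[1])
  m <- expression_matrix(vals, labels)
  build_decision_system(m, colnames(vals), discretize = "none")
}

# smallest attribute-subset size that preserves full-set discernibility,
# by exhaustive enumeration (oracle for the Johnson greedy heuristic)
brute_force_min_reduct_size <- function(ds) {
  p <- length(ds$features)
  for (k in 1:p) {
    combos <- utils::combn(p, k)
    for (ci in seq_len(ncol(combos))) {
      if (reduct_valid(ds, combos[, ci])) return(k)
    }
  }
  p
}

# classical binary MCC from confusion counts
classical_binary_mcc <- function(tp, fn, tn, fp) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# label vectors realizing a binary confusion matrix
confusion_labels <- function(tp, fn, tn, fp) {
  list(truth = c(rep("pos", tp + fn), rep("neg", tn + fp)),
       pred = c(rep("pos", tp), rep("neg", fn),
                rep("neg", tn), rep("pos", fp)))
}
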