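# Internal helpers shared across modules.

#' Derive a deterministic sub-seed from a base seed and integer ids
#'
#' Linear-congruential mixing keeps every derived seed inside the 32-bit
#' integer range; results depend only on the base seed and the ids, never on
#' execution order, so parallel or reordered loops reproduce bit-identically.
#'
#' @param seed base integer seed.
#' @param ... integer ids (e.g. subset index, tree index).
#' @return a single integer seed between 0 and 2^31 - 2.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (id in ids) {
    x <- (x * 48271 + as.numeric(id) * 2246822519 + 1013904223) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Stratified train/test split
#'
#' Draws `train_fraction` of each class (rounded, but at least one cell kept
#' on each side whenever a class has two or more members) into the training
#' set. Deterministic given `seed`.
#'
#' @param labels factor or vector of class labels.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.66, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- as.factor(labels)
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_cl <- length(idx)
      if (n_cl == 0L) next
      n_tr <- round(train_fraction * n_cl)
      if (n_cl >= 2L) n_tr <- min(max(n_tr, 1L), n_cl - 1L) else n_tr <- 1L
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Stratified cross-validation fold assignment
#'
#' Distributes each class across folds as evenly as possible (fold sizes for
#' a class differ by at most one cell). Deterministic given `seed`.
#'
#' @param labels factor or vector of class labels.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..n_folds), one per cell.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds number of cells (", n, ")")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  tab <- table(labels)
  if (any(tab < n_folds)) {
    warning("class(es) ", paste(names(tab)[tab < n_folds], collapse = ", "),
            " have fewer members than folds; some folds will lack them")
  }
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    # the fold counter continues across classes so all n_folds folds are
    # used even when a class has fewer members than folds (leave-one-out
    # limit included)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  fold
}

# Assert helper producing consistent error messages.
abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
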