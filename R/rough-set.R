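# Rough-set machinery: supervised entropy/MDL discretization, decision
# systems with generalized decisions, discernibility matrices and
# product-of-sums discernibility functions (simplified by idempotence and
# absorption), and the greedy Johnson reduct.

# ---- supervised discretization (Fayyad-Irani entropy/MDL) -------------------

# Returns cut points for one continuous attribute given class labels; empty
# when no cut passes the MDL criterion (the attribute then discretizes to a
# single constant bin).
mdl_cuts <- function(x, y) {
  y <- as.factor(y)
  rec <- function(idx) {
    xv <- x[idx]; yv <- y[idx]
    n <- length(idx)
    ord <- order(xv)
    xv <- xv[ord]; yv <- yv[ord]
    ux <- unique(xv)
    if (length(ux) < 2L || n < 4L) return(numeric(0))
    h_parent <- .entropy_bits(yv)
    best <- NULL; best_ent <- Inf
    boundaries <- which(diff(xv) > 0)
    for (b in boundaries) {
      left <- yv[seq_len(b)]; right <- yv[-seq_len(b)]
      ent <- length(left) / n * .entropy_bits(left) +
        length(right) / n * .entropy_bits(right)
      if (ent < best_ent - 1e-12) {
        best_ent <- ent
        best <- b
      }
    }
    if (is.null(best)) return(numeric(0))
    left <- yv[seq_len(best)]; right <- yv[-seq_len(best)]
    gain <- h_parent - best_ent
    k <- nlevels(droplevels(yv))
    k1 <- nlevels(droplevels(left)); k2 <- nlevels(droplevels(right))
    delta <- log2(3^k - 2) -
      (k * h_parent - k1 * .entropy_bits(left) - k2 * .entropy_bits(right))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (xv[best] + xv[best + 1L]) / 2
    lidx <- idx[x[idx] <= cut]; ridx <- idx[x[idx] > cut]
    c(rec(lidx), cut, rec(ridx))
  }
  sort(rec(seq_along(x)))
}

apply_cuts <- function(x, cuts) {
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}

# ---- decision system --------------------------------------------------------

#' Build a rough-set decision system
#'
#' Views the expression matrix restricted to `features` as objects x
#' condition attributes with the class label as decision attribute, and
#' computes the generalized decision: for each object, the set of labels
#' occurring among objects with an identical attribute vector.
#'
#' @param m an imputed [expression_matrix()].
#' @param features non-empty character vector of gene ids.
#' @param discretize `"mdl"` for supervised entropy/MDL discretization of
#'   each gene (used by the discernibility stage) or `"none"` to keep raw
#'   values.
#' @return a `decision_system` list: `values` (attribute matrix, discrete
#'   codes or raw), `raw_values`, `labels`, `features`, `cuts` (per-gene
#'   cut points when discretized), `gdec` (per-object sorted label sets),
#'   `gdec_key` (string key of `gdec` for fast comparison).
#' @export
build_decision_system <- function(m, features, discretize = c("mdl", "none")) {
  stopifnot(inherits(m, "expression_matrix"))
  discretize <- match.arg(discretize)
  abort_if(length(features) == 0L, "empty feature set")
  missing_feats <- setdiff(features, gene_ids(m))
  abort_if(length(missing_feats) > 0,
           "features not in matrix: ", paste(missing_feats, collapse = ", "))
  abort_if(any(m$missing_mask), "matrix must be imputed first")
  raw <- m$values[, features, drop = FALSE]
  labels <- droplevels(m$labels)
  cuts <- NULL
  if (discretize == "mdl") {
    cuts <- lapply(seq_along(features), function(j) mdl_cuts(raw[, j], labels))
    names(cuts) <- features
    vals <- vapply(seq_along(features),
                   function(j) apply_cuts(raw[, j], cuts[[j]]),
                   integer(nrow(raw)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    dimnames(vals) <- dimnames(raw)
  } else {
    vals <- raw
  }
  profile <- apply(vals, 1L, paste, collapse = "\r")
  gdec <- lapply(split(as.character(labels), profile), function(ls) sort(unique(ls)))
  gd <- gdec[profile]
  structure(list(values = vals, raw_values = raw, labels = labels,
                 features = features, cuts = cuts,
                 gdec = unname(gd),
                 gdec_key = vapply(gd, paste, "", collapse = "|")),
            class = "decision_system")
}

# ---- discernibility ---------------------------------------------------------

# Simplify a product of sums under idempotence (duplicate conjunction
# removal) and absorption (a sum that is a superset of another sum is
# removed). `sets` is a list of sorted integer vectors.
simplify_pos <- function(sets) {
  if (length(sets) == 0L) return(sets)
  keys <- vapply(sets, paste, "", collapse = ",")
  sets <- sets[!duplicated(keys)]
  lens <- lengths(sets)
  sets <- sets[order(lens)]
  kept <- list()
  by_attr <- list()  # attr -> indices of kept sets containing it
  klens <- integer(0)
  for (s in sets) {
    hits <- integer(length(kept))
    for (a in s) {
      ids <- by_attr[[as.character(a)]]
      if (!is.null(ids)) hits[ids] <- hits[ids] + 1L
    }
    if (any(hits == klens[seq_along(hits)])) next  # absorbed by a subset
    kept[[length(kept) + 1L]] <- s
    klens <- c(klens, length(s))
    for (a in s) {
      key <- as.character(a)
      by_attr[[key]] <- c(by_attr[[key]], length(kept))
    }
  }
  kept
}

# Bit-chunked difference keys: encode which attributes differ between two
# objects as one double per chunk of <= 50 attributes (exact in doubles).
.diff_keys <- function(vals) {
  p <- ncol(vals)
  chunks <- split(seq_len(p), ceiling(seq_len(p) / 50))
  weights <- lapply(chunks, function(ch) 2^(seq_along(ch) - 1))
  n <- nrow(vals)
  keyfun <- function(i, js) {
    # returns character keys of the differing-attribute sets of (i, js)
    neq <- vals[js, , drop = FALSE] !=
      matrix(vals[i, ], length(js), p, byrow = TRUE)
    parts <- vapply(seq_along(chunks), function(ci) {
      neq[, chunks[[ci]], drop = FALSE] %*% weights[[ci]]
    }, numeric(length(js)))
    if (is.null(dim(parts))) parts <- matrix(parts, nrow = length(js))
    apply(parts, 1L, paste, collapse = "_")
  }
  decode <- function(key) {
    parts <- as.numeric(strsplit(key, "_", fixed = TRUE)[[1]])
    out <- integer(0)
    for (ci in seq_along(chunks)) {
      k <- parts[ci]
      bits <- integer(0)
      pos <- 1L
      while (k > 0) {
        if (k %% 2 == 1) bits <- c(bits, pos)
        k <- k %/% 2
        pos <- pos + 1L
      }
      out <- c(out, chunks[[ci]][bits])
    }
    out
  }
  list(keyfun = keyfun, decode = decode)
}

#' Discernibility structure of a decision system
#'
#' For every object pair with different generalized decisions, collects the
#' set of attributes on which the pair differs (pairs with equal
#' generalized decisions are never discerned). Materializes the per-object
#' discernibility functions f(x) and the global function g(U), each a
#' product of sums simplified by idempotence and absorption.
#'
#' @param s a `decision_system` from [build_decision_system()].
#' @param keep_pairs store the full pair list (memory-heavy for large
#'   systems); defaults to `TRUE` for systems with <= 200 objects.
#' @return a `discernibility_structure` list: `f` (per-object list of
#'   attribute-index conjunctions), `g` (global conjunction list),
#'   `attrs` (attribute names), optionally `pairs` (data.frame `i`, `j`,
#'   `set_id`) with `sets` (the distinct attribute sets).
#' @export
discernibility_matrix <- function(s, keep_pairs = nrow(s$values) <= 200L) {
  stopifnot(inherits(s, "decision_system"))
  n <- nrow(s$values)
  enc <- .diff_keys(s$values)
  key_cache <- new.env(parent = emptyenv())
  row_keys <- vector("list", n)   # unique keys touching each object
  pair_i <- integer(0); pair_j <- integer(0); pair_key <- character(0)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    js <- js[s$gdec_key[js] != s$gdec_key[i]]
    if (length(js) == 0L) next
    keys <- enc$keyfun(i, js)
    row_keys[[i]] <- c(row_keys[[i]], keys)
    for (jj in seq_along(js)) {
      row_keys[[js[jj]]] <- c(row_keys[[js[jj]]], keys[jj])
    }
    if (keep_pairs) {
      pair_i <- c(pair_i, rep(i, length(js)))
      pair_j <- c(pair_j, js)
      pair_key <- c(pair_key, keys)
    }
  }
  decode_unique <- function(keys) {
    lapply(unique(keys), function(k) {
      if (is.null(key_cache[[k]])) key_cache[[k]] <- enc$decode(k)
      key_cache[[k]]
    })
  }
  f <- lapply(row_keys, function(keys) {
    if (length(keys) == 0L) return(list())
    simplify_pos(decode_unique(keys))
  })
  g <- simplify_pos(decode_unique(unlist(row_keys, use.names = FALSE)))
  out <- list(f = f, g = g, attrs = s$features, n = n)
  if (keep_pairs) {
    sets_keys <- unique(pair_key)
    out$sets <- decode_unique(sets_keys)  # unsimplified distinct entries
    out$pairs <- data.frame(i = pair_i, j = pair_j,
                            set_id = match(pair_key, sets_keys))
  }
  structure(out, class = "discernibility_structure")
}

#' Look up one discernibility-matrix entry
#'
#' @param ds a `discernibility_structure` built with `keep_pairs = TRUE`.
#' @param i,j object indices.
#' @return character vector of discerning attribute names (empty when the
#'   pair is not discerned).
#' @export
discernibility_entry <- function(ds, i, j) {
  abort_if(is.null(ds$pairs), "structure was built with keep_pairs = FALSE")
  if (i == j) return(character(0))
  lo <- min(i, j); hi <- max(i, j)
  hit <- which(ds$pairs$i == lo & ds$pairs$j == hi)
  if (length(hit) == 0L) return(character(0))
  ds$attrs[ds$sets[[ds$pairs$set_id[hit[1]]]]]
}

#' Johnson reduct of a discernibility function
#'
#' Greedy set cover over the conjunctions: repeatedly pick the attribute
#' occurring in the most remaining conjunctions (ties to the lowest
#' attribute index), add it to the reduct, and drop every conjunction it
#' covers, until none remain.
#'
#' @param x a `discernibility_structure` (its global function `g` is used),
#'   or directly a list of integer-vector conjunctions.
#' @param attrs optional attribute names for labeling the result.
#' @return character (or integer, when unnamed) vector: the reduct.
#' @export
johnson_reduct <- function(x, attrs = NULL) {
  if (inherits(x, "discernibility_structure")) {
    if (is.null(attrs)) attrs <- x$attrs
    conj <- x$g
  } else {
    conj <- x
  }
  abort_if(any(lengths(conj) == 0L),
           "logic error: empty conjunction in discernibility function")
  reduct <- integer(0)
  while (length(conj) > 0L) {
    freq <- table(unlist(lapply(conj, unique)))
    ids <- as.integer(names(freq))
    best <- ids[freq == max(freq)]
    a <- min(best)  # tie-break: ascending attribute index
    reduct <- c(reduct, a)
    conj <- conj[!vapply(conj, function(s) a %in% s, logical(1))]
  }
  reduct <- sort(reduct)
  if (!is.null(attrs)) attrs[reduct] else reduct
}

#' Check that an attribute subset preserves discernibility
#'
#' @param s a `decision_system`.
#' @param subset attribute names (or indices) to test.
#' @return `TRUE` when every object pair discerned by the full attribute
#'   set (i.e. differing generalized decisions and at least one differing
#'   attribute) also differs on some attribute of `subset`.
#' @export
reduct_valid <- function(s, subset) {
  stopifnot(inherits(s, "decision_system"))
  if (is.character(subset)) subset <- match(subset, s$features)
  n <- nrow(s$values)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (s$gdec_key[i] == s$gdec_key[j]) next
      full_diff <- any(s$values[i, ] != s$values[j, ])
      if (!full_diff) next
      if (!any(s$values[i, subset] != s$values[j, subset])) return(FALSE)
    }
  }
  TRUE
}
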