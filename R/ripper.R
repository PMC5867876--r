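# RIPPER rule induction over continuous attributes, restricted to a reduct:
# rules for the minority class are grown condition-by-condition by FOIL
# gain on a growing set, pruned on a pruning set by worth (p - n)/(p + n),
# admitted under an IREP precision check and an MDL budget, then revisited
# in global optimization passes (replacement/revision, MDL-best kept). The
# majority class becomes the condition-free default rule.

#' FOIL information gain of a rule refinement
#'
#' `p0`/`n0` are positives/negatives covered before the refinement and
#' `p`/`n` after; gain is `p * (log2(p/(p+n)) - log2(p0/(p0+n0)))`, with 0
#' when the refinement covers no positives.
#'
#' @param p0,n0,p,n non-negative counts with `p <= p0`, `n <= n0`.
#' @return gain in bits.
#' @export
foil_gain <- function(p0, n0, p, n) {
  abort_if(p0 + n0 == 0, "logic error: empty parent coverage")
  abort_if(p > p0 || n > n0 || min(p0, n0, p, n) < 0, "invalid counts")
  if (p == 0) return(0)
  p * (log2(p / (p + n)) - log2(p0 / (p0 + n0)))
}

#' RIPPER parameters
#'
#' @param grow_frac fraction of the training data used as the growing set
#'   (remainder prunes); the split is stratified.
#' @param dl_budget description-length slack in bits: rule search stops
#'   once the ruleset's MDL exceeds the best seen by more than this.
#' @param k_opt number of global optimization passes.
#' @param seed integer seed; per-rule seeds are derived from it.
#' @return a `ripper_params` list.
#' @export
ripper_params <- function(grow_frac = 2 / 3, dl_budget = 64, k_opt = 2L,
                          seed = 1L) {
  abort_if(grow_frac <= 0 || grow_frac >= 1, "grow_frac must be in (0, 1)")
  structure(list(grow_frac = grow_frac, dl_budget = dl_budget,
                 k_opt = as.integer(k_opt), seed = as.integer(seed)),
            class = "ripper_params")
}

# vectorized FOIL gain used in the grow search (p may be a vector)
.foil_gain_vec <- function(p0, n0, p, n) {
  base <- log2(p0 / (p0 + n0))
  g <- p * (log2(p / (p + n)) - base)
  g[p == 0] <- 0
  g
}

# internal rule representation: list of (attr index, op, threshold)
.cover_conds <- function(conds, X, idx) {
  for (cc in conds) {
    v <- X[idx, cc$attr]
    idx <- idx[if (cc$op == ">=") v >= cc$threshold else v <= cc$threshold]
    if (length(idx) == 0L) break
  }
  idx
}

.grow_rule <- function(X, pos, idx) {
  .grow_rule_excluding(X, pos, idx, integer(0))
}

# worth of a rule on a pruning set: (p - n) / (p + n), -1 on zero coverage
.rule_worth <- function(conds, X, pos, idx) {
  cov <- .cover_conds(conds, X, idx)
  p <- sum(pos[cov]); n <- sum(!pos[cov])
  if (p + n == 0L) return(-1)
  (p - n) / (p + n)
}

.prune_rule <- function(conds, X, pos, idx_prune) {
  if (length(conds) == 0L) return(conds)
  worth <- vapply(seq_along(conds), function(j) {
    .rule_worth(conds[seq_len(j)], X, pos, idx_prune)
  }, numeric(1))
  conds[seq_len(which.max(worth))]  # ties -> shortest prefix
}

# ruleset MDL on the full training data: per-condition theory bits plus
# binomially coded exception bits (false positives among covered, false
# negatives among uncovered).
.ruleset_dl <- function(rules, X, pos) {
  n <- nrow(X)
  cond_bits <- log2(2 * ncol(X)) + log2(max(n, 2))
  theory <- sum(vapply(rules, length, 1L)) * cond_bits +
    length(rules) * log2(max(length(rules) + 1, 2))
  covered <- rep(FALSE, n)
  for (r in rules) covered[.cover_conds(r, X, seq_len(n))] <- TRUE
  fp <- sum(covered & !pos)
  fn <- sum(!covered & pos)
  ncov <- sum(covered)
  exceptions <- log2(ncov + 1) + lchoose(ncov, fp) / log(2) +
    log2(n - ncov + 1) + lchoose(n - ncov, fn) / log(2)
  theory + exceptions
}

.grow_prune_once <- function(X, pos, idx, seed, start_conds = NULL) {
  sp <- stratified_split(factor(ifelse(pos[idx], "p", "n")), 2 / 3, seed)
  grow_idx <- idx[sp$train]; prune_idx <- idx[sp$test]
  conds <- if (is.null(start_conds)) list() else start_conds
  grown <- .grow_rule_from(X, pos, grow_idx, conds)
  .prune_rule(grown, X, pos, prune_idx)
}

# grow starting from existing conditions (used by the revision variant)
.grow_rule_from <- function(X, pos, idx, conds) {
  idx <- .cover_conds(conds, X, idx)
  more <- .grow_rule_excluding(X, pos, idx,
                               vapply(conds, function(cc) cc$attr, 1L))
  c(conds, more)
}

.grow_rule_excluding <- function(X, pos, idx, used0) {
  # same as .grow_rule but with pre-used attributes excluded
  conds <- list(); used <- used0
  repeat {
    p0 <- sum(pos[idx]); n0 <- sum(!pos[idx])
    if (n0 == 0L || p0 == 0L) break
    best <- NULL; best_gain <- 0
    for (j in setdiff(seq_len(ncol(X)), used)) {
      v <- X[idx, j]
      ord <- order(v)
      vs <- v[ord]; ps <- pos[idx][ord]
      cpos <- cumsum(ps); cneg <- cumsum(!ps)
      b <- which(diff(vs) > 0)
      if (length(b) == 0L) next
      thr <- (vs[b] + vs[b + 1L]) / 2
      g_le <- .foil_gain_vec(p0, n0, cpos[b], cneg[b])
      g_ge <- .foil_gain_vec(p0, n0, p0 - cpos[b], n0 - cneg[b])
      for (op in c("<=", ">=")) {
        g <- if (op == "<=") g_le else g_ge
        k <- which.max(g)
        if (length(k) == 1L && g[k] > best_gain + 1e-12) {
          best_gain <- g[k]
          best <- list(attr = j, op = op, threshold = thr[k])
        }
      }
    }
    if (is.null(best)) break
    conds[[length(conds) + 1L]] <- best
    used <- c(used, best$attr)
    idx <- .cover_conds(list(best), X, idx)
  }
  conds
}

# IREP admission: pruned rule must keep majority-positive precision on the
# pruning set and cover at least one positive.
.rule_admissible <- function(conds, X, pos, prune_idx) {
  if (length(conds) == 0L) return(FALSE)
  cov <- .cover_conds(conds, X, prune_idx)
  p <- sum(pos[cov]); n <- sum(!pos[cov])
  if (length(prune_idx) == 0L) return(TRUE)  # nothing to veto on
  p + n > 0L && p / (p + n) > 0.5
}

#' Learn an ordered threshold rule set with RIPPER
#'
#' Learns conjunctive rules for the minority class of a two-class decision
#' system over continuous attribute values restricted to `reduct`, then
#' appends a condition-free default rule predicting the majority class.
#' See the module header for the grow/prune/MDL schedule.
#'
#' @param s a `decision_system` from [build_decision_system()] (its
#'   `raw_values` are used; thresholds are midpoints of observed values).
#' @param reduct attribute (gene) names to consider; `NULL` for all.
#' @param params a [ripper_params()].
#' @return a [rule_set()]; each rule carries its training support (matching
#'   cells of the outcome class) and coverage (support / class size).
#' @export
ripper <- function(s, reduct = NULL, params = ripper_params()) {
  stopifnot(inherits(s, "decision_system"))
  y <- droplevels(s$labels)
  abort_if(nlevels(y) < 2L, "degenerate labels: need two classes")
  abort_if(nlevels(y) > 2L, "rule induction supports two classes only")
  if (is.null(reduct)) reduct <- s$features
  if (is.character(reduct)) {
    abort_if(!all(reduct %in% s$features), "reduct not a subset of attributes")
  }
  tab <- table(y)
  pos_class <- names(tab)[which.min(tab)]
  neg_class <- names(tab)[which.max(tab)]
  if (length(reduct) == 0L) {
    return(rule_set(list(), neg_class))
  }
  X <- s$raw_values[, reduct, drop = FALSE]
  pos <- y == pos_class
  n <- nrow(X)

  rules <- list()
  remaining <- seq_len(n)
  min_dl <- .ruleset_dl(list(), X, pos)
  rule_i <- 0L
  repeat {
    if (!any(pos[remaining])) break
    rule_i <- rule_i + 1L
    seed_r <- derive_seed(params$seed, 6L, rule_i)
    sp <- stratified_split(factor(ifelse(pos[remaining], "p", "n")),
                           params$grow_frac, seed_r)
    grow_idx <- remaining[sp$train]; prune_idx <- remaining[sp$test]
    conds <- .grow_rule(X, pos, grow_idx)
    conds <- .prune_rule(conds, X, pos, prune_idx)
    if (!.rule_admissible(conds, X, pos, prune_idx)) break
    cand <- c(rules, list(conds))
    dl <- .ruleset_dl(cand, X, pos)
    if (dl > min_dl + params$dl_budget) break
    min_dl <- min(min_dl, dl)
    rules <- cand
    remaining <- setdiff(remaining, .cover_conds(conds, X, seq_len(n)))
  }

  # global optimization: replacement / revision variants, MDL-best kept
  for (pass in seq_len(params$k_opt)) {
    for (ri in seq_along(rules)) {
      others <- rules[-ri]
      base <- seq_len(n)
      for (r in others) base <- setdiff(base, .cover_conds(r, X, seq_len(n)))
      if (!any(pos[base])) next
      seed_o <- derive_seed(params$seed, 7L, pass, ri)
      replacement <- .grow_prune_once(X, pos, base, seed_o)
      revision <- .grow_prune_once(X, pos, base, derive_seed(seed_o, 1L),
                                   start_conds = rules[[ri]])
      variants <- list(rules[[ri]], replacement, revision)
      variants <- variants[lengths(variants) > 0]
      if (length(variants) == 0L) next
      dls <- vapply(variants, function(v) {
        .ruleset_dl(c(rules[-ri], list(v)), X, pos)
      }, numeric(1))
      rules[[ri]] <- variants[[which.min(dls)]]
    }
  }

  # mop up positives left uncovered after optimization
  covered <- rep(FALSE, n)
  for (r in rules) covered[.cover_conds(r, X, seq_len(n))] <- TRUE
  remaining <- which(!covered)
  while (any(pos[remaining])) {
    rule_i <- rule_i + 1L
    seed_r <- derive_seed(params$seed, 6L, rule_i)
    sp <- stratified_split(factor(ifelse(pos[remaining], "p", "n")),
                           params$grow_frac, seed_r)
    conds <- .grow_rule(X, pos, remaining[sp$train])
    conds <- .prune_rule(conds, X, pos, remaining[sp$test])
    if (!.rule_admissible(conds, X, pos, remaining[sp$test])) break
    cand <- c(rules, list(conds))
    dl <- .ruleset_dl(cand, X, pos)
    if (dl > min_dl + params$dl_budget) break
    min_dl <- min(min_dl, dl)
    rules <- cand
    remaining <- setdiff(remaining, .cover_conds(conds, X, seq_len(n)))
  }

  # final global pruning: greedily delete any rule whose removal lowers the
  # ruleset description length (this is what discards rules that only fit
  # noise)
  repeat {
    if (length(rules) == 0L) break
    dl_now <- .ruleset_dl(rules, X, pos)
    dls <- vapply(seq_along(rules), function(ri) {
      .ruleset_dl(rules[-ri], X, pos)
    }, numeric(1))
    best <- which.min(dls)
    if (dls[best] < dl_now) rules <- rules[-best] else break
  }

  # drop rules without training support, then package with statistics
  keep <- vapply(rules, function(r) {
    cov <- .cover_conds(r, X, seq_len(n))
    sum(pos[cov]) >= 1L
  }, logical(1))
  rules <- rules[keep]
  class_size <- sum(pos)
  out_rules <- lapply(rules, function(r) {
    cov <- .cover_conds(r, X, seq_len(n))
    support <- sum(pos[cov])
    decision_rule(lapply(r, function(cc)
      list(gene = reduct[cc$attr], op = cc$op, threshold = cc$threshold)),
      pos_class, support = support, coverage = support / class_size)
  })
  rule_set(out_rules, neg_class)
}
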