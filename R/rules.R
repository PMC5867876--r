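# Ordered IF-THEN threshold rule sets: construction, application,
# statistics, JSON round trip, and the rule-interaction network export.

#' Construct a decision rule
#'
#' @param conditions list of `list(gene=, op=, threshold=)` with `op` one
#'   of `">="`/`"<="`; genes within one rule must be distinct. An empty
#'   list makes a condition-free (default) rule.
#' @param outcome predicted class.
#' @param support number of matching training cells of the outcome class
#'   (`NA` when unknown).
#' @param coverage support divided by the outcome-class size.
#' @return a `decision_rule` list.
#' @export
decision_rule <- function(conditions, outcome, support = NA_real_,
                          coverage = NA_real_) {
  genes <- vapply(conditions, function(cc) cc$gene, "")
  abort_if(anyDuplicated(genes) > 0, "conditions reference duplicate genes")
  for (cc in conditions) {
    abort_if(!cc$op %in% c(">=", "<="), "unsupported relation: ", cc$op)
    abort_if(!is.finite(cc$threshold), "non-finite threshold")
  }
  structure(list(conditions = conditions, outcome = outcome,
                 support = support, coverage = coverage),
            class = "decision_rule")
}

#' Construct an ordered rule set
#'
#' @param rules list of [decision_rule()]s, applied in order.
#' @param default_class class returned when no rule matches ("other
#'   conditions"); appended internally as a condition-free last rule.
#' @return a `rule_set` list.
#' @export
rule_set <- function(rules, default_class) {
  stopifnot(all(vapply(rules, inherits, logical(1), "decision_rule")))
  structure(list(rules = rules, default_class = default_class),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> ", length(x$rules), " rule(s) + default -> ",
      x$default_class, "\n", sep = "")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    conds <- paste(vapply(r$conditions, function(cc)
      sprintf("%s %s %g", cc$gene, cc$op, cc$threshold), ""),
      collapse = " AND ")
    stat <- if (!is.na(r$support))
      sprintf("  [support %g, coverage %.3f]", r$support, r$coverage) else ""
    cat(sprintf("  Rule %d: IF %s THEN %s%s\n", i, conds, r$outcome, stat))
  }
  cat("  Rule ", length(x$rules) + 1L, ": Other conditions -> ",
      x$default_class, "\n", sep = "")
  invisible(x)
}

rule_matches <- function(rule, values) {
  # values: named numeric vector or matrix with gene columns
  if (is.matrix(values)) {
    hit <- rep(TRUE, nrow(values))
    for (cc in rule$conditions) {
      abort_if(!cc$gene %in% colnames(values), "missing gene value: ", cc$gene)
      hit <- hit & (if (cc$op == ">=") values[, cc$gene] >= cc$threshold
                    else values[, cc$gene] <= cc$threshold)
    }
    hit
  } else {
    for (cc in rule$conditions) {
      abort_if(!cc$gene %in% names(values), "missing gene value: ", cc$gene)
      v <- values[[cc$gene]]
      ok <- if (cc$op == ">=") v >= cc$threshold else v <= cc$threshold
      if (!ok) return(FALSE)
    }
    TRUE
  }
}

#' Apply an ordered rule set to one cell
#'
#' Returns the outcome of the first rule (in rank order) whose conditions
#' all hold, or the default class when none match.
#'
#' @param r a [rule_set()].
#' @param cell named numeric vector of gene expression values; must cover
#'   every gene referenced by the rules.
#' @return predicted class (character).
#' @export
apply_rules <- function(r, cell) {
  stopifnot(inherits(r, "rule_set"))
  for (rule in r$rules) {
    if (rule_matches(rule, cell)) return(rule$outcome)
  }
  r$default_class
}

#' Predict classes for a matrix of cells
#'
#' @param object a [rule_set()].
#' @param newdata numeric matrix with gene columns (cells as rows).
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.rule_set <- function(object, newdata, ...) {
  out <- rep(object$default_class, nrow(newdata))
  undecided <- rep(TRUE, nrow(newdata))
  for (rule in object$rules) {
    hit <- undecided & rule_matches(rule, newdata)
    out[hit] <- rule$outcome
    undecided <- undecided & !hit
  }
  out
}

#' Rule-interaction network edges
#'
#' For every unordered gene pair co-occurring in a rule, emits an edge
#' weighted by the sum over such rules of support x coverage (rules with
#' unknown statistics contribute 1), normalized to \[0, 1\] by the maximum
#' edge.
#'
#' @param r a [rule_set()].
#' @return data.frame `gene1`, `gene2`, `weight` (possibly empty).
#' @export
rule_network_edges <- function(r) {
  stopifnot(inherits(r, "rule_set"))
  acc <- list()
  for (rule in r$rules) {
    genes <- sort(vapply(rule$conditions, function(cc) cc$gene, ""))
    if (length(genes) < 2L) next
    w <- if (is.na(rule$support) || is.na(rule$coverage)) 1
         else rule$support * rule$coverage
    pairs <- utils::combn(genes, 2L)
    for (k in seq_len(ncol(pairs))) {
      key <- paste(pairs[, k], collapse = "\r")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      weight = numeric(0)))
  }
  keys <- sort(names(acc))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  w <- unlist(acc[keys])
  data.frame(gene1 = vapply(parts, `[`, "", 1L),
             gene2 = vapply(parts, `[`, "", 2L),
             weight = w / max(w), row.names = NULL)
}

#' Write a rule set as JSON
#'
#' @param r a [rule_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(r, path) {
  payload <- list(
    rules = lapply(seq_along(r$rules), function(i) {
      rule <- r$rules[[i]]
      list(rank = i, conditions = rule$conditions, outcome = rule$outcome,
           support = rule$support, coverage = rule$coverage)
    }),
    default_class = r$default_class)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path path written by [write_rules()].
#' @return a [rule_set()].
#' @export
read_rules <- function(path) {
  payload <- jsonlite::read_json(path)
  rules <- lapply(payload$rules, function(rr) {
    decision_rule(lapply(rr$conditions, function(cc)
      list(gene = cc$gene, op = cc$op, threshold = as.numeric(cc$threshold))),
      rr$outcome,
      support = if (is.null(rr$support)) NA_real_ else as.numeric(rr$support),
      coverage = if (is.null(rr$coverage)) NA_real_ else as.numeric(rr$coverage))
  })
  rule_set(rules, payload$default_class)
}

#' Published PDX-vs-human reference rule set
#'
#' The seven-rule threshold classifier reported for distinguishing original
#' human breast-tumor cells from PDX cells on Biomark single-cell qPCR
#' expression: six conjunctive rules predicting "Human tumor" and a
#' condition-free default predicting "PDX tumor". Support and coverage were
#' not published and are `NA`.
#'
#' @return a [rule_set()].
#' @export
pdx_reference_rules <- function() {
  cond <- function(gene, op, threshold) list(gene = gene, op = op,
                                             threshold = threshold)
  rule_set(list(
    decision_rule(list(cond("KRT19", ">=", 1.939224),
                       cond("KRT5", "<=", 0.148786),
                       cond("CDH3", "<=", 0.868794)), "Human tumor"),
    decision_rule(list(cond("EMP1", ">=", 4.237572),
                       cond("CAV2", "<=", 1.610886)), "Human tumor"),
    decision_rule(list(cond("TP53", "<=", 0.291193),
                       cond("CXCR4", ">=", 4.367387),
                       cond("TGFBR2", "<=", 1.868461)), "Human tumor"),
    decision_rule(list(cond("CXCR4", "<=", -2.474571),
                       cond("CD44", ">=", 0.086944),
                       cond("PTEN", ">=", 0.143515),
                       cond("VIM", "<=", 0.647694)), "Human tumor"),
    decision_rule(list(cond("PARP2", ">=", 3.111536)), "Human tumor"),
    decision_rule(list(cond("PLCB4", ">=", 3.744729),
                       cond("AKT1", "<=", -0.070679)), "Human tumor")
  ), default_class = "PDX tumor")
}
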