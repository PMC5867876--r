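# The published reference rule set for human-vs-PDX breast tumor cells is
# the fixture here: six conjunctive human-tumor rules plus the
# condition-free PDX default.

ref_genes <- c("KRT19", "KRT5", "CDH3", "EMP1", "CAV2", "TP53", "CXCR4",
               "TGFBR2", "CD44", "PTEN", "VIM", "PARP2", "PLCB4", "AKT1")

neutral_cell <- function() {
  # satisfies no rule: every ">=" antecedent unmet, every "<=" antecedent
  # unmet where possible without re-triggering others
  stats::setNames(c(0, 1, 1, 0, 2, 1, 0, 2, 0, 0, 1, 0, 0, 1), ref_genes)
}

test_that("first-match rule application reproduces the reference decisions", {
  rs <- pdx_reference_rules()
  expect_length(rs$rules, 6L)

  # high PARP2 alone triggers the single-condition rule
  cell <- neutral_cell(); cell["PARP2"] <- 3.5
  expect_equal(apply_rules(rs, cell), "Human tumor")

  # nothing satisfied falls through to the default
  expect_equal(apply_rules(rs, neutral_cell()), "PDX tumor")

  # keratin/cadherin conjunction
  cell <- neutral_cell()
  cell["KRT19"] <- 2.0; cell["KRT5"] <- 0.1; cell["CDH3"] <- 0.5
  expect_equal(apply_rules(rs, cell), "Human tumor")

  # one violated conjunct blocks the rule
  cell["CDH3"] <- 1.5
  expect_equal(apply_rules(rs, cell), "PDX tumor")

  expect_error(apply_rules(rs, c(KRT19 = 5)), "missing gene")
})

test_that("each reference conjunction, satisfied in isolation, fires", {
  rs <- pdx_reference_rules()
  for (ri in seq_along(rs$rules)) {
    cell <- neutral_cell()
    for (cc in rs$rules[[ri]]$conditions) {
      cell[cc$gene] <- if (cc$op == ">=") cc$threshold + 0.1
                       else cc$threshold - 0.1
    }
    expect_equal(apply_rules(rs, cell), "Human tumor")
  }
})

test_that("matrix prediction agrees with cell-by-cell application", {
  rs <- pdx_reference_rules()
  set.seed(4)
  mat <- matrix(rnorm(50 * length(ref_genes), 1, 2), 50,
                dimnames = list(NULL, ref_genes))
  by_row <- vapply(seq_len(50), function(i) apply_rules(rs, mat[i, ]), "")
  expect_equal(predict(rs, mat), by_row)
})

test_that("rule network edges reflect co-occurrence and additivity", {
  edges <- rule_network_edges(pdx_reference_rules())
  key <- paste(edges$gene1, edges$gene2)
  expect_true(all(c("CDH3 KRT19", "CDH3 KRT5", "KRT19 KRT5") %in% key))
  expect_equal(max(edges$weight), 1)

  # single-condition rules only -> no edges
  solo <- rule_set(list(decision_rule(
    list(list(gene = "g1", op = ">=", threshold = 1)), "x")), "y")
  expect_equal(nrow(rule_network_edges(solo)), 0L)

  # shared pair sums contributions: (2*0.5 + 1*0.25) vs (1*0.25)
  two <- rule_set(list(
    decision_rule(list(list(gene = "g1", op = ">=", threshold = 1),
                       list(gene = "g2", op = "<=", threshold = 2)),
                  "x", support = 2, coverage = 0.5),
    decision_rule(list(list(gene = "g1", op = ">=", threshold = 3),
                       list(gene = "g2", op = "<=", threshold = 0),
                       list(gene = "g3", op = "<=", threshold = 0)),
                  "x", support = 1, coverage = 0.25)), "y")
  e2 <- rule_network_edges(two)
  w <- stats::setNames(e2$weight, paste(e2$gene1, e2$gene2))
  expect_equal(unname(w["g1 g2"]), 1)          # (1 + 0.25) is the max
  expect_equal(unname(w["g1 g3"]), 0.25 / 1.25)
})

test_that("rule sets survive a JSON round trip", {
  rs <- pdx_reference_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_rules(rs, path)
  back <- read_rules(path)
  expect_equal(length(back$rules), length(rs$rules))
  expect_equal(back$default_class, rs$default_class)
  for (i in seq_along(rs$rules)) {
    expect_equal(back$rules[[i]]$conditions, rs$rules[[i]]$conditions)
    expect_equal(back$rules[[i]]$outcome, rs$rules[[i]]$outcome)
  }
})

test_that("rule construction rejects malformed conditions", {
  expect_error(decision_rule(list(
    list(gene = "g1", op = ">=", threshold = 1),
    list(gene = "g1", op = "<=", threshold = 2)), "x"), "duplicate")
  expect_error(decision_rule(list(
    list(gene = "g1", op = ">", threshold = 1)), "x"), "relation")
  expect_error(decision_rule(list(
    list(gene = "g1", op = ">=", threshold = NA_real_)), "x"), "finite")
})
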