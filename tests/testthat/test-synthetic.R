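test_that("generator honors the spec dimensions and is seed-deterministic", {
  sim <- generate_matrix(synthetic_spec(seed = 5))
  expect_equal(dim(sim$matrix), c(831L, 69L))
  expect_equal(as.integer(table(sim$matrix$labels)[c("human", "pdx")]),
               c(174L, 657L))
  expect_length(sim$truth$informative_gene_ids, 15L)

  sim2 <- generate_matrix(synthetic_spec(seed = 5))
  expect_identical(sim$matrix$values, sim2$matrix$values)
  expect_identical(sim$matrix$missing_mask, sim2$matrix$missing_mask)

  sim3 <- generate_matrix(synthetic_spec(seed = 6))
  expect_false(identical(sim$matrix$values, sim3$matrix$values))
})

test_that("infeasible and inconsistent specs are rejected", {
  expect_error(synthetic_spec(n_genes = 10, informative_genes = 11),
               "infeasible")
  expect_error(synthetic_spec(class_counts = c(human = 10, pdx = 10)),
               "class_counts sum")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
})

test_that("informative genes carry the requested mean shift", {
  # large n so each gene's pooled mean difference has standard error well
  # inside the +/- 0.15 acceptance window around 1.5 * baseline_sd
  spec <- synthetic_spec(n_cells = 4000, n_genes = 40,
                         class_counts = c(human = 2000, pdx = 2000),
                         informative_genes = 10, effect_size = 1.5,
                         baseline_sd = 1.5, seed = 21)
  sim <- generate_matrix(spec)
  m <- sim$matrix
  human <- m$labels == "human"
  for (g in sim$truth$informative_gene_ids) {
    diff <- mean(m$values[human, g]) - mean(m$values[!human, g])
    expect_lt(abs(diff - 1.5 * 1.5), 0.15)
  }
  # background genes carry no shift
  bg <- setdiff(gene_ids(m), sim$truth$informative_gene_ids)[1:10]
  for (g in bg) {
    diff <- mean(m$values[human, g]) - mean(m$values[!human, g])
    expect_lt(abs(diff), 0.2)
  }
})

test_that("zero-effect data is null-calibrated and missingness matches rate", {
  spec <- synthetic_spec(n_cells = 400, n_genes = 200,
                         class_counts = c(human = 100, pdx = 300),
                         informative_genes = 0, missing_rate = 0.1,
                         seed = 31)
  sim <- generate_matrix(spec)
  m <- sim$matrix
  # fraction of |t| > t_crit at alpha = 0.05 should sit near 5%
  pvals <- apply(m$values, 2, function(x) {
    stats::t.test(x[m$labels == "human"], x[m$labels == "pdx"])$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
  # binomial band for the realized missing fraction
  se <- sqrt(0.1 * 0.9 / length(m$missing_mask))
  expect_lt(abs(mean(m$missing_mask) - 0.1), 3 * se)
})

test_that("cells satisfying a planted conjunction belong to the stated class", {
  rule <- list(conditions = list(list(gene = 2, op = ">=", threshold = 2.5),
                                 list(gene = 5, op = "<=", threshold = 0.0)),
               class = "human", frac = 0.8)
  spec <- synthetic_spec(n_cells = 1000, n_genes = 10,
                         class_counts = c(human = 300, pdx = 700),
                         informative_genes = 0, rule_genes = list(rule),
                         seed = 41)
  sim <- generate_matrix(spec)
  m <- sim$matrix
  sat <- m$values[, 2] >= 2.5 & m$values[, 5] <= 0.0
  expect_gt(sum(sat), 100)  # ~80% of the human class
  expect_gte(mean(m$labels[sat] == "human"), 0.95)
  expect_equal(sim$truth$planted_rules[[1]]$conditions[[1]]$gene, "gene_02")
})
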