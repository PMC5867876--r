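test_that("generalized decisions union labels over identical profiles", {
  vals <- rbind(c(0, 0), c(0, 0), c(1, 0))
  m <- make_matrix(vals, c("A", "B", "A"), genes = c("a1", "a2"))
  ds <- build_decision_system(m, c("a1", "a2"), discretize = "none")
  expect_equal(ds$gdec[[1]], c("A", "B"))
  expect_equal(ds$gdec[[2]], c("A", "B"))
  expect_equal(ds$gdec[[3]], "A")

  # all-distinct profiles give singleton decisions
  m2 <- make_matrix(diag(3), c("A", "B", "A"))
  ds2 <- build_decision_system(m2, gene_ids(m2), discretize = "none")
  expect_true(all(lengths(ds2$gdec) == 1L))
  expect_equal(unlist(ds2$gdec), c("A", "B", "A"))
})

test_that("generalized decision matches a brute-force grouping oracle", {
  for (seed in 1:20) {
    ds <- random_decision_system(8, 3, n_vals = 2L, seed = seed)
    for (i in seq_len(8)) {
      same <- vapply(seq_len(8), function(j) {
        all(ds$values[j, ] == ds$values[i, ])
      }, logical(1))
      expect_equal(ds$gdec[[i]], sort(unique(as.character(ds$labels[same]))))
      expect_true(as.character(ds$labels[i]) %in% ds$gdec[[i]])
    }
  }
})

test_that("discernibility entries follow the differing-decision rule", {
  # same label, different values: never discerned
  m <- make_matrix(rbind(c(0, 0), c(1, 1)), c("A", "A"))
  dm <- discernibility_matrix(
    build_decision_system(m, gene_ids(m), discretize = "none"),
    keep_pairs = TRUE)
  expect_length(discernibility_entry(dm, 1, 2), 0)
  expect_length(dm$g, 0)

  # single differing attribute
  m2 <- make_matrix(rbind(c(0, 0), c(1, 0)), c("A", "B"),
                    genes = c("a1", "a2"))
  dm2 <- discernibility_matrix(
    build_decision_system(m2, gene_ids(m2), discretize = "none"),
    keep_pairs = TRUE)
  expect_equal(discernibility_entry(dm2, 1, 2), "a1")
  expect_equal(discernibility_entry(dm2, 2, 1), "a1")  # symmetric
  expect_length(discernibility_entry(dm2, 1, 1), 0)
})

test_that("product-of-sums simplification applies idempotence and absorption", {
  # (a1|a3|a5) & (a1|a2) with added conjunct (a1|a2|a4): absorption drops
  # the superset
  s <- xenorules:::simplify_pos(list(c(1, 3, 5), c(1, 2), c(1, 2, 4)))
  expect_equal(s[order(lengths(s))], list(c(1, 2), c(1, 3, 5)))
  # duplicates collapse
  s2 <- xenorules:::simplify_pos(list(c(1, 2), c(1, 2), 3))
  expect_equal(s2[order(lengths(s2))], list(3, c(1, 2)))
})

test_that("Johnson reduct follows the greedy frequency rule with tie-breaks", {
  # brute force confirms {a2} is the unique minimal hitting set
  expect_equal(johnson_reduct(list(c(1, 2), c(2, 3), 2)), 2)
  expect_equal(johnson_reduct(list(1, 2)), c(1, 2))
  expect_equal(johnson_reduct(list(c(1, 2))), 1)  # frequency tie -> lowest
  expect_error(johnson_reduct(list(integer(0))), "empty conjunction")
})

test_that("Johnson reducts are valid and near-minimal on random systems", {
  for (seed in 1:60) {
    ds <- random_decision_system(sample(4:10, 1), sample(3:6, 1),
                                 n_vals = 2L, seed = seed)
    dm <- discernibility_matrix(ds, keep_pairs = FALSE)
    if (length(dm$g) == 0L) next
    reduct <- johnson_reduct(dm)
    expect_true(reduct_valid(ds, reduct))
    min_size <- brute_force_min_reduct_size(ds)
    bound <- min_size * (1 + log(length(dm$g)))
    expect_lte(length(reduct), bound)
  }
})

test_that("MDL discretization cuts separable genes and skips noise", {
  set.seed(3)
  y <- rep(c("A", "B"), each = 60)
  x <- c(rnorm(60, 0, 0.3), rnorm(60, 3, 0.3))
  cuts <- xenorules:::mdl_cuts(x, y)
  expect_gte(length(cuts), 1L)
  expect_true(any(cuts > 0.5 & cuts < 2.5))
  noise <- rnorm(120)
  expect_length(xenorules:::mdl_cuts(noise, y), 0L)
})
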