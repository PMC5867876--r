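test_that("load_matrix parses a delimited table preserving order", {
  path <- write_fixture_csv(c("g1,g2,class",
                              "1.5,2.5,human",
                              "3,4,pdx",
                              "5,6,pdx"))
  m <- load_matrix(path, "class")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(gene_ids(m), c("g1", "g2"))
  expect_equal(as.character(m$labels), c("human", "pdx", "pdx"))
  expect_equal(unname(m$values[, "g1"]), c(1.5, 3, 5))
  expect_false(any(m$missing_mask))
})

test_that("missing tokens set the mask; bad fields and headers error", {
  path <- write_fixture_csv(c("g1,g2,class", "1,NA,human", "2,3,pdx"))
  m <- load_matrix(path, "class")
  expect_true(m$missing_mask[1, "g2"])
  expect_true(is.na(m$values[1, "g2"]))
  expect_false(any(m$missing_mask[, "g1"]))

  dup <- write_fixture_csv(c("g1,g1,class", "1,2,human"))
  expect_error(load_matrix(dup, "class"), "duplicate column")

  bad <- write_fixture_csv(c("g1,g2,class", "1,x7,human"))
  expect_error(load_matrix(bad, "class"), "row 1, column 'g2'")

  path2 <- write_fixture_csv(c("g1,g2,class", "1,2,human"))
  expect_error(load_matrix(path2, "label"), "label column")
})

test_that("write_matrix/load_matrix round trip preserves values and order", {
  m <- make_matrix(matrix(c(1, 2, NA, 4, 5, 6), 2, byrow = TRUE),
                   c("human", "pdx"), genes = c("ga", "gb", "gc"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  m2 <- load_matrix(path, "class", id_column = "cell_id")
  expect_equal(m2$values, m$values)
  expect_equal(m2$missing_mask, m$missing_mask)
  expect_equal(as.character(m2$labels), as.character(m$labels))
})

test_that("filter_missing drops genes first, then cells, strictly above threshold", {
  # g3 missing in 3/4 cells (> 0.5) is dropped; then c4, missing both
  # retained genes (2/2 > 0.5), is dropped
  vals <- rbind(c(1, 2, NA), c(3, 4, NA), c(5, 6, 7), c(NA, NA, NA))
  m <- make_matrix(vals, c("human", "human", "pdx", "pdx"),
                   genes = c("g1", "g2", "g3"),
                   cells = paste0("c", 1:4))
  f <- filter_missing(m)
  expect_equal(gene_ids(f), c("g1", "g2"))
  expect_equal(cell_ids(f), c("c1", "c2", "c3"))
  expect_equal(attr(f, "removed"), list(genes = "g3", cells = "c4"))

  # exactly half missing is retained
  half <- make_matrix(rbind(c(1, NA), c(2, 3)), c("human", "pdx"),
                      genes = c("g1", "g2"))
  expect_equal(dim(filter_missing(half)), c(2L, 2L))
})

test_that("filter_missing is an idempotent identity on clean data", {
  m <- make_matrix(matrix(rnorm(12), 4), c("a", "a", "b", "b"))
  expect_identical(filter_missing(m)$values, m$values)

  set.seed(42)
  vals <- matrix(rnorm(60), 10)
  vals[sample(60, 20)] <- NA
  m2 <- make_matrix(vals, rep(c("a", "b"), 5))
  once <- filter_missing(m2)
  twice <- filter_missing(once)
  expect_identical(once$values, twice$values)
  expect_lte(ncol(once$values), ncol(m2$values))
  expect_lte(nrow(once$values), nrow(m2$values))
  # retained entries bit-identical
  expect_identical(once$values,
                   m2$values[cell_ids(once), gene_ids(once)])
})

test_that("impute_nn follows the shared-gene distance and tie-break rules", {
  # c3's only observed gene g1 is equidistant from c1 and c2; the tie
  # breaks to c1 (input order), so with k = 1 its g2 becomes 2
  vals <- rbind(c(1, 2), c(1, 4), c(9, NA))
  m <- make_matrix(vals, c("a", "a", "b"), genes = c("g1", "g2"))
  imp <- impute_nn(m, k = 1)
  expect_equal(imp$values[3, "g2"], 2)
  expect_false(any(imp$missing_mask))

  # with k covering all other cells the imputed value is the column mean
  imp2 <- impute_nn(m, k = 2)
  expect_equal(imp2$values[3, "g2"], 3)

  expect_error(impute_nn(m, k = 5), "exceeds")
})

test_that("impute_nn leaves observed values unchanged and stays in range", {
  set.seed(7)
  vals <- matrix(rnorm(200), 20)
  miss <- matrix(runif(200) < 0.15, 20)
  vals[miss] <- NA
  m <- make_matrix(vals, rep(c("a", "b"), 10))
  imp <- impute_nn(m, k = 3)
  expect_identical(imp$values[!miss], m$values[!miss])
  for (g in which(colSums(miss) > 0)) {
    obs <- m$values[!miss[, g], g]
    filled <- imp$values[miss[, g], g]
    expect_true(all(filled >= min(obs) & filled <= max(obs)))
  }
  # no missing data: identical output
  clean <- make_matrix(matrix(rnorm(20), 4), c("a", "a", "b", "b"))
  expect_identical(impute_nn(clean, k = 2)$values, clean$values)
})
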