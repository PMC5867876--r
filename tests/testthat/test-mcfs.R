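test_that("sample_projections draws uniform subsets deterministically", {
  # m = d forces the full feature set
  pr <- sample_projections(5, 5, 3, seed = 1)
  expect_true(all(vapply(pr, identical, logical(1), 1:5)))

  expect_identical(sample_projections(69, 5, 50, seed = 2),
                   sample_projections(69, 5, 50, seed = 2))
  expect_error(sample_projections(4, 5, 1), "exceeds")

  # per-feature inclusion counts stay within 4 binomial SDs of s*m/d
  pr <- sample_projections(69, 5, 1000, seed = 3)
  counts <- tabulate(unlist(pr), 69)
  expected <- 1000 * 5 / 69
  sd4 <- 4 * sqrt(1000 * (5 / 69) * (1 - 5 / 69))
  expect_true(all(abs(counts - expected) < sd4))
})

test_that("weighted accuracy is the mean of per-class recalls", {
  truth <- c(rep("A", 4), rep("B", 4))
  pred <- c(rep("A", 4), "B", "B", "A", "A")
  expect_equal(weighted_accuracy(pred, truth), 0.75)
  expect_equal(weighted_accuracy(truth, truth), 1)
  # majority-only prediction with 9:1 classes
  truth2 <- c(rep("A", 9), "B")
  expect_equal(weighted_accuracy(rep("A", 10), truth2), 0.5)
  expect_error(weighted_accuracy(character(0), character(0)), "empty")
})

test_that("information gain matches direct entropy evaluation", {
  expect_equal(information_gain(c("A", "A", "B", "B"),
                                c("A", "A"), c("B", "B")), 1)
  expect_equal(information_gain(c("A", "A", "B", "B"),
                                c("A", "B"), c("A", "B")), 0)
  expect_equal(information_gain(c("A", "A", "A", "B"),
                                c("A", "A"), c("A", "B")),
               0.8112781 - 0.5, tolerance = 1e-6)
  expect_error(information_gain(c("A", "B"), c("A"), c("A")), "partition")
})

test_that("a single known tree reproduces the relative-importance formula", {
  # train cells 1-8: gene_1 separates the classes perfectly (IG = 1 at the
  # root over all 8 training samples); test cells 9-12: one of two class-a
  # cells falls on the wrong side, so wAcc = (0.5 + 1)/2 = 0.75 and
  # RI(gene_1) = 0.75^1 * 1.0 * (8/8)^1 = 0.75
  vals <- cbind(gene_1 = c(0, 0, 0, 0, 1, 1, 1, 1, 0, 1, 1, 1),
                gene_2 = rep(0, 12))
  labels <- c(rep("a", 4), rep("b", 4), "a", "a", "b", "b")
  m <- make_matrix(vals, labels)
  p <- mcfs_params(d = 2, s = 1, t = 1, m = 2, u = 1, v = 1, seed = 1)
  fixed <- function(labels, seed) list(train = 1:8, test = 9:12)
  r <- rank_features(m, p, resample = fixed)
  expect_equal(r$ri[r$gene_id == "gene_1"], 0.75)
  expect_equal(r$ri[r$gene_id == "gene_2"], 0)

  # u = v = 0 reduces RI to the summed information gain of the splits
  p0 <- mcfs_params(d = 2, s = 1, t = 1, m = 2, u = 0, v = 0, seed = 1)
  r0 <- rank_features(m, p0, resample = fixed)
  expect_equal(r0$ri[r0$gene_id == "gene_1"], 1)
})

test_that("ranking is deterministic and column-order invariant at m = d", {
  sim <- generate_matrix(synthetic_spec(
    n_cells = 120, n_genes = 8, class_counts = c(human = 40, pdx = 80),
    informative_genes = 2, seed = 8))
  m <- sim$matrix
  p <- mcfs_params(d = 8, s = 10, t = 2, m = 8, seed = 4)
  r1 <- rank_features(m, p)
  r2 <- rank_features(m, p)
  expect_identical(r1, r2)

  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  mp <- expression_matrix(m$values[, perm], m$labels)
  rp <- rank_features(mp, p)
  ri1 <- stats::setNames(r1$ri, r1$gene_id)
  rip <- stats::setNames(rp$ri, rp$gene_id)
  expect_equal(rip[names(ri1)], ri1)
})

test_that("RI is non-negative, zero for constant features, signal-ranked", {
  sim <- generate_matrix(synthetic_spec(
    n_cells = 300, n_genes = 20, class_counts = c(human = 100, pdx = 200),
    informative_genes = 5, effect_size = 2, seed = 12))
  m <- sim$matrix
  vals <- m$values
  vals[, 20] <- 1  # constant gene
  m <- expression_matrix(vals, m$labels)
  p <- mcfs_params(d = 20, s = 60, t = 2, seed = 9)
  r <- rank_features(m, p)
  expect_true(all(r$ri >= 0))
  expect_equal(r$ri[r$gene_id == "gene_20"], 0)
  planted <- setdiff(sim$truth$informative_gene_ids, "gene_20")
  expect_gte(sum(planted %in% r$gene_id[1:10]), length(planted) - 1)
})

test_that("single-class input and unimputed matrices are rejected", {
  m <- make_matrix(matrix(rnorm(20), 5), rep("a", 5))
  expect_error(rank_features(m, mcfs_params(d = 4, s = 1, t = 1)),
               "degenerate")
  vals <- matrix(rnorm(20), 5)
  vals[1] <- NA
  m2 <- make_matrix(vals, c("a", "a", "b", "b", "b"))
  expect_error(rank_features(m2, mcfs_params(d = 4, s = 1, t = 1)),
               "imputed")
})

test_that("permutation cutoff flags few genes on null data", {
  sim <- generate_matrix(synthetic_spec(
    n_cells = 150, n_genes = 12, class_counts = c(human = 50, pdx = 100),
    informative_genes = 0, seed = 77))
  p <- mcfs_params(d = 12, s = 30, t = 2, seed = 5)
  cut <- ri_cutoff(sim$matrix, p, n_perm = 8, quantile_level = 0.95)
  expect_lte(length(cut$significant), ceiling(0.10 * 12))
  # quantile 0 with one permutation returns that permutation's max RI
  cut1 <- ri_cutoff(sim$matrix, p, n_perm = 1, quantile_level = 0)
  expect_equal(cut1$threshold, cut1$null_max[1])
})
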