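# Synthetic two-class expression matrices with planted signal: mean-shifted
# informative genes, optional threshold-rule structure, optional correlated
# gene blocks, completely-at-random missingness. The defaults mirror the
# study conditions the pipeline targets: 831 single cells (174 human tumor,
# 657 PDX) by 69 genes, 15 informative genes shifted by 1.5 within-class
# standard deviations.

#' Specification for a synthetic expression matrix
#'
#' @param n_cells total number of cells.
#' @param n_genes total number of genes.
#' @param class_counts named per-class cell counts; must sum to `n_cells`.
#'   The first name is the minority/"signal" class receiving the mean shift.
#' @param informative_genes number of genes with a class-dependent mean
#'   shift.
#' @param effect_size mean shift in units of `baseline_sd`.
#' @param rule_genes list of planted rules; each rule is a list with
#'   `conditions` (a list of `list(gene=, op=, threshold=)` with `op` one of
#'   `">="`/`"<="`), `class` (the implied class), and `frac` (fraction of
#'   that class generated to satisfy the conjunction).
#' @param baseline_mean,baseline_sd background Normal parameters.
#' @param missing_rate fraction of entries masked completely at random.
#' @param label_noise probability a cell's label is flipped (binary designs).
#' @param correlation_blocks list of integer gene-index vectors; genes in a
#'   block share a latent factor (pairwise correlation ~0.5) to mimic
#'   co-expressed families such as keratins.
#' @param clip optional length-2 numeric range to clamp values into.
#' @param seed integer seed; identical spec + seed reproduce bit-identically.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 831L, n_genes = 69L,
                           class_counts = c(human = 174L, pdx = 657L),
                           informative_genes = 15L, effect_size = 1.5,
                           rule_genes = list(),
                           baseline_mean = 1, baseline_sd = 1.5,
                           missing_rate = 0, label_noise = 0,
                           correlation_blocks = list(), clip = NULL,
                           seed = 1L) {
  abort_if(sum(class_counts) != n_cells,
           "class_counts sum (", sum(class_counts), ") != n_cells (", n_cells, ")")
  abort_if(is.null(names(class_counts)) || any(names(class_counts) == ""),
           "class_counts must be named")
  abort_if(missing_rate < 0 || missing_rate >= 1, "missing_rate must be in [0, 1)")
  n_rule_genes <- length(unique(unlist(lapply(rule_genes, function(r)
    vapply(r$conditions, function(cc) as.integer(cc$gene), 1L)))))
  abort_if(informative_genes + n_rule_genes > n_genes,
           "infeasible spec: more structured genes (", informative_genes + n_rule_genes,
           ") than n_genes (", n_genes, ")")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 class_counts = class_counts,
                 informative_genes = as.integer(informative_genes),
                 effect_size = effect_size, rule_genes = rule_genes,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 missing_rate = missing_rate, label_noise = label_noise,
                 correlation_blocks = correlation_blocks, clip = clip,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Truncated-normal draws by inverse-CDF so the generator stays a pure
# function of the seeded uniform stream.
.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Background entries are Normal(`baseline_mean`, `baseline_sd`);
#' informative genes gain `effect_size * baseline_sd` in the first-named
#' class; rule genes are sampled conditionally on the label so each planted
#' conjunction holds for `frac` of its class and is force-violated (one
#' condition pushed to the wrong side) everywhere else, making satisfying
#' cells almost surely members of the stated class.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (list
#'   with `informative_gene_ids`, `planted_rules`, `effect_sizes`).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_cells; p <- spec$n_genes
  classes <- names(spec$class_counts)
  labels <- factor(rep(classes, spec$class_counts), levels = classes)
  genes <- sprintf("gene_%02d", seq_len(p))
  cells <- sprintf("cell_%04d", seq_len(n))
  signal_class <- classes[1]

  rule_gene_idx <- unique(unlist(lapply(spec$rule_genes, function(r)
    vapply(r$conditions, function(cc) as.integer(cc$gene), 1L))))

  out <- with_seed(spec$seed, {
    vals <- matrix(rnorm(n * p, spec$baseline_mean, spec$baseline_sd), n, p,
                   dimnames = list(cells, genes))
    for (block in spec$correlation_blocks) {
      f <- rnorm(n, 0, spec$baseline_sd)
      for (g in block) {
        vals[, g] <- spec$baseline_mean +
          sqrt(0.5) * f + sqrt(0.5) * (vals[, g] - spec$baseline_mean)
      }
    }
    informative <- if (spec$informative_genes > 0) {
      sample(setdiff(seq_len(p), rule_gene_idx), spec$informative_genes)
    } else integer(0)
    eff <- numeric(p)
    eff[informative] <- spec$effect_size * spec$baseline_sd
    vals[labels == signal_class, informative] <-
      vals[labels == signal_class, informative, drop = FALSE] +
      spec$effect_size * spec$baseline_sd
    for (r in spec$rule_genes) {
      in_class <- which(labels == r$class)
      frac <- if (is.null(r$frac)) 1 else r$frac
      sat <- in_class[runif(length(in_class)) < frac]
      unsat <- setdiff(seq_len(n), sat)
      for (cc in r$conditions) {
        g <- as.integer(cc$gene)
        if (cc$op == ">=") {
          vals[sat, g] <- .rtrunc_norm(length(sat), spec$baseline_mean,
                                       spec$baseline_sd, lower = cc$threshold)
        } else {
          vals[sat, g] <- .rtrunc_norm(length(sat), spec$baseline_mean,
                                       spec$baseline_sd, upper = cc$threshold)
        }
      }
      # violate exactly one (uniformly chosen) condition per non-satisfying cell
      viol <- sample.int(length(r$conditions), length(unsat), replace = TRUE)
      for (ci in seq_along(r$conditions)) {
        cc <- r$conditions[[ci]]
        g <- as.integer(cc$gene)
        rows <- unsat[viol == ci]
        if (cc$op == ">=") {
          vals[rows, g] <- .rtrunc_norm(length(rows), spec$baseline_mean,
                                        spec$baseline_sd, upper = cc$threshold)
        } else {
          vals[rows, g] <- .rtrunc_norm(length(rows), spec$baseline_mean,
                                        spec$baseline_sd, lower = cc$threshold)
        }
      }
    }
    if (spec$label_noise > 0 && length(classes) == 2L) {
      flip <- runif(n) < spec$label_noise
      labels[flip] <- factor(classes[3L - as.integer(labels[flip])],
                             levels = classes)
    }
    if (!is.null(spec$clip)) {
      vals <- pmin(pmax(vals, spec$clip[1]), spec$clip[2])
    }
    mask <- matrix(runif(n * p) < spec$missing_rate, n, p,
                   dimnames = list(cells, genes))
    list(vals = vals, mask = mask, informative = sort(informative),
         eff = eff, labels = labels)
  })

  planted <- lapply(spec$rule_genes, function(r) {
    list(conditions = lapply(r$conditions, function(cc)
      list(gene = genes[as.integer(cc$gene)], op = cc$op,
           threshold = cc$threshold)),
      class = r$class, frac = if (is.null(r$frac)) 1 else r$frac)
  })
  truth <- list(informative_gene_ids = genes[out$informative],
                planted_rules = planted,
                effect_sizes = stats::setNames(out$eff, genes))
  list(matrix = expression_matrix(out$vals, out$labels, out$mask),
       truth = truth)
}

#' Write a ground-truth description as JSON
#'
#' @param truth the `truth` element of [generate_matrix()] output.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
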