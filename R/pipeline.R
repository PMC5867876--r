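# End-to-end orchestration: filter -> impute -> MCFS ranking -> IFS ->
# rough-set rule learning, with every artifact written under an output
# directory and a manifest recording the configuration, seeds and counts.

#' Pipeline configuration
#'
#' @param input path to a delimited expression table (see [load_matrix()]),
#'   or `NULL` to simulate from `synthetic`.
#' @param synthetic a [synthetic_spec()] used when `input` is `NULL`.
#' @param label_column,delimiter,id_column passed to [load_matrix()].
#' @param gene_frac,cell_frac missingness thresholds for [filter_missing()].
#' @param impute_k neighbor count for [impute_nn()].
#' @param mcfs named list of [mcfs_params()] overrides (e.g. `s`, `t`).
#' @param n_folds cross-validation folds for the IFS stage.
#' @param classifier a [classifier_spec()].
#' @param ripper a [ripper_params()].
#' @param out_dir output directory (created if absent).
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = synthetic_spec(),
                            label_column = "class", delimiter = ",",
                            id_column = NULL,
                            gene_frac = 0.5, cell_frac = 0.5, impute_k = 10L,
                            mcfs = list(), n_folds = 10L,
                            classifier = classifier_spec(),
                            ripper = ripper_params(),
                            out_dir = "pipeline_out", seed = 1L) {
  abort_if(gene_frac <= 0 || gene_frac > 1,
           "parameter error: gene_frac must be in (0, 1]")
  abort_if(cell_frac <= 0 || cell_frac > 1,
           "parameter error: cell_frac must be in (0, 1]")
  structure(list(input = input, synthetic = synthetic,
                 label_column = label_column, delimiter = delimiter,
                 id_column = id_column, gene_frac = gene_frac,
                 cell_frac = cell_frac, impute_k = as.integer(impute_k),
                 mcfs = mcfs, n_folds = as.integer(n_folds),
                 classifier = classifier, ripper = ripper,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           force = TRUE, digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stages: load or simulate, missingness filter, nearest-neighbor
#' imputation, MCFS ranking, IFS with cross-validated random forest, and
#' rough-set rule learning (MDL discretization, discernibility, Johnson
#' reduct, RIPPER) on the optimal feature set. Writes `ranking.tsv`,
#' `ifs_curve.tsv`, `optimal_features.txt`, `rules.json`,
#' `rule_edges.tsv`, `matrix.csv` (the analyzed matrix) and
#' `manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `matrix`, `ranking`, `ifs`, `reduct`, `rules`,
#'   `edges`, `paths`, `manifest` (invisibly returned components are also
#'   on disk).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()

  if (!is.null(cfg$input)) {
    say("load: ", cfg$input)
    m <- load_matrix(cfg$input, cfg$label_column, cfg$delimiter,
                     cfg$id_column)
  } else {
    say("simulate: ", cfg$synthetic$n_cells, " cells x ",
        cfg$synthetic$n_genes, " genes")
    sim <- generate_matrix(cfg$synthetic)
    m <- sim$matrix
    write_ground_truth(sim$truth, file.path(cfg$out_dir, "ground_truth.json"))
  }
  stage_counts$input <- dim(m)

  m <- filter_missing(m, cfg$gene_frac, cfg$cell_frac)
  removed <- attr(m, "removed")
  say("filter: removed ", length(removed$genes), " genes, ",
      length(removed$cells), " cells -> ", nrow(m$values), " x ",
      ncol(m$values))
  stage_counts$filtered <- dim(m)
  if (any(m$missing_mask)) {
    say("impute: k = ", cfg$impute_k)
    m <- impute_nn(m, cfg$impute_k)
  }
  write_matrix(m, file.path(cfg$out_dir, "matrix.csv"),
               label_column = cfg$label_column)

  mp <- do.call(mcfs_params,
                c(list(d = ncol(m$values)), cfg$mcfs,
                  if (is.null(cfg$mcfs$seed))
                    list(seed = derive_seed(cfg$seed, 11L))))
  say("rank: MCFS s = ", mp$s, ", t = ", mp$t, ", m = ", mp$m)
  ranking <- rank_features(m, mp)
  write_ranking(ranking, file.path(cfg$out_dir, "ranking.tsv"))

  clf <- cfg$classifier
  clf$seed <- derive_seed(cfg$seed, 12L)
  say("ifs: ", ncol(m$values), " candidate sets, ", cfg$n_folds,
      "-fold CV (", clf$name, ")")
  ifs <- run_ifs(m, ranking, clf, cfg$n_folds,
                 seed = derive_seed(cfg$seed, 13L))
  write_ifs_curve(ifs, file.path(cfg$out_dir, "ifs_curve.tsv"))
  writeLines(ifs$optimal_features,
             file.path(cfg$out_dir, "optimal_features.txt"))
  say("ifs: optimum i* = ", ifs$optimal_index, ", mean CV MCC = ",
      sprintf("%.4f", ifs$curve$mcc[ifs$optimal_index]))

  say("rules: discretize + discernibility + Johnson reduct + RIPPER")
  ds <- build_decision_system(m, ifs$optimal_features, discretize = "mdl")
  dm <- discernibility_matrix(ds, keep_pairs = FALSE)
  if (length(dm$g) > 0) {
    reduct <- johnson_reduct(dm)
  } else {
    # wholly inconsistent system (no pair with differing generalized
    # decisions): no attribute constraint survives, so rule induction
    # falls back to the full optimal feature set
    say("rules: discernibility function empty; using all optimal features")
    reduct <- ifs$optimal_features
  }
  rp <- cfg$ripper
  rp$seed <- derive_seed(cfg$seed, 14L)
  rules <- ripper(ds, reduct = reduct, params = rp)
  write_rules(rules, file.path(cfg$out_dir, "rules.json"))
  edges <- rule_network_edges(rules)
  utils::write.table(edges, file.path(cfg$out_dir, "rule_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("rules: ", length(rules$rules), " rule(s) for the minority class, ",
      nrow(edges), " network edge(s)")

  manifest <- list(
    config = unclass(cfg), config_hash = config_hash(cfg),
    stage_counts = stage_counts,
    n_rules = length(rules$rules), reduct = reduct,
    optimal_index = ifs$optimal_index,
    optimal_mcc = ifs$curve$mcc[ifs$optimal_index],
    package_version = as.character(utils::packageVersion("xenorules")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  paths <- file.path(cfg$out_dir,
                     c("matrix.csv", "ranking.tsv", "ifs_curve.tsv",
                       "optimal_features.txt", "rules.json",
                       "rule_edges.tsv", "manifest.json"))
  invisible(list(matrix = m, ranking = ranking, ifs = ifs, reduct = reduct,
                 rules = rules, edges = edges, paths = paths,
                 manifest = manifest))
}
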