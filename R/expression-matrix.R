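# Expression-matrix container and the data-preparation steps: missingness
# filters and nearest-neighbor-averaging imputation.

#' Construct an expression matrix
#'
#' The pipeline's universal input: a cells x genes matrix of continuous
#' (log-scale) expression values, one class label per cell, and a logical
#' mask marking entries that were not measured.
#'
#' @param values numeric cells x genes matrix; rownames are cell ids and
#'   colnames gene ids (generated as `cell_i` / `gene_j` when absent).
#' @param labels per-cell class labels (coerced to factor), e.g.
#'   `"human"` / `"pdx"`.
#' @param missing_mask logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return an object of class `expression_matrix` with elements `values`,
#'   `labels`, `missing_mask`.
#' @export
expression_matrix <- function(values, labels, missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("gene_", seq_len(ncol(values)))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  abort_if(!identical(dim(values), dim(missing_mask)),
           "values and missing_mask must have identical dimensions")
  abort_if(length(labels) != nrow(values),
           "labels length (", length(labels), ") != number of cells (", nrow(values), ")")
  abort_if(anyDuplicated(rownames(values)) > 0, "duplicate cell ids")
  abort_if(anyDuplicated(colnames(values)) > 0, "duplicate gene ids")
  values[missing_mask] <- NA_real_
  dimnames(missing_mask) <- dimnames(values)
  structure(
    list(values = values, labels = as.factor(labels), missing_mask = missing_mask),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes\n", sep = "")
  cat("  classes: ", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                           collapse = ", "), "\n", sep = "")
  cat("  missing: ", sum(x$missing_mask), " entries (",
      sprintf("%.2f%%", 100 * mean(x$missing_mask)), ")\n", sep = "")
  invisible(x)
}

#' Cell and gene identifiers of an expression matrix
#'
#' @param m an [expression_matrix()].
#' @return character vector of ids, in matrix order.
#' @export
cell_ids <- function(m) rownames(m$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$values)

#' Read an expression table from delimited text
#'
#' Expects cells as rows and genes as columns, a header row, and one label
#' column. Fields matching a missing token (case-insensitive) become missing
#' entries; anything else must parse as a number.
#'
#' @param path file path.
#' @param label_column name of the class-label column.
#' @param delimiter field separator (default `","`).
#' @param id_column optional name of a cell-id column; row numbers are used
#'   when absent.
#' @param missing_tokens strings treated as missing (default `""`, `"NA"`,
#'   `"NaN"`, case-insensitive).
#' @return an [expression_matrix()].
#' @export
load_matrix <- function(path, label_column, delimiter = ",", id_column = NULL,
                        missing_tokens = c("", "na", "nan")) {
  abort_if(!file.exists(path), "file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1]]
  header <- trimws(header)
  abort_if(!label_column %in% header,
           "configuration error: label column '", label_column, "' not in header")
  dup <- header[duplicated(header)]
  abort_if(length(dup) > 0, "format error: duplicate column name(s): ",
           paste(unique(dup), collapse = ", "))
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "")
  labels <- trimws(raw[[label_column]])
  keep <- setdiff(names(raw), c(label_column, id_column))
  ids <- if (!is.null(id_column)) {
    abort_if(!id_column %in% header, "configuration error: id column '",
             id_column, "' not in header")
    trimws(raw[[id_column]])
  } else {
    paste0("cell_", seq_len(nrow(raw)))
  }
  abort_if(anyDuplicated(ids) > 0, "format error: duplicate cell ids")
  tokens <- tolower(missing_tokens)
  vals <- matrix(NA_real_, nrow(raw), length(keep), dimnames = list(ids, keep))
  mask <- matrix(FALSE, nrow(raw), length(keep), dimnames = list(ids, keep))
  for (j in seq_along(keep)) {
    field <- trimws(raw[[keep[j]]])
    miss <- tolower(field) %in% tokens
    num <- suppressWarnings(as.numeric(field))
    bad <- which(!miss & is.na(num))
    abort_if(length(bad) > 0, "format error: unparseable numeric field '",
             field[bad[1]], "' at row ", bad[1], ", column '", keep[j], "'")
    num[miss] <- NA_real_
    vals[, j] <- num
    mask[, j] <- miss
  }
  expression_matrix(vals, labels, mask)
}

#' Write an expression matrix to delimited text
#'
#' Missing entries are written as `NA`; the label column is appended last so
#' a round trip through [load_matrix()] preserves gene order.
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @param delimiter field separator.
#' @param label_column name for the label column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = ",", label_column = "class") {
  out <- as.data.frame(m$values, check.names = FALSE)
  out[m$missing_mask] <- NA
  out <- cbind(cell_id = cell_ids(m), out)
  out[[label_column]] <- as.character(m$labels)
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Filter genes and cells by missingness
#'
#' First drops every gene missing in strictly more than `gene_frac` of
#' cells, then drops every cell missing in strictly more than `cell_frac`
#' of the retained genes. Entries missing in exactly the threshold fraction
#' are kept (the rule is "more than half", not "at least half"). The two
#' steps repeat until nothing more is removed, so the filter is a
#' projection (applying it twice equals applying it once); on typical
#' missingness one pass already reaches the fixed point.
#'
#' @param m an [expression_matrix()].
#' @param gene_frac,cell_frac missingness thresholds in (0, 1]; both default
#'   to 0.5.
#' @return the filtered [expression_matrix()]; the removal report is attached
#'   as attribute `"removed"` (list with `genes` and `cells` character
#'   vectors).
#' @export
filter_missing <- function(m, gene_frac = 0.5, cell_frac = 0.5) {
  stopifnot(inherits(m, "expression_matrix"))
  abort_if(gene_frac <= 0 || gene_frac > 1, "gene_frac must be in (0, 1]")
  abort_if(cell_frac <= 0 || cell_frac > 1, "cell_frac must be in (0, 1]")
  keep_g <- rep(TRUE, ncol(m$values))
  keep_c <- rep(TRUE, nrow(m$values))
  repeat {
    mask <- m$missing_mask[keep_c, keep_g, drop = FALSE]
    drop_g <- colMeans(mask) > gene_frac
    abort_if(all(drop_g), "degenerate result: all genes removed")
    keep_g[keep_g] <- !drop_g
    mask <- m$missing_mask[keep_c, keep_g, drop = FALSE]
    drop_c <- rowMeans(mask) > cell_frac
    abort_if(all(drop_c), "degenerate result: all cells removed")
    keep_c[keep_c] <- !drop_c
    if (!any(drop_g) && !any(drop_c)) break
  }
  out <- expression_matrix(m$values[keep_c, keep_g, drop = FALSE],
                           droplevels(m$labels[keep_c]),
                           m$missing_mask[keep_c, keep_g, drop = FALSE])
  attr(out, "removed") <- list(genes = gene_ids(m)[!keep_g],
                               cells = cell_ids(m)[!keep_c])
  out
}

# Pairwise cell distances under missingness: root-mean-square difference over
# the genes observed in both cells (scale-corrected for unequal support).
# Pairs sharing no observed gene get Inf.
.nn_distances <- function(values, observed) {
  V <- values
  V[!observed] <- 0
  O <- observed * 1
  V2 <- V * V
  shared <- O %*% t(O)
  ss <- V2 %*% t(O) + O %*% t(V2) - 2 * (V %*% t(V))
  ss[ss < 0] <- 0  # numerical noise
  d <- sqrt(ss / pmax(shared, 1))
  d[shared == 0] <- Inf
  diag(d) <- Inf
  d
}

#' Impute missing entries by nearest-neighbor averaging
#'
#' Each missing entry (cell i, gene g) becomes the mean of gene g over the k
#' cells nearest to i that observed g. Distance is the root-mean-square
#' difference over genes observed in both cells; neighbors lacking g are
#' skipped in favor of the next nearest; ties are broken by input row order.
#' If no cell observed g among candidates, the gene's overall observed mean
#' is used.
#'
#' @param m an [expression_matrix()].
#' @param k number of neighbors to average (default 10).
#' @return an [expression_matrix()] with an all-`FALSE` missing mask.
#' @export
impute_nn <- function(m, k = 10L) {
  stopifnot(inherits(m, "expression_matrix"))
  n <- nrow(m$values)
  abort_if(k < 1, "k must be >= 1")
  abort_if(k > n - 1L, "k (", k, ") exceeds number of other cells (", n - 1L, ")")
  if (!any(m$missing_mask)) return(m)
  observed <- !m$missing_mask
  abort_if(any(rowSums(observed) == 0), "a cell has no observed gene")
  abort_if(any(colSums(observed) == 0), "a gene is observed in no cell")
  vals <- m$values
  d <- .nn_distances(vals, observed)
  gene_means <- colSums(vals * observed) / colSums(observed)
  for (i in which(rowSums(m$missing_mask) > 0)) {
    ord <- order(d[i, ], seq_len(n))  # stable: ties by row order
    for (g in which(m$missing_mask[i, ])) {
      nb <- ord[observed[ord, g] & is.finite(d[i, ord])]
      if (length(nb) == 0L) {
        vals[i, g] <- gene_means[g]
      } else {
        vals[i, g] <- mean(m$values[nb[seq_len(min(k, length(nb)))], g])
      }
    }
  }
  expression_matrix(vals, m$labels, matrix(FALSE, n, ncol(vals),
                                           dimnames = dimnames(vals)))
}
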