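# Covariance-form multi-class Matthews correlation coefficient and
# companion confusion-matrix metrics.
#
# With one-hot truth Y and prediction X (n samples x N classes),
#   MCC = cov(X, Y) / sqrt(cov(X, X) * cov(Y, Y)),
#   cov(X, Y) = (1/N) * sum_k sum_i (x_ik - xbar_k)(y_ik - ybar_k).
# The 1/N prefactors cancel in the ratio. For N = 2 this equals the
# classical binary MCC (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

#' One-hot label indicator matrix
#'
#' @param labels label vector.
#' @param class_order character vector of classes defining column order;
#'   every label must appear in it.
#' @return n x N binary matrix with one 1 per row.
#' @export
indicator <- function(labels, class_order) {
  abort_if(length(labels) == 0L, "empty labels")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), class_order)
  abort_if(length(bad) > 0, "unknown label(s): ", paste(bad, collapse = ", "))
  out <- matrix(0L, length(labels), length(class_order),
                dimnames = list(NULL, class_order))
  out[cbind(seq_along(labels), match(labels, class_order))] <- 1L
  out
}

# Unnormalized centered cross-covariance sum; the 1/N factor cancels in MCC.
.cov_sum <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sum(Xc * Yc)
}

#' Matthews correlation coefficient from indicator matrices
#'
#' @param X predicted-class indicator matrix (see [indicator()]).
#' @param Y true-class indicator matrix of the same shape.
#' @return value in \[-1, 1\]; a constant prediction or constant truth
#'   makes the denominator zero, in which case 0 is returned with a
#'   warning (standard degenerate-denominator convention).
#' @export
mcc <- function(X, Y) {
  abort_if(!identical(dim(X), dim(Y)), "X and Y must have identical shape")
  sxx <- .cov_sum(X, X)
  syy <- .cov_sum(Y, Y)
  if (sxx == 0 || syy == 0) {
    warning("degenerate MCC denominator (constant prediction or truth); returning 0")
    return(0)
  }
  .cov_sum(X, Y) / sqrt(sxx * syy)
}

#' MCC from label vectors
#'
#' Convenience wrapper building the indicator matrices over the union of
#' classes (or a supplied order) and calling [mcc()].
#'
#' @param truth,predicted label vectors of equal length.
#' @param class_order optional class order; defaults to the sorted union.
#' @return MCC value.
#' @export
mcc_labels <- function(truth, predicted, class_order = NULL) {
  if (is.null(class_order)) {
    class_order <- sort(unique(c(as.character(truth), as.character(predicted))))
  }
  if (length(class_order) < 2L) class_order <- c(class_order, ".other")
  mcc(indicator(predicted, class_order), indicator(truth, class_order))
}

#' Confusion counts (truth by prediction)
#'
#' @param truth,predicted label vectors of equal length.
#' @param class_order class order for rows/columns; defaults to sorted
#'   union.
#' @return N x N integer matrix, rows = truth, columns = prediction.
#' @export
confusion_counts <- function(truth, predicted, class_order = NULL) {
  abort_if(length(truth) != length(predicted), "length mismatch")
  abort_if(length(truth) == 0L, "empty input")
  if (is.null(class_order)) {
    class_order <- sort(unique(c(as.character(truth), as.character(predicted))))
  }
  table(factor(truth, class_order), factor(predicted, class_order),
        dnn = c("truth", "predicted"))
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' Sensitivity is the recall of `positive_class`; specificity the recall of
#' its complement (pooled over the remaining classes); accuracy the trace
#' over the total.
#'
#' @param counts confusion matrix from [confusion_counts()].
#' @param positive_class class treated as positive.
#' @return named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
basic_metrics <- function(counts, positive_class) {
  counts <- as.matrix(counts)
  abort_if(sum(counts) == 0, "empty confusion matrix")
  abort_if(!positive_class %in% rownames(counts),
           "positive_class not in confusion matrix")
  pos <- rownames(counts) == positive_class
  tp <- sum(counts[pos, pos])
  fn <- sum(counts[pos, !pos])
  tn <- sum(counts[!pos, !pos])
  fp <- sum(counts[!pos, pos])
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = sum(diag(counts)) / sum(counts))
}
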