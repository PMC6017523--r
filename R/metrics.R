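#' Multi-class confusion matrix
#'
#' Entry `C[i, j]` counts samples of true class `i` predicted as class `j`.
#'
#' @param truth,pred Label vectors of equal, positive length.
#' @param classes Ordered class set; defaults to the sorted union of the
#'   labels observed in `truth` and `pred`.
#' @return A `G x G` integer matrix of class `seqrbm_confusion` with the
#'   class ordering as dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (length(truth) == 0) abort("empty label vectors")
  if (length(truth) != length(pred)) abort("`truth` and `pred` differ in length")
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth), as.character(pred))))
  if (!all(c(truth, pred) %in% classes)) {
    abort("labels outside the declared class set")
  }
  m <- table(
    factor(truth, levels = classes),
    factor(pred, levels = classes)
  )
  m <- matrix(as.integer(m), nrow = length(classes), dimnames = list(truth = classes, pred = classes))
  structure(m, class = c("seqrbm_confusion", "matrix", "array"))
}

check_confusion <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) abort("confusion matrix must be square")
  C
}

#' Classification accuracy from a confusion matrix
#'
#' @param C A square confusion matrix.
#' @return `trace(C) / sum(C)`.
#' @export
accuracy <- function(C) {
  C <- check_confusion(C)
  if (sum(C) == 0) abort("confusion matrix has zero total")
  sum(diag(C)) / sum(C)
}

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification rate
#' (off-diagonal row mass / row total): 0 for perfect classification, 1 when
#' every sample of every class is misclassified.
#'
#' @param C A square confusion matrix with positive row sums.
#' @return A value in `[0, 1]`.
#' @export
ber <- function(C) {
  C <- check_confusion(C)
  rs <- rowSums(C)
  if (any(rs == 0)) {
    abort(sprintf("class '%s' has no samples (zero row sum)", rownames(C)[which(rs == 0)[1]]))
  }
  # computed via the recall identity so ber(C) == 1 - mean(per_class_recall(C))
  # holds exactly in floating point
  1 - mean(diag(C) / rs)
}

#' Multi-class Matthews correlation coefficient
#'
#' The Gorodkin generalization of the MCC to G classes, computed from the
#' confusion matrix; values lie in `[-1, 1]`, with 1 for perfect
#' classification and 0 when all samples are assigned to a single class.
#' Degenerate denominators (either factor zero) return 0.
#'
#' @param C A square confusion matrix.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(C) {
  C <- check_confusion(C)
  s <- sum(C)
  if (s == 0) abort("confusion matrix has zero total")
  c0 <- sum(diag(C))
  tk <- rowSums(C) # true counts
  pk <- colSums(C) # predicted counts
  num <- c0 * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Per-class recall
#'
#' `C[i, i] / rowsum_i` for each class — the class-specific contribution to
#' overall classification. Satisfies `ber(C) == 1 - mean(per_class_recall(C))`.
#'
#' @param C A square confusion matrix with positive row sums.
#' @return A named numeric vector of length G.
#' @export
per_class_recall <- function(C) {
  C <- check_confusion(C)
  rs <- rowSums(C)
  if (any(rs == 0)) {
    abort(sprintf("class '%s' has no samples (zero row sum)", rownames(C)[which(rs == 0)[1]]))
  }
  stats::setNames(diag(C) / rs, rownames(C))
}
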