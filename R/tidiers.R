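#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line labs
#'   scale_y_continuous theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `seqrbm_cv` object.
#' @param ... Unused.
#' @return `tidy()`: one row per fold with accuracy, MCC and BER;
#'   `glance()`: a one-row summary with the fold means and settings.
#' @export
tidy.seqrbm_cv <- function(x, ...) x$fold_metrics

#' @rdname tidy.seqrbm_cv
#' @export
glance.seqrbm_cv <- function(x, ...) {
  tibble(
    accuracy = x$mean_accuracy, mcc = x$mean_mcc, ber = x$mean_ber,
    k = x$k, seed = x$seed, classifier = x$classifier,
    normalize_scope = x$normalize_scope
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `seqrbm_confusion` matrix.
#' @param ... Unused.
#' @return A tibble with columns `truth`, `pred`, `n`.
#' @export
tidy.seqrbm_confusion <- function(x, ...) {
  d <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(d) <- c("truth", "pred", "n")
  as_tibble(d)
}

#' @rdname tidy.seqrbm_cv
#' @export
tidy.seqrbm_ranking <- function(x, ...) x$table

#' @rdname tidy.seqrbm_cv
#' @export
tidy.seqrbm_grid <- function(x, ...) x$table[, c("architecture", "n_layers", "accuracy", "mcc", "ber")]

#' Per-class recall plot of a cross-validation result
#'
#' The class-specific contribution to overall classification, computed from
#' the pooled confusion matrix.
#'
#' @param object A `seqrbm_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seqrbm_cv <- function(object, ...) {
  d <- tibble(
    class = factor(names(object$per_class_recall), levels = names(object$per_class_recall)),
    recall = unname(object$per_class_recall)
  )
  ggplot(d, aes(x = .data$class, y = .data$recall)) +
    geom_col(fill = "steelblue") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      x = NULL, y = "per-class recall",
      title = sprintf("%s, %d-fold CV", object$classifier, object$k)
    ) +
    theme_minimal()
}

#' Accuracy plot of an index ranking
#'
#' @param object A `seqrbm_ranking` object.
#' @param top Number of top combinations to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seqrbm_ranking <- function(object, top = 12, ...) {
  d <- utils::head(object$table, top)
  d$combination <- factor(d$combination, levels = rev(d$combination))
  ggplot(d, aes(x = .data$accuracy, y = .data$combination)) +
    geom_point(colour = "steelblue", size = 2) +
    labs(
      x = "mean CV accuracy", y = NULL,
      title = sprintf("top index combinations (arity %d)", object$arity)
    ) +
    theme_minimal()
}

#' Reconstruction-error traces of a pretrained stack
#'
#' @param object A `seqrbm_stack` object from [pretrain_stack()].
#' @param ... Unused.
#' @return A ggplot of per-layer reconstruction error by epoch.
#' @export
autoplot.seqrbm_stack <- function(object, ...) {
  d <- purrr::imap(object$layers, function(l, i) {
    tibble(layer = paste0("layer ", i), epoch = seq_along(l$recon_error), error = l$recon_error)
  })
  d <- dplyr::bind_rows(d)
  ggplot(d, aes(x = .data$epoch, y = .data$error, colour = .data$layer)) +
    geom_line() +
    labs(x = "epoch", y = "mean reconstruction error") +
    theme_minimal()
}
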