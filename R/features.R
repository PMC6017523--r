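# Feature tables: one row per sequence, columns `.id`, `.label`, then numeric
# feature columns whose names record provenance (alignment position + index
# ordinal, or transform component).

new_feature_tbl <- function(values, ids, labels, tag) {
  stopifnot(is.matrix(values), nrow(values) == length(ids), length(ids) == length(labels))
  if (!all(is.finite(values))) abort("feature matrix contains non-finite values")
  out <- dplyr::bind_cols(
    tibble(.id = as.character(ids), .label = as.character(labels)),
    as_tibble(values, .name_repair = "minimal")
  )
  attr(out, "transform_tag") <- tag
  class(out) <- c("seqrbm_features", class(out))
  out
}

#' Extract the numeric matrix / labels / ids from a feature table
#'
#' @param x A feature table as returned by [encode_sequences()], [aacomp()]
#'   and friends: a tibble with `.id` and `.label` columns followed by
#'   numeric feature columns.
#' @return `feature_matrix()`: the numeric matrix (rows = sequences);
#'   `feature_labels()`: the label vector; `feature_names()`: the feature
#'   column names.
#' @export
feature_matrix <- function(x) {
  cols <- setdiff(names(x), c(".id", ".label"))
  m <- as.matrix(as_tibble(x)[, cols])
  rownames(m) <- x$.id
  m
}

#' @rdname feature_matrix
#' @export
feature_labels <- function(x) x$.label

#' @rdname feature_matrix
#' @export
feature_names <- function(x) setdiff(names(x), c(".id", ".label"))

#' @export
print.seqrbm_features <- function(x, ...) {
  cat(sprintf(
    "<seqrbm_features: %d x %d (%s)>\n",
    nrow(x), length(feature_names(x)),
    attr(x, "transform_tag") %||% "?"
  ))
  NextMethod()
}

#' Write / read a feature table as TSV
#'
#' The TSV layout is `id`, `label`, then one column per feature.
#'
#' @param x A feature table.
#' @param path File path.
#' @return `write_features()`: `path` invisibly; `read_features()`: the
#'   feature table.
#' @export
write_features <- function(x, path) {
  out <- as_tibble(x)
  names(out)[1:2] <- c("id", "label")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  new_feature_tbl(
    as.matrix(d[, -(1:2), drop = FALSE]),
    ids = d[[1]], labels = d[[2]], tag = "tsv"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
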