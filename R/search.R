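#' Grid search over stacked-RBM architectures
#'
#' Evaluates every architecture in the Cartesian product of the width grid
#' taken `n_layers` at a time (for each entry of `layer_counts`), by
#' stratified k-fold cross-validation, and returns the full table with the
#' best architecture. Scan order is layer counts ascending with later
#' layers' widths varying fastest; ties keep the first architecture
#' encountered.
#'
#' @param features A feature table.
#' @param layer_counts Integer vector of hidden-layer counts to try.
#' @param width_grid Integer vector of layer widths to try.
#' @param k,seed Cross-validation folds and master seed.
#' @param build_classifier Function mapping a width vector to a classifier
#'   specification; defaults to an RBM with those hidden layers built from
#'   `base_cfg`.
#' @param base_cfg A [deep_net_config()] supplying training hyperparameters
#'   for the default RBM builder.
#' @return A list of class `seqrbm_grid`: `table` (tibble of architecture,
#'   widths, mean accuracy/MCC/BER), `best` (row index of the winner), and
#'   the search settings.
#' @export
grid_search_architecture <- function(features, layer_counts = 1:2,
                                     width_grid = c(100, 200, 300, 500, 800),
                                     k = 10L, seed = 1L,
                                     build_classifier = NULL,
                                     base_cfg = deep_net_config()) {
  if (length(layer_counts) == 0 || length(width_grid) == 0) abort("empty search grid")
  if (is.null(build_classifier)) {
    build_classifier <- function(widths) {
      cfg <- base_cfg
      cfg$hidden_layers <- as.integer(widths)
      rbm_classifier(cfg)
    }
  }
  archs <- unlist(lapply(sort(layer_counts), function(nl) {
    g <- do.call(expand.grid, rev(replicate(nl, width_grid, simplify = FALSE)))
    lapply(seq_len(nrow(g)), function(i) as.integer(rev(unlist(g[i, ]))))
  }), recursive = FALSE)
  rows <- purrr::map(archs, function(widths) {
    cv <- cross_validate(features, build_classifier(widths), k = k, seed = seed)
    tibble(
      architecture = paste(widths, collapse = "-"),
      n_layers = length(widths),
      accuracy = cv$mean_accuracy, mcc = cv$mean_mcc, ber = cv$mean_ber
    )
  })
  table <- dplyr::bind_rows(rows)
  table$widths <- archs
  structure(
    list(
      table = table, best = which.max(table$accuracy),
      best_architecture = archs[[which.max(table$accuracy)]],
      k = k, seed = seed
    ),
    class = "seqrbm_grid"
  )
}

#' @export
print.seqrbm_grid <- function(x, ...) {
  cat(sprintf(
    "<seqrbm_grid: %d architectures, best %s (accuracy %.4f)>\n",
    nrow(x$table), x$table$architecture[x$best], x$table$accuracy[x$best]
  ))
  invisible(x)
}

rank_one <- function(seqs, indices, classifier, k, seed, combo_label) {
  feats <- encode_sequences(seqs, indices)
  cv <- cross_validate(feats, classifier, k = k, seed = seed)
  tibble(
    combination = combo_label,
    accuracy = cv$mean_accuracy, mcc = cv$mean_mcc, ber = cv$mean_ber
  )
}

new_ranking <- function(table, arity, k, seed) {
  table <- dplyr::arrange(table, dplyr::desc(.data$accuracy))
  structure(
    list(table = table, arity = arity, k = k, seed = seed),
    class = "seqrbm_ranking"
  )
}

#' Rank single property indices by cross-validated accuracy
#'
#' Runs the full encode -> normalize -> classify pipeline once per index in
#' the database and ranks indices by mean CV accuracy (MCC and BER
#' attached). Per-index work is seeded as `seed + ordinal`, so results are
#' identical however the loop is scheduled.
#'
#' @param seqs An aligned [seq_set()] tibble.
#' @param db A `seqrbm_aaindex` database (or subset).
#' @param classifier A classifier specification (default a stacked RBM).
#' @param k,seed CV folds and master seed.
#' @param top Number of top entries to return in `top_table` (the full
#'   table is always kept).
#' @return A list of class `seqrbm_ranking` with the sorted `table`
#'   (columns `combination`, `accuracy`, `mcc`, `ber`) and `top_table`.
#' @export
rank_property_indices <- function(seqs, db, classifier = rbm_classifier(),
                                  k = 10L, seed = 1L, top = 12L) {
  if (nrow(db) == 0) abort("empty AAindex database")
  rows <- purrr::map(seq_len(nrow(db)), function(i) {
    idx <- get_index(db, db$ordinal[i])
    rank_one(seqs, list(idx), classifier,
      k = k, seed = seed + db$ordinal[i],
      combo_label = as.character(db$ordinal[i])
    )
  })
  out <- new_ranking(dplyr::bind_rows(rows), arity = 1L, k = k, seed = seed)
  out$top_table <- utils::head(out$table, top)
  out
}

#' Search combinations of property indices
#'
#' Evaluates every unordered combination of the base ordinals at the given
#' arity with interleaved multi-index encoding, and ranks combinations by
#' mean CV accuracy.
#'
#' @param seqs An aligned [seq_set()] tibble.
#' @param db A `seqrbm_aaindex` database.
#' @param base Integer vector of candidate ordinals (e.g. the top-12 single
#'   indices).
#' @param arity Combination size (2 or 3).
#' @param classifier A classifier specification.
#' @param k,seed CV folds and master seed.
#' @return A `seqrbm_ranking`; combinations are labelled `"65-205"` style.
#' @export
search_index_combinations <- function(seqs, db, base, arity = 2L,
                                      classifier = rbm_classifier(),
                                      k = 10L, seed = 1L) {
  base <- unique(as.integer(base))
  arity <- as.integer(arity)
  if (arity > length(base)) abort("`arity` exceeds the number of base indices")
  combos <- utils::combn(base, arity, simplify = FALSE)
  rows <- purrr::imap(combos, function(cmb, i) {
    idxs <- lapply(cmb, function(o) get_index(db, o))
    rank_one(seqs, idxs, classifier,
      k = k, seed = seed + i,
      combo_label = paste(cmb, collapse = "-")
    )
  })
  new_ranking(dplyr::bind_rows(rows), arity = arity, k = k, seed = seed)
}

#' @export
print.seqrbm_ranking <- function(x, ...) {
  cat(sprintf("<seqrbm_ranking: arity %d, %d combinations>\n", x$arity, nrow(x$table)))
  print(utils::head(x$table, 12))
  invisible(x)
}
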