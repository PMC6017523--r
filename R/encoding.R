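#' Encode aligned sequences with one or more property indices
#'
#' Each alignment column is replaced by the numeric property value of its
#' residue under each supplied index: sequence `R1..RL` becomes
#' `I1(1)..I1(n), I2(1)..I2(n), ..., IL(1)..IL(n)` — with several indices the
#' values are interleaved position by position, giving a row of length
#' `L * n`. Gaps (and ambiguity codes) contribute 0 at every index slot.
#'
#' @param seqs An aligned [seq_set()] tibble.
#' @param indices A single [property_index()], a list of them, or a
#'   `seqrbm_aaindex` database subset (all its entries are used, in order).
#' @return A feature table (`N x (L*n)`), feature names `p<position>_x<ordinal>`.
#' @examples
#' s <- seq_set("s1", "mG", "AC-D", aligned = TRUE)
#' idx <- property_index(setNames(seq(-2, 2, length.out = 20), seqrbm:::AA_ORDER))
#' encode_sequences(s, idx)
#' @export
encode_sequences <- function(seqs, indices) {
  if (!is_aligned(seqs)) abort("encode_sequences() needs an aligned sequence set")
  indices <- as_index_list(indices)
  if (length(indices) == 0) abort("`indices` must contain at least one property index")
  L <- alignment_length(seqs)
  n <- length(indices)
  chars <- matrix(
    unlist(strsplit(seqs$residues, "", fixed = TRUE)),
    nrow = nrow(seqs), ncol = L, byrow = TRUE
  )
  ords <- vapply(indices, function(ix) attr(ix, "ordinal") %||% 0L, integer(1))
  tags <- ifelse(ords > 0, ords, seq_len(n))
  out <- matrix(0, nrow = nrow(seqs), ncol = L * n)
  for (k in seq_len(n)) {
    lk <- lookup_vector(indices[[k]])
    # columns k, n + k, 2n + k, ... : interleaved per position
    out[, seq(k, L * n, by = n)] <- matrix(lk[chars], nrow = nrow(seqs), ncol = L)
  }
  colnames(out) <- paste0(
    "p", rep(seq_len(L), each = n), "_x", rep(tags, times = L)
  )
  new_feature_tbl(out, seqs$id, seqs$label,
    tag = sprintf("encode[%s]", paste(tags, collapse = ","))
  )
}

as_index_list <- function(indices) {
  if (inherits(indices, "seqrbm_aaindex")) {
    return(lapply(indices$ordinal, function(o) get_index(indices, o)))
  }
  if (is.numeric(indices) && !is.null(names(indices))) return(list(property_index(indices)))
  if (inherits(indices, "seqrbm_index")) return(list(indices))
  if (is.list(indices)) {
    return(lapply(indices, function(ix) {
      if (inherits(ix, "seqrbm_index")) ix else property_index(ix)
    }))
  }
  abort("`indices` must be a property index, a list of them, or an AAindex database")
}

# Map any alphabet character to its index value; gaps and ambiguity codes -> 0.
lookup_vector <- function(index) {
  lk <- c(unclass(index)[AA_ORDER], stats::setNames(rep(0, 1 + length(AA_AMBIGUOUS)), c(AA_GAP, AA_AMBIGUOUS)))
  lk
}

#' Min-max normalize a feature table to [0, 1]
#'
#' Scales every feature column to `(x - min) / (max - min)`. When `stats`
#' (fitted on a training fold) are supplied they are applied as-is and
#' out-of-range values are clipped to `[0, 1]`; otherwise the statistics are
#' fitted on `x` itself and attached to the result. Constant features map
#' to 0.
#'
#' @param x A feature table.
#' @param stats Optional statistics from a previous fit, as returned by
#'   [minmax_stats()].
#' @return The normalized feature table, with the fitted statistics
#'   retrievable via [minmax_stats()].
#' @export
minmax_normalize <- function(x, stats = NULL) {
  m <- feature_matrix(x)
  if (is.null(stats)) {
    stats <- tibble(
      feature = colnames(m),
      min = apply(m, 2, min),
      max = apply(m, 2, max)
    )
  } else if (!identical(stats$feature, colnames(m))) {
    abort("`stats` do not match the feature columns of `x`")
  }
  rng <- stats$max - stats$min
  scaled <- sweep(m, 2, stats$min, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- new_feature_tbl(scaled, x$.id, x$.label,
    tag = paste0(attr(x, "transform_tag") %||% "?", "+minmax")
  )
  attr(out, "minmax_stats") <- stats
  out
}

#' @rdname minmax_normalize
#' @export
minmax_stats <- function(x) attr(x, "minmax_stats")
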