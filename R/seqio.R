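#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

#' Construct a labelled sequence set
#'
#' A sequence set is a tibble with one row per sequence and columns `id`,
#' `label` and `residues` (upper-case one-letter amino-acid codes, `-` for
#' alignment gaps, with `B`/`Z`/`X`/`U` accepted as ambiguity codes).
#' Alignment status is carried as attributes `aligned` and, when aligned,
#' `alignment_length`.
#'
#' @param id Character vector of record identifiers.
#' @param label Character vector of class labels (e.g. GPCR subfamily names).
#' @param residues Character vector of sequences.
#' @param aligned Logical; if `TRUE` all sequences must have equal length,
#'   which becomes the alignment length.
#' @return A tibble of class `seqrbm_seqs`.
#' @examples
#' seq_set(c("s1", "s2"), c("mG", "Cs"), c("ACD-", "AC-D"), aligned = TRUE)
#' @export
seq_set <- function(id, label, residues, aligned = FALSE) {
  if (length(id) == 0) abort("a sequence set needs at least one record")
  stopifnot(length(id) == length(label), length(id) == length(residues))
  residues <- toupper(gsub("*", "", residues, fixed = TRUE))
  bad <- !grepl(paste0("^[", paste(c(AA_ORDER, AA_AMBIGUOUS), collapse = ""), "-]+$"), residues)
  if (any(bad)) {
    abort(sprintf(
      "record '%s' contains characters outside the amino-acid alphabet",
      id[which(bad)[1]]
    ), class = "seqrbm_alphabet_error")
  }
  if (any(grepl(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"), residues))) {
    warn("ambiguity codes (B/Z/X/U) present; downstream encoders treat them as gaps")
  }
  out <- tibble(
    id = unname(as.character(id)),
    label = unname(as.character(label)),
    residues = unname(residues)
  )
  lens <- nchar(residues)
  if (aligned) {
    if (length(unique(lens)) != 1L) {
      abort("aligned = TRUE but sequence lengths differ", class = "seqrbm_alignment_error")
    }
    attr(out, "alignment_length") <- unname(lens[1])
  }
  attr(out, "aligned") <- aligned
  class(out) <- c("seqrbm_seqs", class(out))
  out
}

#' @export
print.seqrbm_seqs <- function(x, ...) {
  al <- if (is_aligned(x)) sprintf("aligned, L = %d", alignment_length(x)) else "unaligned"
  cat(sprintf("<seqrbm_seqs: %d records, %d classes, %s>\n", nrow(x), length(unique(x$label)), al))
  NextMethod()
}

#' @rdname seq_set
#' @param x A `seqrbm_seqs` tibble.
#' @export
is_aligned <- function(x) isTRUE(attr(x, "aligned"))

#' @rdname seq_set
#' @export
alignment_length <- function(x) attr(x, "alignment_length")

#' Read a labelled FASTA file
#'
#' Reads amino-acid sequences, extracting one class label per record from the
#' header. Wrapped and single-line FASTA bodies are both accepted and `*`
#' terminators are stripped.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; require equal lengths and record the alignment
#'   length.
#' @param label_rule Either a function mapping a header string to a label, or
#'   the name of a built-in rule. The default, `"last_pipe"`, takes the last
#'   `|`-delimited token of the header.
#' @return A [seq_set()] tibble.
#' @export
read_fasta <- function(path, aligned = FALSE, label_rule = "last_pipe") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  rule <- if (is.function(label_rule)) label_rule else switch(label_rule,
    last_pipe = function(h) {
      parts <- strsplit(h, "|", fixed = TRUE)[[1]]
      parts[length(parts)]
    },
    abort(sprintf("unknown label_rule '%s'", label_rule))
  )
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  labels <- vapply(headers, rule, character(1), USE.NAMES = FALSE)
  ids <- vapply(
    headers,
    function(h) strsplit(h, "|", fixed = TRUE)[[1]][1],
    character(1), USE.NAMES = FALSE
  )
  ids <- sub("\\s.*$", "", ids)
  seq_set(ids, labels, as.character(ss), aligned = aligned)
}

#' Write a sequence set to FASTA
#'
#' Headers are written as `id|label` so that [read_fasta()] with the default
#' label rule round-trips both sequences and labels.
#'
#' @param seqs A [seq_set()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs$residues)
  names(ss) <- paste(seqs$id, seqs$label, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Tabulate class sizes of a sequence set
#'
#' @param seqs A [seq_set()] tibble.
#' @return A tibble with columns `label` and `n`, in order of first appearance.
#' @export
class_counts <- function(seqs) {
  dplyr::count(as_tibble(seqs), .data$label, name = "n")
}

# Strip gaps and ambiguity codes; alignment-free transforms operate on the
# bare residue string.
degap <- function(residues) {
  gsub(paste0("[-", paste(AA_AMBIGUOUS, collapse = ""), "]"), "", residues)
}
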