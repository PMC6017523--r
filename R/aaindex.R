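#' Construct an ad-hoc amino-acid property index
#'
#' A property index maps each of the 20 standard residues to a real number.
#' Indices taken from the AAindex database carry their accession and ordinal
#' (position in the preprocessed database); ad-hoc scales use ordinal 0.
#'
#' @param values Numeric vector of 20 finite values named by one-letter
#'   residue codes (any order; stored in canonical AAindex order
#'   A R N D C Q E G H I L K M F P S T W Y V).
#' @param accession Accession string (free text for ad-hoc scales).
#' @param description Free-text description.
#' @param ordinal Integer position in the preprocessed database, or 0.
#' @return A named numeric vector of class `seqrbm_index` with attributes
#'   `accession`, `description` and `ordinal`.
#' @export
property_index <- function(values, accession = "adhoc", description = "", ordinal = 0L) {
  if (is.null(names(values)) || !setequal(names(values), AA_ORDER)) {
    abort("`values` must be named by the 20 standard one-letter residue codes")
  }
  values <- values[AA_ORDER]
  if (length(values) != 20L || !all(is.finite(values))) {
    abort("a property index needs exactly 20 finite values")
  }
  structure(values,
    accession = accession, description = description,
    ordinal = as.integer(ordinal), class = "seqrbm_index"
  )
}

new_aaindex_db <- function(accession, description, values) {
  out <- tibble(
    ordinal = seq_along(accession),
    accession = accession,
    description = description,
    values = values
  )
  if (anyDuplicated(out$accession)) abort("duplicate accessions in AAindex database")
  class(out) <- c("seqrbm_aaindex", class(out))
  out
}

#' Load the AAindex1 database bundled with seqinr
#'
#' Builds the full AAindex1 table (version 9, 544 indices) from the parsed
#' copy that ships with the seqinr package. With `preprocess = TRUE`, entries
#' containing any missing residue value are dropped and the remainder are
#' renumbered 1..531 in original database order — the preprocessed form used
#' for index-by-ordinal experiments.
#'
#' @param preprocess Drop entries with missing values and renumber.
#' @return A tibble of class `seqrbm_aaindex` with columns `ordinal`,
#'   `accession`, `description` and a list-column `values` of named
#'   20-residue numeric vectors.
#' @export
aaindex_db <- function(preprocess = TRUE) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  entries <- env$aaindex
  vals <- lapply(entries, function(e) {
    v <- as.numeric(e$I)
    names(v) <- AA_ORDER
    v
  })
  db <- new_aaindex_db(
    accession = vapply(entries, function(e) e$H, character(1), USE.NAMES = FALSE),
    description = vapply(entries, function(e) e$D, character(1), USE.NAMES = FALSE),
    values = unname(vals)
  )
  if (preprocess) db <- preprocess_aaindex(db)
  db
}

preprocess_aaindex <- function(db) {
  keep <- vapply(db$values, function(v) all(is.finite(v)), logical(1))
  out <- db[keep, , drop = FALSE]
  out$ordinal <- seq_len(nrow(out))
  class(out) <- unique(c("seqrbm_aaindex", class(out)))
  out
}

#' Parse an AAindex1 flat-format file
#'
#' Reads the canonical AAindex1 text format: per-entry blocks of keyed lines
#' (`H` accession, `D` description, ..., `I` followed by two rows of ten
#' values in residue order A R N D C Q E G H I / L K M F P S T W Y V) closed
#' by `//`. Missing values are written `NA` in the database and kept as `NA`
#' unless `preprocess = TRUE`.
#'
#' @param path Path to an AAindex1 flat file.
#' @param preprocess Drop entries with missing values and renumber (see
#'   [aaindex_db()]).
#' @return A `seqrbm_aaindex` tibble.
#' @export
load_aaindex1 <- function(path, preprocess = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0) abort("not an AAindex1 flat file: no '//' block terminators")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  parse_block <- function(block) {
    keyed <- grepl("^[A-Z*] |^[A-Z*]$", block)
    key <- ifelse(keyed, substr(block, 1, 1), NA)
    # continuation lines inherit the preceding key
    for (i in seq_along(key)) if (is.na(key[i]) && i > 1) key[i] <- key[i - 1]
    text <- ifelse(keyed, substring(block, 3), block)
    h <- trimws(text[which(key == "H")[1]])
    if (is.na(h) || h == "") abort("malformed AAindex1 block: missing H (accession) line")
    d <- paste(trimws(text[key == "D"]), collapse = " ")
    i_lines <- which(key == "I")
    if (length(i_lines) == 0) {
      abort(sprintf("malformed AAindex1 block '%s': missing I (values) lines", h))
    }
    val_text <- paste(text[i_lines[-1]], collapse = " ")
    toks <- strsplit(trimws(val_text), "\\s+")[[1]]
    if (length(toks) != 20L) {
      abort(sprintf(
        "AAindex1 entry '%s': expected 20 values, found %d", h, length(toks)
      ), class = "seqrbm_format_error")
    }
    v <- suppressWarnings(as.numeric(toks))
    if (any(is.na(v) & toks != "NA")) {
      abort(sprintf("AAindex1 entry '%s': unparseable value", h))
    }
    names(v) <- AA_ORDER
    list(accession = h, description = d, values = v)
  }
  blocks <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  blocks <- Filter(function(b) any(nzchar(trimws(b))), blocks)
  parsed <- lapply(blocks, parse_block)
  db <- new_aaindex_db(
    accession = vapply(parsed, `[[`, character(1), "accession"),
    description = vapply(parsed, `[[`, character(1), "description"),
    values = lapply(parsed, `[[`, "values")
  )
  if (preprocess) db <- preprocess_aaindex(db)
  db
}

#' Write an AAindex database in AAindex1 flat format
#'
#' @param db A `seqrbm_aaindex` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex1 <- function(db, path) {
  fmt_row <- function(v) {
    paste0("  ", paste(ifelse(is.na(v), "NA", sprintf("%.9g", v)), collapse = "   "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    v <- db$values[[i]]
    writeLines(c(
      paste("H", db$accession[i]),
      paste("D", db$description[i]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      fmt_row(v[1:10]),
      fmt_row(v[11:20]),
      "//"
    ), con)
  }
  invisible(path)
}

#' Ordinal-to-accession manifest of an AAindex database
#'
#' Index experiments refer to indices by ordinal (position in the
#' preprocessed database); the manifest records which accession each ordinal
#' denotes so results remain interpretable against other preprocessings.
#'
#' @param db A `seqrbm_aaindex` tibble.
#' @param path Optional path; when given, the manifest is also written as JSON.
#' @return A tibble with columns `ordinal`, `accession`, `description`.
#' @export
aaindex_manifest <- function(db, path = NULL) {
  m <- as_tibble(db)[, c("ordinal", "accession", "description")]
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  m
}

#' Retrieve one property index from a database
#'
#' @param db A `seqrbm_aaindex` tibble.
#' @param which An ordinal (numeric) or accession (character).
#' @return A [property_index()] vector.
#' @export
get_index <- function(db, which) {
  i <- if (is.numeric(which)) match(as.integer(which), db$ordinal) else match(which, db$accession)
  if (is.na(i)) abort(sprintf("index '%s' not found in database", as.character(which)))
  property_index(db$values[[i]],
    accession = db$accession[i],
    description = db$description[i], ordinal = db$ordinal[i]
  )
}
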