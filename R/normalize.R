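# Lexical normalization: special-character filtering, stop-word removal and
# Porter stemming. All dictionary matching in the pipeline happens on the
# normalized (stemmed) token forms produced here.

#' Default stop-word list
#'
#' A small pinned English stop-word list used by every pipeline stage unless
#' the caller supplies a different one. Matching results are sensitive to the
#' stop-word list, so the default is fixed and versioned with the package; a
#' custom list can be loaded with [read_stop_words()].
#'
#' @return character vector of lowercase stop words.
#' @export
default_stop_words <- function() {
  c("the", "of", "in", "a", "an", "to", "and", "or", "with", "for", "on", "by")
}

#' Read a stop-word list from file
#'
#' One token per line, UTF-8; blank lines and lines starting with `#` are
#' ignored; tokens are lowercased.
#'
#' @param path path to the stop-word file.
#' @return character vector of stop words.
#' @export
read_stop_words <- function(path) {
  if (!file.exists(path)) stop("stop-word file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tolower(lines)
}

#' Filter special characters from a label
#'
#' Replaces every character outside `[a-zA-Z0-9]` (punctuation such as "%" or
#' "-", and any other symbol) by a single space and lowercases the result.
#' This closed character rule keeps differently punctuated labels from
#' different ontologies comparable.
#'
#' @param text character vector of labels.
#' @return character vector of the same length, lowercase, alphanumerics and
#'   spaces only.
#' @export
filter_characters <- function(text) {
  stopifnot(is.character(text))
  tolower(gsub("[^a-zA-Z0-9]", " ", text))
}

#' Tokenize a character-filtered label
#'
#' Splits on whitespace and drops stop words, preserving token order. Numerals
#' are kept as tokens (labels like "4th finger" need them).
#'
#' @param text a single character-filtered string (see [filter_characters()]).
#' @param stop_words character vector of stop words to drop.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, stop_words = default_stop_words()) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  tokens[!tokens %in% stop_words]
}

#' Normalize a label into tokens and stems
#'
#' Composition of [filter_characters()], [tokenize()] and [porter_stem()].
#' Returns a `normalized_text` record holding the original string, its
#' tokens and the per-token stems (equal lengths). With `stem = FALSE` the
#' stems are the raw tokens, which lets the pipeline run with stemming
#' switched off for ablation.
#'
#' @param text a single label string.
#' @param stop_words stop-word vector.
#' @param stem logical; apply the Porter stemmer (default `TRUE`).
#' @return object of class `normalized_text` with fields `original`, `tokens`,
#'   `stems`.
#' @examples
#' normalize_label("decreased depth")
#' @export
normalize_label <- function(text, stop_words = default_stop_words(),
                            stem = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- tokenize(filter_characters(text), stop_words)
  stems <- if (stem) porter_stem(tokens) else tokens
  structure(
    list(original = text, tokens = tokens, stems = stems),
    class = "normalized_text"
  )
}

#' @export
print.normalized_text <- function(x, ...) {
  cat("<normalized_text> \"", x$original, "\"\n", sep = "")
  cat("  tokens:", paste(x$tokens, collapse = " "), "\n")
  cat("  stems: ", paste(x$stems, collapse = " "), "\n")
  invisible(x)
}
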