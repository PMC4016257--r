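# Dictionary-based concept recognition. Lexicons map normalized (stemmed)
# phrases to concept ids; annotation scans every contiguous token subsequence
# of a normalized label; containment filtering removes annotations whose span
# lies strictly inside a longer one.

#' Build a dictionary lexicon from an ontology
#'
#' One entry per distinct normalized term. The entry key is the space-joined
#' stem sequence of the term; each key maps to the set of (concept id, origin)
#' pairs whose label or synonym normalizes to it. Obsolete concepts are
#' excluded; terms that normalize to nothing (stop words / punctuation only)
#' are skipped with a warning.
#'
#' @param x an [ontology()].
#' @param use_synonyms logical; also index synonyms (default `TRUE`).
#' @param stop_words stop-word vector, shared with the rest of the pipeline.
#' @param stem logical; stem the dictionary (default `TRUE`). Must match the
#'   setting used to normalize the labels being annotated.
#' @return object of class `eq_lexicon`: fields `namespace`, `entries`
#'   (named list; each element a data.frame with columns `id`, `origin`),
#'   `stem`.
#' @export
build_lexicon <- function(x, use_synonyms = TRUE,
                          stop_words = default_stop_words(), stem = TRUE) {
  stopifnot(inherits(x, "eq_ontology"))
  keys <- character(0)
  ids <- character(0)
  origins <- character(0)
  skipped <- character(0)
  for (k in x$concepts) {
    if (k$obsolete) next
    terms <- c(stats::setNames(k$label, "label"),
               if (use_synonyms && length(k$synonyms)) {
                 stats::setNames(k$synonyms, rep("synonym", length(k$synonyms)))
               })
    for (j in seq_along(terms)) {
      nt <- normalize_label(terms[[j]], stop_words, stem = stem)
      if (!length(nt$stems)) {
        skipped <- c(skipped, paste0(k$id, " '", terms[[j]], "'"))
        next
      }
      keys <- c(keys, paste(nt$stems, collapse = " "))
      ids <- c(ids, k$id)
      origins <- c(origins, names(terms)[j])
    }
  }
  if (length(skipped)) {
    warning("skipped term(s) normalizing to empty: ",
            paste(skipped, collapse = "; "))
  }
  entries <- list()
  if (length(keys)) {
    df <- unique(data.frame(key = keys, id = ids, origin = origins,
                            stringsAsFactors = FALSE))
    entries <- lapply(split(df[c("id", "origin")], df$key), function(d) {
      rownames(d) <- NULL
      d[order(d$id, d$origin), , drop = FALSE]
    })
  }
  structure(
    list(namespace = x$namespace, entries = entries, stem = stem),
    class = "eq_lexicon"
  )
}

#' @export
print.eq_lexicon <- function(x, ...) {
  cat("<eq_lexicon> namespace=", x$namespace,
      " entries=", length(x$entries),
      if (!x$stem) " (unstemmed)", "\n", sep = "")
  invisible(x)
}

.empty_annotations <- function() {
  data.frame(phenotype_id = character(0), start = integer(0),
             end = integer(0), concept_id = character(0),
             namespace = character(0), origin = character(0),
             stringsAsFactors = FALSE)
}

#' Recognize concept mentions in a normalized label
#'
#' Tests every contiguous stem subsequence of the label against every
#' lexicon; each hit yields one annotation per mapped concept id. Spans are
#' token-indexed, 0-based and half-open over the label's (stop-word-free)
#' token sequence. Annotations from different lexicons may overlap; use
#' [filter_contained()] to drop spans strictly contained in longer ones.
#'
#' @param label a `normalized_text` (see [normalize_label()]), produced with
#'   the same stop-word list and stemming setting as the lexicons.
#' @param lexicons a single `eq_lexicon` or a list of them.
#' @param phenotype_id CURIE recorded in the annotations' provenance column.
#' @return data.frame with columns `phenotype_id`, `start`, `end`,
#'   `concept_id`, `namespace`, `origin`.
#' @export
annotate <- function(label, lexicons, phenotype_id = NA_character_) {
  stopifnot(inherits(label, "normalized_text"))
  if (inherits(lexicons, "eq_lexicon")) lexicons <- list(lexicons)
  n <- length(label$stems)
  if (n == 0L || !length(lexicons)) return(.empty_annotations())
  out <- list()
  for (lex in lexicons) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        key <- paste(label$stems[i:j], collapse = " ")
        hit <- lex$entries[[key]]
        if (is.null(hit)) next
        out[[length(out) + 1L]] <- data.frame(
          phenotype_id = phenotype_id, start = i - 1L, end = j,
          concept_id = hit$id, namespace = lex$namespace,
          origin = hit$origin, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(.empty_annotations())
  ann <- do.call(rbind, out)
  ann <- unique(ann)
  ann <- ann[order(ann$start, ann$end, ann$namespace, ann$concept_id), ,
             drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Remove annotations entirely contained in longer ones
#'
#' An annotation is dropped iff another annotation's span contains it and is
#' strictly longer. Annotations with identical spans (including
#' cross-namespace duplicates) are all kept. The operation is idempotent, and
#' afterwards no remaining span is strictly contained in another.
#'
#' @param annotations annotation data.frame (see [annotate()]), all referring
#'   to the same label.
#' @return filtered annotation data.frame.
#' @export
filter_contained <- function(annotations) {
  n <- nrow(annotations)
  if (n <= 1L) return(annotations)
  len <- annotations$end - annotations$start
  keep <- vapply(seq_len(n), function(i) {
    !any(annotations$start <= annotations$start[i] &
           annotations$end[i] <= annotations$end &
           len > len[i])
  }, logical(1L))
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find cross-namespace duplicate annotations
#'
#' Identical spans annotated with concepts from different namespaces signal
#' the same term existing in several ontologies (non-orthogonal ontologies);
#' they are kept during decomposition but surfaced as duplication warnings in
#' the evaluation report.
#'
#' @param annotations annotation data.frame for one label.
#' @return data.frame with columns `phenotype_id`, `start`, `end`,
#'   `concept_ids` (pipe-joined) for each duplicated span.
#' @export
duplicated_spans <- function(annotations) {
  if (!nrow(annotations)) {
    return(data.frame(phenotype_id = character(0), start = integer(0),
                      end = integer(0), concept_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(annotations$start, annotations$end)
  dup <- vapply(split(seq_len(nrow(annotations)), key), function(idx) {
    length(unique(annotations$namespace[idx])) > 1L
  }, logical(1L))
  keys <- names(dup)[dup]
  rows <- lapply(keys, function(k) {
    idx <- which(key == k)
    data.frame(phenotype_id = annotations$phenotype_id[idx[1L]],
               start = annotations$start[idx[1L]],
               end = annotations$end[idx[1L]],
               concept_ids = paste(sort(unique(annotations$concept_id[idx])),
                                   collapse = "|"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(phenotype_id = character(0), start = integer(0),
                      end = integer(0), concept_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}
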