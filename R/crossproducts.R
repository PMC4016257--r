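# Quality cross products: a composite quality concept (the "whole") is
# decomposable into the quality concepts whose stemmed terms form a subset of
# the whole's stemmed words. At annotation time, groups of quality annotations
# that exactly cover a whole's stem set are replaced by one annotation for
# the whole.

.term_stem_sets <- function(k, stop_words, stem) {
  # list of (via, stems) for the concept's label and synonyms; empty
  # normalizations dropped; stems are de-duplicated sets
  terms <- c(stats::setNames(list(k$label), "label"),
             stats::setNames(as.list(k$synonyms),
                             rep("synonym", length(k$synonyms))))
  out <- list()
  for (j in seq_along(terms)) {
    nt <- normalize_label(terms[[j]], stop_words, stem = stem)
    if (!length(nt$stems)) next
    out[[length(out) + 1L]] <- list(via = names(terms)[j],
                                    stems = sort(unique(nt$stems)))
  }
  out
}

#' Derive quality cross products by stem-subset comparison
#'
#' For every ordered pair of quality concepts (A, B), B is recorded as a
#' component of A iff the stem set of at least one of B's terms (label or
#' synonym) is a non-empty subset of the stem set of at least one of A's
#' terms, and B differs from A. Wholes with no components are absent from the
#' result. Obsolete concepts are ignored on both sides.
#'
#' @param quality_ontology the quality [ontology()] (PATO-style).
#' @param stop_words stop-word vector shared with the rest of the pipeline.
#' @param stem logical; stem terms before comparison (default `TRUE`).
#' @return named list of class `eq_crossproducts`, keyed by whole id. Each
#'   element has fields `whole_id`, `component_ids` (sorted union over all
#'   terms), `via` (term kind of the first term with components, label
#'   preferred), `whole_stems` (that term's stem set) and `terms` (per-term
#'   breakdown used for annotation combination).
#' @export
derive_cross_products <- function(quality_ontology,
                                  stop_words = default_stop_words(),
                                  stem = TRUE) {
  stopifnot(inherits(quality_ontology, "eq_ontology"))
  live <- Filter(function(k) !k$obsolete, quality_ontology$concepts)
  term_sets <- lapply(live, .term_stem_sets, stop_words = stop_words,
                      stem = stem)
  ids <- names(term_sets)
  # inverted index stem -> concept ids having a term that contains the stem
  index <- new.env(parent = emptyenv())
  for (id in ids) {
    for (t in term_sets[[id]]) {
      for (s in t$stems) {
        index[[s]] <- unique(c(index[[s]], id))
      }
    }
  }
  out <- list()
  for (id in ids) {
    terms_out <- list()
    for (t in term_sets[[id]]) {
      # candidates: concepts sharing at least one stem with this term
      cand <- unique(unlist(lapply(t$stems, function(s) index[[s]])))
      cand <- setdiff(cand, id)
      comp <- cand[vapply(cand, function(b) {
        any(vapply(term_sets[[b]], function(tb) {
          all(tb$stems %in% t$stems)
        }, logical(1L)))
      }, logical(1L))]
      if (length(comp)) {
        terms_out[[length(terms_out) + 1L]] <-
          list(via = t$via, stems = t$stems, component_ids = sort(comp))
      }
    }
    if (length(terms_out)) {
      prefer <- order(vapply(terms_out, function(t) t$via != "label",
                             logical(1L)))
      terms_out <- terms_out[prefer]
      out[[id]] <- list(
        whole_id = id,
        component_ids = sort(unique(unlist(
          lapply(terms_out, function(t) t$component_ids)))),
        via = terms_out[[1L]]$via,
        whole_stems = terms_out[[1L]]$stems,
        terms = terms_out
      )
    }
  }
  structure(out, class = "eq_crossproducts",
            namespace = quality_ontology$namespace)
}

#' @export
print.eq_crossproducts <- function(x, ...) {
  cat("<eq_crossproducts> namespace=", attr(x, "namespace"),
      " wholes=", length(x), "\n", sep = "")
  invisible(x)
}

#' Export a cross-product table
#'
#' TSV with columns `whole_id`, `component_ids` (pipe-separated) and `via`.
#'
#' @param cross_products result of [derive_cross_products()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cross_products <- function(cross_products, path) {
  ids <- sort(names(cross_products))
  rows <- vapply(ids, function(id) {
    cp <- cross_products[[id]]
    paste(cp$whole_id, paste(cp$component_ids, collapse = "|"), cp$via,
          sep = "\t")
  }, character(1L))
  writeLines(c("whole_id\tcomponent_ids\tvia", unname(rows)), path,
             useBytes = TRUE)
  invisible(path)
}

.annotation_stems <- function(annotations, label) {
  lapply(seq_len(nrow(annotations)), function(i) {
    sort(unique(label$stems[(annotations$start[i] + 1L):annotations$end[i]]))
  })
}

#' Combine quality annotations into cross-product wholes
#'
#' Whenever a set of quality annotations exists whose stem sets are each
#' contained in, and whose union exactly equals, a whole's term stem set
#' (exact cover: no missing and no leftover stems), that set is replaced by a
#' single annotation for the whole spanning from the earliest start to the
#' latest end. Non-quality annotations are never touched. Wholes are
#' processed largest stem set first, so a component that is itself consumed
#' by a larger whole is not reused by a smaller one; wholes of equal size
#' that are both exactly covered are all emitted as alternative annotations.
#'
#' @param annotations containment-filtered annotation data.frame for one
#'   label.
#' @param cross_products result of [derive_cross_products()].
#' @param label the `normalized_text` the annotations refer to.
#' @return annotation data.frame with combined quality annotations.
#' @export
combine_annotations <- function(annotations, cross_products, label) {
  if (!length(cross_products) || !nrow(annotations)) return(annotations)
  quality_ns <- attr(cross_products, "namespace")
  is_q <- annotations$namespace == quality_ns
  if (!any(is_q)) return(annotations)
  q_idx <- which(is_q)
  q_stems <- .annotation_stems(annotations[q_idx, , drop = FALSE], label)

  # candidate (whole, term) pairs, largest stem set first, ties by whole id
  pairs <- list()
  for (id in names(cross_products)) {
    for (t in cross_products[[id]]$terms) {
      pairs[[length(pairs) + 1L]] <- list(whole_id = id, via = t$via,
                                          stems = t$stems)
    }
  }
  sizes <- vapply(pairs, function(p) length(p$stems), integer(1L))
  ord <- order(-sizes, vapply(pairs, function(p) p$whole_id, character(1L)))
  pairs <- pairs[ord]
  sizes <- sizes[ord]

  consumed <- logical(length(q_idx))
  fired_wholes <- character(0)
  new_rows <- list()
  for (tier in unique(sizes)) {
    tier_pairs <- pairs[sizes == tier]
    tier_consumed <- logical(length(q_idx))
    for (p in tier_pairs) {
      if (p$whole_id %in% fired_wholes) next
      avail <- which(!consumed)
      if (!length(avail)) break
      sub <- avail[vapply(avail, function(i) {
        all(q_stems[[i]] %in% p$stems)
      }, logical(1L))]
      # drop annotations that already are the whole over its full stem set
      sub <- sub[!(annotations$concept_id[q_idx[sub]] == p$whole_id &
                     vapply(sub, function(i) setequal(q_stems[[i]], p$stems),
                            logical(1L)))]
      if (!length(sub)) next
      if (!setequal(sort(unique(unlist(q_stems[sub]))), p$stems)) next
      rows <- q_idx[sub]
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        phenotype_id = annotations$phenotype_id[rows[1L]],
        start = min(annotations$start[rows]),
        end = max(annotations$end[rows]),
        concept_id = p$whole_id,
        namespace = quality_ns,
        origin = p$via,
        stringsAsFactors = FALSE
      )
      fired_wholes <- c(fired_wholes, p$whole_id)
      tier_consumed[sub] <- TRUE
    }
    consumed <- consumed | tier_consumed
  }
  if (!length(new_rows)) return(annotations)
  keep <- rep(TRUE, nrow(annotations))
  keep[q_idx[consumed]] <- FALSE
  out <- rbind(annotations[keep, , drop = FALSE], do.call(rbind, new_rows))
  out <- unique(out)
  out <- out[order(out$start, out$end, out$namespace, out$concept_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
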