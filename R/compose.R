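# Assemble candidate EQ statements from filtered, combined annotations and
# apply quality replacement rules (unconditional id rewrites and conditional
# label-pattern rewrites).

#' Construct an EQ statement
#'
#' The post-composed representation of one phenotype: a set of entity ids
#' (anatomy/process namespaces) and a set of quality ids, with provenance.
#'
#' @param phenotype_id CURIE of the decomposed phenotype concept.
#' @param entity_ids character vector of entity CURIEs.
#' @param quality_ids character vector of quality CURIEs.
#' @param provenance `"generated"` or `"gold"`.
#' @param source which term of the phenotype was decomposed: `"label"` or
#'   `"synonym"`.
#' @return object of class `eq_statement`.
#' @export
eq_statement <- function(phenotype_id, entity_ids, quality_ids,
                         provenance = "generated", source = "label") {
  structure(
    list(phenotype_id = phenotype_id,
         entity_ids = sort(unique(as.character(entity_ids))),
         quality_ids = sort(unique(as.character(quality_ids))),
         provenance = provenance, source = source),
    class = "eq_statement"
  )
}

#' @export
print.eq_statement <- function(x, ...) {
  cat("<eq_statement> ", x$phenotype_id, " (", x$provenance, "/", x$source,
      ")\n  E: ", paste(x$entity_ids, collapse = ", "),
      "\n  Q: ", paste(x$quality_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compose an EQ statement from annotations
#'
#' Splits the surviving annotations by role: concepts matched from the
#' quality lexicon become qualities, everything else (anatomy/process
#' lexicons) becomes entities. Returns `NULL` when no annotation at all was
#' found — the phenotype then counts as not transformed.
#'
#' @param phenotype the phenotype [concept()] being decomposed.
#' @param annotations filtered and combined annotation data.frame.
#' @param quality_ns the quality namespace (e.g. `"PATO"`).
#' @param source `"label"` or `"synonym"` (which term was annotated).
#' @return an [eq_statement()], or `NULL` if `annotations` is empty.
#' @export
compose_eq <- function(phenotype, annotations, quality_ns,
                       source = "label") {
  if (is.null(annotations) || !nrow(annotations)) return(NULL)
  is_q <- annotations$namespace == quality_ns
  eq_statement(phenotype$id,
               entity_ids = annotations$concept_id[!is_q],
               quality_ids = annotations$concept_id[is_q],
               provenance = "generated", source = source)
}

#' Create a replacement rule
#'
#' Unconditional rules rewrite a quality id wherever it occurs in a generated
#' statement (e.g. "absent" is conventionally curated as "lacks all parts of
#' type"). Conditional rules rewrite a quality id only when a token pattern
#' matches the phenotype label; patterns are token sequences with at most one
#' `*` gap wildcard standing for one or more tokens, and are compared on
#' stems. A conditional rule may ship with `replacement = NA` (trigger-only):
#' it documents a known rewrite pattern whose target id must be supplied by
#' the user before the rule has any effect.
#'
#' @param kind `"unconditional"` or `"conditional"`.
#' @param trigger quality CURIE the rule removes.
#' @param replacement quality CURIE the rule inserts (or `NA` for
#'   trigger-only conditional rules).
#' @param pattern for conditional rules, the token pattern as one string,
#'   e.g. `"increased * number"`.
#' @return object of class `eq_rule`.
#' @export
replacement_rule <- function(kind, trigger, replacement, pattern = NULL) {
  kind <- match.arg(kind, c("unconditional", "conditional"))
  if (!is_curie(trigger)) stop("rule trigger is not a CURIE: ", trigger)
  if (!is.na(replacement)) {
    if (!is_curie(replacement)) {
      stop("rule replacement is not a CURIE: ", replacement)
    }
    if (identical(replacement, trigger)) {
      stop("rule replacement must differ from its trigger: ", trigger)
    }
  }
  pat_tokens <- NULL
  if (kind == "conditional") {
    if (is.null(pattern) || !nzchar(pattern)) {
      stop("conditional rule needs a non-empty pattern")
    }
    pat_tokens <- strsplit(trimws(pattern), "[[:space:]]+")[[1L]]
    if (sum(pat_tokens == "*") > 1L) {
      stop("conditional pattern may contain at most one gap wildcard: ",
           pattern)
    }
    if (all(pat_tokens == "*")) {
      stop("conditional pattern needs at least one literal token: ", pattern)
    }
  } else if (is.na(replacement)) {
    stop("unconditional rule needs a replacement id")
  }
  structure(
    list(kind = kind, trigger = trigger, replacement = replacement,
         pattern = pattern, pattern_tokens = pat_tokens),
    class = "eq_rule"
  )
}

#' Load replacement rules from a YAML file
#'
#' The file holds a top-level `rules:` list; each entry has `kind`,
#' `trigger`, `replacement` (may be `null` for trigger-only conditional
#' rules) and, for conditional rules, `pattern`. Rules apply in file order.
#' When a quality ontology is supplied, every non-null replacement id in that
#' ontology's namespace must name a concept in it; an unknown id is an error
#' at load time (ids from other namespaces can never fire on the corpus and
#' are left unchecked).
#'
#' @param path path to the rule file.
#' @param quality_ontology optional [ontology()] used to validate replacement
#'   ids.
#' @return list of [replacement_rule()] records.
#' @export
load_replacement_rules <- function(path, quality_ontology = NULL) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$rules
  if (is.null(entries)) entries <- list()
  rules <- lapply(entries, function(e) {
    replacement_rule(kind = e$kind, trigger = e$trigger,
                     replacement = if (is.null(e$replacement)) {
                       NA_character_
                     } else e$replacement,
                     pattern = e$pattern)
  })
  if (!is.null(quality_ontology)) {
    # only ids in the quality ontology's namespace are checkable; rules for
    # other namespaces stay loaded but can never fire on this corpus
    for (r in rules) {
      if (!is.na(r$replacement) &&
          curie_prefix(r$replacement) == quality_ontology$namespace &&
          is.null(quality_ontology$concepts[[r$replacement]])) {
        stop("rule replacement id not in quality ontology: ", r$replacement)
      }
    }
  }
  rules
}

#' Bundled replacement rules
#'
#' `default_rules()` returns the unconditional convention rewrite (absent,
#' PATO:0000462, becomes lacks all parts of type, PATO:0002000).
#' `conditional_rules()` additionally returns the label-conditional rewrites
#' for "increased activity" (quality becomes increased rate, PATO:0000912)
#' and "increased ... number" (quality becomes has extra parts of type,
#' PATO:0002001), plus the mirrored "decreased" trigger-only patterns whose
#' replacement ids must be supplied by the user.
#'
#' @param quality_ontology optional [ontology()] to validate replacement ids
#'   against.
#' @return list of [replacement_rule()] records.
#' @export
default_rules <- function(quality_ontology = NULL) {
  load_replacement_rules(
    system.file("extdata", "rules_unconditional.yml", package = "eqcompose"),
    quality_ontology
  )
}

#' @rdname default_rules
#' @export
conditional_rules <- function(quality_ontology = NULL) {
  c(default_rules(quality_ontology),
    load_replacement_rules(
      system.file("extdata", "rules_conditional.yml", package = "eqcompose"),
      quality_ontology
    ))
}

.pattern_matches <- function(pattern_tokens, stems) {
  pat <- porter_stem(pattern_tokens[pattern_tokens != "*"])
  star <- which(pattern_tokens == "*")
  n <- length(stems)
  if (!length(star)) {
    k <- length(pat)
    if (k > n) return(FALSE)
    for (i in seq_len(n - k + 1L)) {
      if (all(stems[i:(i + k - 1L)] == pat)) return(TRUE)
    }
    return(FALSE)
  }
  # one gap wildcard, standing for one or more tokens
  pre <- porter_stem(pattern_tokens[seq_len(star - 1L)])
  post <- porter_stem(pattern_tokens[-seq_len(star)])
  a <- length(pre)
  b <- length(post)
  if (a + b + 1L > n) return(FALSE)
  for (i in seq_len(n - a - b)) {           # start of pre (gap >= 1)
    if (a && !all(stems[i:(i + a - 1L)] == pre)) next
    for (j in (i + a + 1L):(n - b + 1L)) {  # start of post, gap >= 1
      if (!b || all(stems[j:(j + b - 1L)] == post)) return(TRUE)
    }
  }
  FALSE
}

#' Apply replacement rules to a generated statement
#'
#' Rules apply in list order. An unconditional rule replaces every occurrence
#' of its trigger quality. A conditional rule replaces its trigger quality
#' only when its token pattern matches the phenotype label's stem sequence;
#' trigger-only rules (replacement `NA`) are inert. Application is idempotent
#' for the bundled rule sets.
#'
#' @param eq an [eq_statement()] (returned unchanged if `NULL`).
#' @param label the phenotype's `normalized_text` (needed by conditional
#'   rules; may be `NULL` when only unconditional rules are used).
#' @param rules list of [replacement_rule()] records.
#' @return the rewritten [eq_statement()].
#' @export
apply_replacements <- function(eq, label = NULL, rules = list()) {
  if (is.null(eq) || !length(rules)) return(eq)
  qs <- eq$quality_ids
  for (r in rules) {
    if (is.na(r$replacement)) next
    if (r$kind == "conditional") {
      if (is.null(label)) next
      if (!.pattern_matches(r$pattern_tokens, label$stems)) next
    }
    qs[qs == r$trigger] <- r$replacement
  }
  eq_statement(eq$phenotype_id, eq$entity_ids, qs,
               provenance = eq$provenance, source = eq$source)
}

.decompose_one <- function(phenotype, term, source, lexicons, cross_products,
                           rules, quality_ns, stop_words, stem) {
  norm <- normalize_label(term, stop_words, stem = stem)
  if (!length(norm$tokens)) return(list(eq = NULL, dup = NULL))
  ann <- annotate(norm, lexicons, phenotype_id = phenotype$id)
  ann <- filter_contained(ann)
  dup <- duplicated_spans(ann)
  if (!is.null(cross_products)) {
    ann <- combine_annotations(ann, cross_products, norm)
  }
  eq <- compose_eq(phenotype, ann, quality_ns, source = source)
  eq <- apply_replacements(eq, norm, rules)
  list(eq = eq, dup = dup)
}

#' Decompose a phenotype ontology into EQ statements
#'
#' Runs the full pipeline per phenotype concept: normalize the label,
#' annotate against all lexicons, filter contained annotations, combine
#' quality annotations into cross-product wholes, compose the EQ statement
#' and apply replacement rules. With `use_synonyms = TRUE` every synonym of
#' the phenotype is decomposed as well and all synonym-derived candidate
#' statements are retained alongside the label-based one (the evaluation
#' tiers decide which candidate counts).
#'
#' @param phenotypes the phenotype [ontology()] (MP/HPO-style).
#' @param lexicons list of `eq_lexicon` objects (anatomy, process, quality).
#' @param cross_products optional result of [derive_cross_products()].
#' @param rules list of [replacement_rule()] records (default: none).
#' @param use_synonyms logical; decompose phenotype synonyms too.
#' @param quality_ns quality namespace; defaults to the cross-product map's
#'   namespace, else the single lexicon namespace that looks like a quality
#'   ontology must be given explicitly.
#' @param stop_words stop-word vector.
#' @param stem logical; stem labels and patterns (default `TRUE`). Must match
#'   the lexicons' setting.
#' @return object of class `eq_decomposition`: `statements` (named list of
#'   label-derived [eq_statement()], omitting untransformed phenotypes),
#'   `synonym_statements` (named list of candidate lists, or `NULL`),
#'   `duplication_warnings` (data.frame of cross-namespace identical spans)
#'   and `log` (per-stage counts).
#' @export
decompose_ontology <- function(phenotypes, lexicons, cross_products = NULL,
                               rules = list(), use_synonyms = FALSE,
                               quality_ns = NULL,
                               stop_words = default_stop_words(),
                               stem = TRUE) {
  stopifnot(inherits(phenotypes, "eq_ontology"))
  if (inherits(lexicons, "eq_lexicon")) lexicons <- list(lexicons)
  if (is.null(quality_ns)) {
    if (!is.null(cross_products)) {
      quality_ns <- attr(cross_products, "namespace")
    } else {
      stop("quality_ns must be given when no cross-product map is supplied")
    }
  }
  lex_ns <- vapply(lexicons, function(l) l$namespace, character(1L))
  if (anyDuplicated(lex_ns)) {
    message("lexicons share a namespace: ",
            paste(unique(lex_ns[duplicated(lex_ns)]), collapse = ", "))
  }
  statements <- list()
  synonym_statements <- if (use_synonyms) list() else NULL
  dups <- list()
  n_label_transformed <- 0L
  for (k in phenotypes$concepts) {
    if (k$obsolete) next
    res <- .decompose_one(k, k$label, "label", lexicons, cross_products,
                          rules, quality_ns, stop_words, stem)
    if (!is.null(res$eq)) {
      statements[[k$id]] <- res$eq
      n_label_transformed <- n_label_transformed + 1L
    }
    if (!is.null(res$dup) && nrow(res$dup)) {
      dups[[length(dups) + 1L]] <- res$dup
    }
    if (use_synonyms && length(k$synonyms)) {
      cands <- list()
      for (syn in k$synonyms) {
        sres <- .decompose_one(k, syn, "synonym", lexicons, cross_products,
                               rules, quality_ns, stop_words, stem)
        if (!is.null(sres$eq)) cands[[length(cands) + 1L]] <- sres$eq
        if (!is.null(sres$dup) && nrow(sres$dup)) {
          dups[[length(dups) + 1L]] <- sres$dup
        }
      }
      if (length(cands)) synonym_statements[[k$id]] <- cands
    }
  }
  dup_df <- if (length(dups)) {
    unique(do.call(rbind, dups))
  } else {
    data.frame(phenotype_id = character(0), start = integer(0),
               end = integer(0), concept_ids = character(0),
               stringsAsFactors = FALSE)
  }
  n_total <- sum(!vapply(phenotypes$concepts, function(k) k$obsolete,
                         logical(1L)))
  transformed_ids <- union(names(statements),
                           names(synonym_statements %||% list()))
  structure(
    list(statements = statements, synonym_statements = synonym_statements,
         duplication_warnings = dup_df,
         log = list(phenotypes = n_total,
                    transformed_label = n_label_transformed,
                    transformed_any = length(transformed_ids),
                    untransformed = n_total - length(transformed_ids))),
    class = "eq_decomposition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eq_decomposition <- function(x, ...) {
  cat("<eq_decomposition> phenotypes=", x$log$phenotypes,
      " transformed=", x$log$transformed_any,
      " (label-based ", x$log$transformed_label, ")",
      " untransformed=", x$log$untransformed, "\n", sep = "")
  invisible(x)
}
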