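# Grading generated EQ statements against gold statements. Three cumulative
# tiers: exact (label-based set equality), exact via a phenotype synonym, and
# relaxed (gold sets contained in the generated sets, i.e. extra assignments
# tolerated for curator removal); below those, partial (some shared concept)
# and disjoint (a statement was generated but shares nothing with gold).

.eval_categories <- c("exact", "exact_synonym", "relaxed", "partial",
                      "disjoint", "not_transformed")

#' Compare one generated statement with its gold statement
#'
#' `exact` mode requires set equality of entities and of qualities; `relaxed`
#' mode requires the gold entity and quality sets to be subsets of the
#' generated ones. When the requested mode fails, the category degrades to
#' `partial` (a shared entity or quality exists) or `disjoint` (no shared
#' concept at all).
#'
#' @param generated an [eq_statement()].
#' @param gold a [gold_eq()] for the same phenotype id.
#' @param mode `"exact"` or `"relaxed"`.
#' @return list of class `eq_match` with fields `phenotype_id`, `category`,
#'   `shared_entities`, `shared_qualities`.
#' @export
match_eq <- function(generated, gold, mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  if (!identical(generated$phenotype_id, gold$phenotype_id)) {
    stop("phenotype id mismatch: ", generated$phenotype_id, " vs ",
         gold$phenotype_id)
  }
  se <- intersect(generated$entity_ids, gold$entity_ids)
  sq <- intersect(generated$quality_ids, gold$quality_ids)
  hit <- if (mode == "exact") {
    setequal(generated$entity_ids, gold$entity_ids) &&
      setequal(generated$quality_ids, gold$quality_ids)
  } else {
    all(gold$entity_ids %in% generated$entity_ids) &&
      all(gold$quality_ids %in% generated$quality_ids)
  }
  category <- if (hit) {
    mode
  } else if (length(se) || length(sq)) {
    "partial"
  } else {
    "disjoint"
  }
  structure(
    list(phenotype_id = gold$phenotype_id, category = category,
         shared_entities = sort(se), shared_qualities = sort(sq)),
    class = "eq_match"
  )
}

.statement_sets <- function(stmts) {
  list(entities = sort(unique(unlist(lapply(stmts, `[[`, "entity_ids")))),
       qualities = sort(unique(unlist(lapply(stmts, `[[`, "quality_ids")))))
}

#' Evaluate a generated corpus against gold statements
#'
#' Classifies every gold phenotype into exactly one category:
#' `exact` when the label-based statement equals gold; otherwise
#' `exact_synonym` when any synonym-derived candidate equals gold; otherwise
#' `relaxed` when gold is contained in the label-based statement or in a
#' candidate; otherwise `partial` when any entity or quality is shared;
#' otherwise `disjoint`; phenotypes with no generated statement at all are
#' `not_transformed`. Percentages are reported over two denominators — all
#' selected phenotypes and transformed phenotypes only — because headline
#' rates differ substantially between the two.
#'
#' @param generated either an `eq_decomposition` (see [decompose_ontology()])
#'   or a named list of label-based [eq_statement()]s.
#' @param gold list of [gold_eq()] records (already restricted with
#'   [select_structure_process()] where appropriate).
#' @param synonyms_generated named list of synonym-candidate lists, or `NULL`
#'   (taken from `generated` when that is an `eq_decomposition`).
#' @return object of class `eq_evaluation`: `counts` (named vector over the
#'   six categories), `pct_of_selected`, `pct_of_transformed`, `results`
#'   (one data.frame row per phenotype), `duplication_warnings`.
#' @export
evaluate_corpus <- function(generated, gold, synonyms_generated = NULL) {
  dup <- NULL
  if (inherits(generated, "eq_decomposition")) {
    if (is.null(synonyms_generated)) {
      synonyms_generated <- generated$synonym_statements
    }
    dup <- generated$duplication_warnings
    generated <- generated$statements
  }
  rows <- lapply(gold, function(g) {
    pid <- g$phenotype_id
    lab <- generated[[pid]]
    syns <- synonyms_generated[[pid]]
    all_stmts <- c(if (!is.null(lab)) list(lab), syns)
    if (!length(all_stmts)) {
      return(list(phenotype_id = pid, category = "not_transformed",
                  shared_entities = character(0),
                  shared_qualities = character(0),
                  gen = list(entities = character(0),
                             qualities = character(0)), gold = g))
    }
    category <- NULL
    if (!is.null(lab) &&
        match_eq(lab, g, "exact")$category == "exact") {
      category <- "exact"
    } else if (any(vapply(syns %||% list(), function(s) {
      match_eq(s, g, "exact")$category == "exact"
    }, logical(1L)))) {
      category <- "exact_synonym"
    } else if (any(vapply(all_stmts, function(s) {
      match_eq(s, g, "relaxed")$category == "relaxed"
    }, logical(1L)))) {
      category <- "relaxed"
    }
    gen_sets <- .statement_sets(all_stmts)
    se <- intersect(gen_sets$entities, g$entity_ids)
    sq <- intersect(gen_sets$qualities, g$quality_ids)
    if (is.null(category)) {
      category <- if (length(se) || length(sq)) "partial" else "disjoint"
    }
    list(phenotype_id = pid, category = category,
         shared_entities = sort(se), shared_qualities = sort(sq),
         gen = gen_sets, gold = g)
  })
  results <- data.frame(
    phenotype_id = vapply(rows, `[[`, character(1L), "phenotype_id"),
    category = vapply(rows, `[[`, character(1L), "category"),
    generated_entities = vapply(rows, function(r) {
      paste(r$gen$entities, collapse = "|")
    }, character(1L)),
    generated_qualities = vapply(rows, function(r) {
      paste(r$gen$qualities, collapse = "|")
    }, character(1L)),
    gold_entities = vapply(rows, function(r) {
      paste(sort(r$gold$entity_ids), collapse = "|")
    }, character(1L)),
    gold_qualities = vapply(rows, function(r) {
      paste(sort(r$gold$quality_ids), collapse = "|")
    }, character(1L)),
    shared_entities = vapply(rows, function(r) {
      paste(r$shared_entities, collapse = "|")
    }, character(1L)),
    shared_qualities = vapply(rows, function(r) {
      paste(r$shared_qualities, collapse = "|")
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  counts <- vapply(.eval_categories, function(cat) {
    sum(results$category == cat)
  }, integer(1L))
  n_selected <- length(gold)
  n_transformed <- n_selected - counts[["not_transformed"]]
  pct <- function(x, d) {
    out <- if (d > 0) round(100 * x / d, 1) else rep(NA_real_, length(x))
    stats::setNames(out, names(x))
  }
  structure(
    list(counts = counts,
         n_selected = n_selected,
         n_transformed = n_transformed,
         pct_of_selected = pct(counts, n_selected),
         pct_of_transformed = pct(counts, n_transformed),
         results = results,
         duplication_warnings = dup),
    class = "eq_evaluation"
  )
}

#' @export
print.eq_evaluation <- function(x, ...) {
  cat("<eq_evaluation> ", x$n_selected, " selected phenotypes, ",
      x$n_transformed, " transformed\n", sep = "")
  for (cat_ in .eval_categories) {
    cat(sprintf("  %-16s %4d  (%5.1f%% of selected)\n", cat_,
                x$counts[[cat_]], x$pct_of_selected[[cat_]]))
  }
  cum <- cumsum(x$counts[c("exact", "exact_synonym", "relaxed")])
  cat("  cumulative exact / +synonym / +relaxed: ",
      paste(cum, collapse = " / "), "\n", sep = "")
  if (!is.null(x$duplication_warnings) && nrow(x$duplication_warnings)) {
    cat("  duplication warnings:", nrow(x$duplication_warnings),
        "cross-namespace identical span(s)\n")
  }
  invisible(x)
}

#' Sample disjoint mismatches for manual audit
#'
#' Uniformly samples `n` phenotypes from the disjoint category (generated
#' statement shares no concept with gold) for curator inspection; returns the
#' whole category when it holds fewer than `n`. Sampling is reproducible via
#' `seed` and does not disturb the caller's RNG state.
#'
#' @param report an `eq_evaluation` (see [evaluate_corpus()]).
#' @param n sample size (>= 0).
#' @param seed integer seed.
#' @return data.frame of sampled result rows.
#' @export
sample_mismatches <- function(report, n = 50L, seed = 1L) {
  stopifnot(inherits(report, "eq_evaluation"), n >= 0L)
  pool <- report$results[report$results$category == "disjoint", ,
                         drop = FALSE]
  if (nrow(pool) <= n) {
    rownames(pool) <- NULL
    return(pool)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  out <- pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the per-concept evaluation file
#'
#' TSV with one row per selected phenotype (category, generated, gold and
#' shared concept sets) preceded by a commented summary block with counts and
#' both percentage denominators.
#'
#' @param report an `eq_evaluation`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_evaluation <- function(report, path) {
  stopifnot(inherits(report, "eq_evaluation"))
  header <- c(
    sprintf("# selected_phenotypes\t%d", report$n_selected),
    sprintf("# transformed_phenotypes\t%d", report$n_transformed),
    vapply(.eval_categories, function(cat_) {
      sprintf("# %s\t%d\t%.1f%% of selected\t%s of transformed",
              cat_, report$counts[[cat_]],
              report$pct_of_selected[[cat_]],
              if (is.na(report$pct_of_transformed[[cat_]])) "NA" else {
                sprintf("%.1f%%", report$pct_of_transformed[[cat_]])
              })
    }, character(1L)),
    if (!is.null(report$duplication_warnings) &&
        nrow(report$duplication_warnings)) {
      vapply(seq_len(nrow(report$duplication_warnings)), function(i) {
        d <- report$duplication_warnings[i, ]
        sprintf("# duplicated_span\t%s\t[%d,%d)\t%s", d$phenotype_id,
                d$start, d$end, d$concept_ids)
      }, character(1L))
    }
  )
  rows_txt <- if (nrow(report$results)) {
    unname(apply(report$results, 1L, paste, collapse = "\t"))
  } else character(0)
  body <- c(paste(names(report$results), collapse = "\t"), rows_txt)
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
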