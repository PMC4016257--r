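# Deterministic synthetic fixture corpora. Generates toy anatomy, process,
# quality and phenotype ontologies plus a gold EQ file with planted match
# categories, so the whole pipeline is testable without downloading any real
# ontology. All ids use synthetic prefixes (MAX/GOX/PATX/MPX) to make clear
# that no real ontology content is shipped.

.noise_flags <- c("plural_suffix", "synonym_label_swap", "contraction",
                  "shared_synonym", "cross_namespace_duplicate")

#' Specify a synthetic fixture corpus
#'
#' Captures everything [generate_fixture()] needs: sizes of the four toy
#' ontologies, the number of composite quality concepts (wholes whose label
#' is the concatenation of two component labels, guaranteeing the stem-subset
#' property), the planted distribution of evaluation categories over the
#' phenotypes, and optional noise flags emulating real-data artefacts
#' (plural suffixes, label/synonym swaps, contracted anatomical terms, shared
#' synonyms, the same term existing in two ontologies).
#'
#' @param seed integer; the only source of randomness.
#' @param n_entities anatomy concepts (every 5th gets a multi-word label that
#'   lexically embeds a quality term; every 3rd gets a synonym).
#' @param n_processes process concepts (every 3rd gets a synonym).
#' @param n_qualities simple (single-word) quality concepts.
#' @param n_composite_qualities composite quality wholes; requires
#'   `2 * n_composite_qualities <= n_qualities`.
#' @param n_phenotypes phenotype concepts.
#' @param noise character vector of flags among `plural_suffix`,
#'   `synonym_label_swap`, `contraction`, `shared_synonym`,
#'   `cross_namespace_duplicate`.
#' @param planted_categories named integer vector over the categories
#'   `exact`, `exact_synonym`, `relaxed`, `partial`, `disjoint`,
#'   `not_transformed`, summing to `n_phenotypes`. Defaults to roughly
#'   40/15/15/12/8/10 percent in that order.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entities = 30L, n_processes = 10L,
                         n_qualities = 20L, n_composite_qualities = 5L,
                         n_phenotypes = 50L, noise = character(0),
                         planted_categories = NULL) {
  stopifnot(n_entities >= 0L, n_processes >= 0L, n_qualities >= 0L,
            n_composite_qualities >= 0L, n_phenotypes >= 0L)
  bad <- setdiff(noise, .noise_flags)
  if (length(bad)) stop("unknown noise flag(s): ", paste(bad, collapse = ", "))
  if (2L * n_composite_qualities > n_qualities) {
    stop("need at least two simple qualities per composite quality")
  }
  if (is.null(planted_categories)) {
    shares <- c(exact = 0.40, exact_synonym = 0.15, relaxed = 0.15,
                partial = 0.12, disjoint = 0.08, not_transformed = 0.10)
    planted_categories <- vapply(shares, function(s) {
      as.integer(floor(s * n_phenotypes))
    }, integer(1L))
    planted_categories[["exact"]] <- planted_categories[["exact"]] +
      n_phenotypes - sum(planted_categories)
  }
  cats <- c("exact", "exact_synonym", "relaxed", "partial", "disjoint",
            "not_transformed")
  full <- stats::setNames(integer(length(cats)), cats)
  full[names(planted_categories)] <- as.integer(planted_categories)
  if (any(full < 0L)) stop("planted category counts must be non-negative")
  if (sum(full) != n_phenotypes) {
    stop("planted category counts must sum to n_phenotypes (",
         sum(full), " != ", n_phenotypes, ")")
  }
  structure(
    list(seed = as.integer(seed), n_entities = as.integer(n_entities),
         n_processes = as.integer(n_processes),
         n_qualities = as.integer(n_qualities),
         n_composite_qualities = as.integer(n_composite_qualities),
         n_phenotypes = as.integer(n_phenotypes), noise = noise,
         planted_categories = full),
    class = "fixture_spec"
  )
}

.with_seed <- function(seed, expr) {
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
  force(expr)
}

# pronounceable nonsense words: CVCCVC over a fixed alphabet, filtered so
# that stems are pairwise distinct, stemming is idempotent on them, none is
# a stop word and none ends in "s" (plural noise must stay reversible)
.fixture_word_pool <- function(n, stop_words) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  words <- character(0)
  stems <- character(0)
  guard <- 0L
  while (length(words) < n) {
    guard <- guard + 1L
    if (guard > 100L * n + 1000L) stop("word pool generation stalled")
    w <- paste0(sample(cons, 1L), sample(vow, 1L), sample(cons, 1L),
                sample(cons, 1L), sample(vow, 1L), sample(cons, 1L))
    s <- porter_stem(w)
    if (w %in% words || s %in% stems) next
    if (w %in% stop_words) next
    if (!identical(porter_stem(s), s)) next
    words <- c(words, w)
    stems <- c(stems, s)
  }
  words
}

.fx_id <- function(prefix, i) sprintf("%s:%07d", prefix, i)

#' Generate a synthetic fixture corpus on disk
#'
#' Writes `anatomy.obo`, `process.obo`, `quality.obo`, `phenotypes.obo` and
#' `gold.tsv` into `out_dir`. Phenotype labels are constructed per planted
#' category: `exact` labels are quality + entity verbatim (rotating through a
#' plain form, a form whose entity label embeds a quality term, and a form
#' that splits a composite quality around the entity so cross-product
#' combination must reassemble it); `exact_synonym` labels decompose wrongly
#' while a phenotype synonym decomposes exactly; `relaxed` labels contain one
#' entity more than gold; `partial` labels share exactly the quality with
#' gold; `disjoint` gold uses concepts absent from the label; and
#' `not_transformed` labels consist of stop words and out-of-dictionary
#' tokens. Generation is a pure function of the spec: the same spec yields
#' byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of the five file paths, invisibly.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stop_words <- default_stop_words()
  pc <- spec$planted_categories
  .with_seed(spec$seed, {
    n_multi <- if (spec$n_entities >= 5L) spec$n_entities %/% 5L else 0L
    pool_n <- spec$n_qualities + spec$n_entities + 2L * n_multi +
      spec$n_processes + (spec$n_entities + spec$n_processes) %/% 3L + 2L +
      pc[["not_transformed"]] + 10L
    pool <- .fixture_word_pool(pool_n, stop_words)
    cursor <- 0L
    take <- function(k = 1L) {
      if (cursor + k > length(pool)) stop("fixture word pool exhausted")
      out <- pool[(cursor + 1L):(cursor + k)]
      cursor <<- cursor + k
      out
    }

    # --- quality ontology -------------------------------------------------
    qual_labels <- take(spec$n_qualities)
    qualities <- lapply(seq_len(spec$n_qualities), function(i) {
      concept(.fx_id("PATX", i), qual_labels[i])
    })
    if ("shared_synonym" %in% spec$noise) {
      if (spec$n_qualities < 2L) {
        stop("shared_synonym noise needs at least two qualities")
      }
      shared <- take(1L)
      qualities[[1L]]$synonyms <- shared
      qualities[[2L]]$synonyms <- shared
    }
    wholes <- lapply(seq_len(spec$n_composite_qualities), function(i) {
      concept(.fx_id("PATX", spec$n_qualities + i),
              paste(qual_labels[2L * i - 1L], qual_labels[2L * i]))
    })
    obs_q <- concept(.fx_id("PATX", spec$n_qualities +
                              spec$n_composite_qualities + 1L),
                     take(1L), obsolete = TRUE)
    quality_ont <- ontology(c(qualities, wholes, list(obs_q)), "PATX")

    # --- anatomy ontology -------------------------------------------------
    entities <- vector("list", spec$n_entities)
    multi_idx <- integer(0)
    # quality terms embedded in multi-word entity labels come from qualities
    # outside the composite pairs; otherwise a phenotype label could start
    # with a whole's own label and legitimately annotate the whole instead
    # of the planted simple quality
    embed_pool <- setdiff(seq_len(spec$n_qualities),
                          seq_len(2L * spec$n_composite_qualities))
    if (!length(embed_pool)) embed_pool <- seq_len(spec$n_qualities)
    for (i in seq_len(spec$n_entities)) {
      if (spec$n_entities >= 5L && i %% 5L == 0L && spec$n_qualities > 0L) {
        embed <- qual_labels[embed_pool[((i %/% 5L - 1L) %%
                                           length(embed_pool)) + 1L]]
        entities[[i]] <- concept(.fx_id("MAX", i),
                                 paste(c(embed, take(2L)), collapse = " "))
        multi_idx <- c(multi_idx, i)
      } else {
        entities[[i]] <- concept(.fx_id("MAX", i), take(1L))
      }
      if (i %% 3L == 0L) entities[[i]]$synonyms <- take(1L)
    }
    obs_a <- concept(.fx_id("MAX", spec$n_entities + 1L), take(1L),
                     obsolete = TRUE)
    single_idx <- setdiff(seq_len(spec$n_entities), multi_idx)

    # --- process ontology -------------------------------------------------
    processes <- lapply(seq_len(spec$n_processes), function(i) {
      k <- concept(.fx_id("GOX", i), take(1L))
      if (i %% 3L == 0L) k$synonyms <- take(1L)
      k
    })
    dup_process <- NULL
    dup_entity_idx <- NULL
    if ("cross_namespace_duplicate" %in% spec$noise) {
      if (pc[["relaxed"]] < 1L || length(single_idx) < 3L) {
        stop("cross_namespace_duplicate noise needs a planted relaxed ",
             "phenotype and at least three single-word entities")
      }
      # reserve the duplicated entity for its one planted phenotype so the
      # extra same-span annotation cannot leak into other categories
      dup_entity_idx <- single_idx[1L]
      dup_process <- concept(.fx_id("GOX", spec$n_processes + 1L),
                             entities[[dup_entity_idx]]$label)
      single_idx <- single_idx[-1L]
    }
    process_ont <- ontology(c(processes,
                              if (!is.null(dup_process)) list(dup_process)),
                            "GOX")

    # --- allocation cursors ----------------------------------------------
    cyc <- function(idx) {
      pos <- 0L
      function() {
        if (!length(idx)) stop("fixture spec leaves no concept to draw from")
        pos <<- pos %% length(idx) + 1L
        idx[pos]
      }
    }
    next_single <- cyc(single_idx)
    next_multi <- cyc(multi_idx)
    next_qual <- cyc(seq_len(spec$n_qualities))
    next_whole <- cyc(seq_along(wholes))

    if (length(single_idx) < 2L &&
        sum(pc[c("exact_synonym", "relaxed", "partial", "disjoint")]) > 0L) {
      stop("planted mismatch categories need at least two single-word ",
           "entities")
    }
    if (spec$n_qualities < 2L && pc[["disjoint"]] > 0L) {
      stop("planted disjoint phenotypes need at least two qualities")
    }

    exact_kinds <- c("plain",
                     if (length(multi_idx)) "containment",
                     if (length(wholes)) "composite")

    phenos <- list()
    gold <- list()
    pid <- 0L
    add_pheno <- function(label, gold_entities, gold_qualities,
                          synonym = NULL) {
      pid <<- pid + 1L
      k <- concept(.fx_id("MPX", pid), label,
                   synonyms = synonym %||% character(0))
      phenos[[pid]] <<- k
      if (!is.null(gold_entities) || !is.null(gold_qualities)) {
        gold[[length(gold) + 1L]] <<- gold_eq(k$id, gold_entities,
                                              gold_qualities)
      }
      k
    }
    plural <- function(word) {
      suffix <- sample(c("s", "es"), 1L, prob = c(0.75, 0.25))
      paste0(word, suffix)
    }

    swap_done <- !("synonym_label_swap" %in% spec$noise)
    contraction_done <- !("contraction" %in% spec$noise)
    dup_done <- is.null(dup_process)

    # --- exact ------------------------------------------------------------
    for (j in seq_len(pc[["exact"]])) {
      kind <- exact_kinds[((j - 1L) %% length(exact_kinds)) + 1L]
      q <- qualities[[next_qual()]]
      if (kind == "plain") {
        e <- entities[[next_single()]]
        tok <- e$label
        if ("plural_suffix" %in% spec$noise) tok <- plural(tok)
        if (!swap_done) {
          # entity now carries its old label as synonym; the phenotype label
          # keeps referencing the old form
          old <- e$label
          e$label <- take(1L)
          e$synonyms <- unique(c(e$synonyms, old))
          entities[[as.integer(sub(".*:", "", e$id))]] <- e
          swap_done <- TRUE
        }
        add_pheno(paste(q$label, tok), e$id, q$id)
      } else if (kind == "containment") {
        e <- entities[[next_multi()]]
        add_pheno(paste(q$label, e$label), e$id, q$id)
      } else {
        wi <- next_whole()
        w <- wholes[[wi]]
        parts <- strsplit(w$label, " ", fixed = TRUE)[[1L]]
        e <- entities[[next_single()]]
        add_pheno(paste(parts[1L], e$label, parts[2L]), e$id, w$id)
      }
    }
    # --- exact_synonym ----------------------------------------------------
    for (j in seq_len(pc[["exact_synonym"]])) {
      q <- qualities[[next_qual()]]
      eA <- entities[[next_single()]]
      eB <- entities[[next_single()]]
      if (identical(eA$id, eB$id)) eB <- entities[[next_single()]]
      add_pheno(paste(q$label, eB$label), eA$id, q$id,
                synonym = paste(q$label, eA$label))
    }
    # --- relaxed ----------------------------------------------------------
    for (j in seq_len(pc[["relaxed"]])) {
      q <- qualities[[next_qual()]]
      if (!dup_done) {
        e <- entities[[dup_entity_idx]]  # label duplicated in process ont
        add_pheno(paste(q$label, e$label), e$id, q$id)
        dup_done <- TRUE
        next
      }
      eA <- entities[[next_single()]]
      eB <- entities[[next_single()]]
      if (identical(eA$id, eB$id)) eB <- entities[[next_single()]]
      add_pheno(paste(q$label, eA$label, eB$label), eA$id, q$id)
    }
    # --- partial ----------------------------------------------------------
    for (j in seq_len(pc[["partial"]])) {
      q <- qualities[[next_qual()]]
      if (!contraction_done) {
        if (!length(multi_idx)) {
          stop("contraction noise needs a multi-word entity ",
               "(n_entities >= 5)")
        }
        e <- entities[[next_multi()]]
        short <- strsplit(e$label, " ", fixed = TRUE)[[1L]][2L]
        add_pheno(paste(q$label, short), e$id, q$id)
        contraction_done <- TRUE
        next
      }
      eA <- entities[[next_single()]]
      eB <- entities[[next_single()]]
      if (identical(eA$id, eB$id)) eB <- entities[[next_single()]]
      add_pheno(paste(q$label, eA$label), eB$id, q$id)
    }
    # --- disjoint ---------------------------------------------------------
    for (j in seq_len(pc[["disjoint"]])) {
      qA <- qualities[[next_qual()]]
      qB <- qualities[[next_qual()]]
      if (identical(qA$id, qB$id)) qB <- qualities[[next_qual()]]
      eA <- entities[[next_single()]]
      eB <- entities[[next_single()]]
      if (identical(eA$id, eB$id)) eB <- entities[[next_single()]]
      add_pheno(paste(qA$label, eA$label), eB$id, qB$id)
    }
    # --- not_transformed --------------------------------------------------
    junk <- take(pc[["not_transformed"]])
    for (j in seq_len(pc[["not_transformed"]])) {
      e <- entities[[next_single()]]
      q <- qualities[[next_qual()]]
      add_pheno(paste("the", junk[j]), e$id, q$id)
    }

    if ("synonym_label_swap" %in% spec$noise && !swap_done) {
      stop("synonym_label_swap noise needs a planted plain exact phenotype")
    }
    if ("contraction" %in% spec$noise && !contraction_done) {
      stop("contraction noise needs a planted partial phenotype")
    }
    if ("plural_suffix" %in% spec$noise &&
        (pc[["exact"]] == 0L || !length(single_idx))) {
      stop("plural_suffix noise needs a planted plain exact phenotype")
    }

    anatomy_ont <- ontology(c(entities, list(obs_a)), "MAX")
    pheno_ont <- ontology(phenos, "MPX")

    paths <- c(anatomy = file.path(out_dir, "anatomy.obo"),
               process = file.path(out_dir, "process.obo"),
               quality = file.path(out_dir, "quality.obo"),
               phenotypes = file.path(out_dir, "phenotypes.obo"),
               gold = file.path(out_dir, "gold.tsv"))
    write_obo(anatomy_ont, paths[["anatomy"]])
    write_obo(process_ont, paths[["process"]])
    write_obo(quality_ont, paths[["quality"]])
    write_obo(pheno_ont, paths[["phenotypes"]])
    write_gold_eq(gold, paths[["gold"]], provenance = FALSE)
    invisible(paths)
  })
}

#' Load a generated fixture directory
#'
#' Convenience loader for the five files written by [generate_fixture()].
#'
#' @param dir fixture directory.
#' @return list with elements `anatomy`, `process`, `quality`, `phenotypes`
#'   (ontologies) and `gold` (list of [gold_eq()]).
#' @export
load_fixture <- function(dir) {
  list(anatomy = parse_obo(file.path(dir, "anatomy.obo"), "MAX"),
       process = parse_obo(file.path(dir, "process.obo"), "GOX"),
       quality = parse_obo(file.path(dir, "quality.obo"), "PATX"),
       phenotypes = parse_obo(file.path(dir, "phenotypes.obo"), "MPX"),
       gold = parse_gold_eq(file.path(dir, "gold.tsv")))
}

#' Exhaustive cross-product oracle
#'
#' Brute-force reference for [derive_cross_products()]: compares every
#' ordered concept pair term by term with a plain quadruple loop and records
#' B as a component of A iff some term stem set of B is a non-empty subset of
#' some term stem set of A. Intended for small ontologies (tests); semantics
#' identical to [derive_cross_products()] by definition.
#'
#' @param quality_ontology the quality [ontology()].
#' @param stop_words stop-word vector.
#' @param stem logical; stem terms before comparison.
#' @return named list keyed by whole id; each element has `whole_id` and
#'   sorted `component_ids`.
#' @export
brute_force_cross_products <- function(quality_ontology,
                                       stop_words = default_stop_words(),
                                       stem = TRUE) {
  live <- Filter(function(k) !k$obsolete, quality_ontology$concepts)
  term_sets <- lapply(live, .term_stem_sets, stop_words = stop_words,
                      stem = stem)
  ids <- names(term_sets)
  out <- list()
  for (a in ids) {
    comp <- character(0)
    for (b in setdiff(ids, a)) {
      found <- FALSE
      for (ta in term_sets[[a]]) {
        for (tb in term_sets[[b]]) {
          if (length(tb$stems) && all(tb$stems %in% ta$stems)) {
            found <- TRUE
          }
        }
      }
      if (found) comp <- c(comp, b)
    }
    if (length(comp)) {
      out[[a]] <- list(whole_id = a, component_ids = sort(comp))
    }
  }
  out
}
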