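# Shared data model (concepts, ontologies, gold EQ statements) and readers /
# writers for OBO flat files, the tabular ontology dialect and gold EQ TSV.

#' CURIE helpers
#'
#' A CURIE is a compact identifier `PREFIX:LOCALID` with a non-empty prefix
#' and local id, e.g. `PATO:0000462`.
#'
#' @param id character vector of identifiers.
#' @return `is_curie()`: logical vector; `curie_prefix()`: the prefix part.
#' @export
is_curie <- function(id) {
  grepl("^[^:[:space:]]+:[^[:space:]]+$", id)
}

#' @rdname is_curie
#' @export
curie_prefix <- function(id) {
  sub(":.*$", "", id)
}

#' Construct a concept record
#'
#' One ontology term: CURIE id, primary label, synonyms and obsolete flag.
#' The namespace is the id's prefix.
#'
#' @param id CURIE string.
#' @param label primary label (may be empty only for obsolete concepts).
#' @param synonyms character vector of synonym strings.
#' @param obsolete logical flag.
#' @return object of class `eq_concept`.
#' @export
concept <- function(id, label, synonyms = character(0), obsolete = FALSE) {
  if (!is_curie(id)) stop("not a CURIE: ", id)
  if (!obsolete && (!is.character(label) || !nzchar(label))) {
    stop("non-obsolete concept needs a non-empty label: ", id)
  }
  structure(
    list(id = id, label = label, synonyms = as.character(synonyms),
         obsolete = isTRUE(obsolete), namespace = curie_prefix(id)),
    class = "eq_concept"
  )
}

#' Construct an ontology
#'
#' A set of concepts keyed by id. The ontology namespace is the declared
#' prefix; concepts whose prefix differs are kept but recorded as foreign
#' (an ontology file may legitimately contain cross-namespace ids).
#'
#' @param concepts list of [concept()] records.
#' @param namespace declared prefix; defaults to the most frequent concept
#'   prefix (empty string for an empty ontology).
#' @return object of class `eq_ontology` with fields `namespace`, `concepts`
#'   (named list) and `foreign_ids`.
#' @export
ontology <- function(concepts = list(), namespace = NULL) {
  ids <- vapply(concepts, function(x) x$id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate concept id: ", ids[duplicated(ids)][1L])
  }
  names(concepts) <- ids
  if (is.null(namespace)) {
    namespace <- if (length(ids)) {
      names(sort(table(curie_prefix(ids)), decreasing = TRUE))[1L]
    } else ""
  }
  foreign <- ids[length(ids) > 0 & curie_prefix(ids) != namespace]
  structure(
    list(namespace = namespace, concepts = concepts,
         foreign_ids = as.character(foreign)),
    class = "eq_ontology"
  )
}

#' @export
print.eq_ontology <- function(x, ...) {
  cat("<eq_ontology> namespace=", x$namespace,
      " concepts=", length(x$concepts),
      " obsolete=", sum(vapply(x$concepts, function(k) k$obsolete, logical(1L))),
      "\n", sep = "")
  if (length(x$foreign_ids)) {
    cat("  foreign ids:", paste(x$foreign_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.eq_ontology <- function(x) length(x$concepts)

.obo_unquote <- function(line) {
  # first double-quoted string on the line, with \" unescaping
  m <- regmatches(line, regexpr('"(\\\\.|[^"\\\\])*"', line))
  if (!length(m)) return(NA_character_)
  body <- substr(m, 2L, nchar(m) - 1L)
  gsub("\\\\(.)", "\\1", body)
}

.obo_strip_comment <- function(line) {
  # OBO trailing comments start with " ! "; do not cut inside quotes
  out <- character(length(line))
  for (i in seq_along(line)) {
    s <- line[i]
    inq <- FALSE
    cut <- NA_integer_
    chs <- strsplit(s, "", fixed = TRUE)[[1L]]
    j <- 1L
    while (j <= length(chs)) {
      if (chs[j] == "\\") j <- j + 1L
      else if (chs[j] == '"') inq <- !inq
      else if (chs[j] == "!" && !inq) { cut <- j; break }
      j <- j + 1L
    }
    out[i] <- if (is.na(cut)) s else substr(s, 1L, cut - 1L)
  }
  trimws(out)
}

#' Parse an OBO flat file into an ontology
#'
#' Reads OBO 1.2/1.4 text. One concept is created per `[Term]` stanza;
#' synonyms are collected from all `synonym:` lines regardless of scope
#' (EXACT/BROAD/... are treated alike) and from legacy `*_synonym:` tags;
#' the obsolete flag comes from `is_obsolete`. Non-`[Term]` stanzas are
#' ignored.
#'
#' @param path path to the OBO file.
#' @param namespace optional declared namespace (defaults to majority prefix).
#' @return an [ontology()].
#' @export
parse_obo <- function(path, namespace = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  concepts <- list()
  in_term <- FALSE
  cur <- NULL
  cur_line <- 0L
  flush <- function(cur, cur_line) {
    if (is.null(cur)) return(NULL)
    if (is.na(cur$id)) {
      stop("malformed [Term] stanza starting at line ", cur_line,
           ": missing id")
    }
    if (is.na(cur$name) && !cur$obsolete) {
      stop("malformed [Term] stanza starting at line ", cur_line,
           ": missing name for non-obsolete term ", cur$id)
    }
    concept(cur$id, if (is.na(cur$name)) "" else cur$name,
            cur$synonyms, cur$obsolete)
  }
  for (i in seq_along(lines)) {
    raw <- lines[i]
    line <- .obo_strip_comment(raw)
    if (startsWith(line, "[")) {
      k <- flush(cur, cur_line)
      if (!is.null(k)) concepts[[length(concepts) + 1L]] <- k
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NA_character_, name = NA_character_,
                    synonyms = character(0), obsolete = FALSE)
        cur_line <- i
      }
      next
    }
    if (!in_term || !nzchar(line)) next
    if (!grepl("^[A-Za-z_-]+:", line)) {
      stop("malformed line ", i, " in OBO file: ", raw)
    }
    tag <- sub(":.*$", "", line)
    val <- trimws(sub("^[A-Za-z_-]+:", "", line))
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "synonym" || grepl("_synonym$", tag)) {
      syn <- .obo_unquote(val)
      if (is.na(syn)) syn <- val
      if (nzchar(syn)) cur$synonyms <- c(cur$synonyms, syn)
    } else if (tag == "is_obsolete") {
      cur$obsolete <- tolower(val) %in% c("true", "1")
    }
  }
  k <- flush(cur, cur_line)
  if (!is.null(k)) concepts[[length(concepts) + 1L]] <- k
  ontology(concepts, namespace)
}

.tbl_sanitize <- function(x) {
  # tabs/pipes inside labels or synonyms would break the dialect
  trimws(gsub("[\t|]+", " ", x))
}

#' Read and write the tabular ontology dialect
#'
#' A UTF-8 tab-separated file with header columns `id`, `name`, `synonyms`
#' (pipe-separated, may be empty) and `obsolete` (`true`/`false`). Writing
#' replaces tab and pipe characters inside labels or synonyms by a single
#' space so the dialect stays unambiguous; `parse_tbl(write_tbl(x))`
#' round-trips any ontology that contains no such characters.
#'
#' @param path path to the .tbl file.
#' @param namespace optional declared namespace.
#' @return `parse_tbl()`: an [ontology()]; `write_tbl()`: the path,
#'   invisibly.
#' @export
parse_tbl <- function(path, namespace = NULL) {
  if (!file.exists(path)) stop("tbl file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  for (col in c("id", "name", "synonyms", "obsolete")) {
    if (!col %in% names(tab)) {
      stop("tbl file is missing mandatory column '", col, "': ", path)
    }
  }
  concepts <- lapply(seq_len(nrow(tab)), function(i) {
    syn <- strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1L]]
    syn <- syn[nzchar(syn)]
    concept(tab$id[i], tab$name[i], syn,
            tolower(tab$obsolete[i]) %in% c("true", "1"))
  })
  ontology(concepts, namespace)
}

#' @rdname parse_tbl
#' @param x an [ontology()] to write.
#' @export
write_tbl <- function(x, path) {
  stopifnot(inherits(x, "eq_ontology"))
  rows <- vapply(x$concepts, function(k) {
    paste(k$id, .tbl_sanitize(k$label),
          paste(.tbl_sanitize(k$synonyms), collapse = "|"),
          if (k$obsolete) "true" else "false",
          sep = "\t")
  }, character(1L))
  writeLines(c("id\tname\tsynonyms\tobsolete", unname(rows)), path,
             useBytes = TRUE)
  invisible(path)
}

#' Write an ontology as an OBO flat file
#'
#' Emits one `[Term]` stanza per concept (id, name, `synonym: "..." EXACT []`
#' lines, `is_obsolete` where set) in the ontology's concept order.
#' `parse_obo()` round-trips the result.
#'
#' @param x an [ontology()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_obo <- function(x, path) {
  stopifnot(inherits(x, "eq_ontology"))
  lines <- c("format-version: 1.2", "")
  for (k in x$concepts) {
    lines <- c(lines, "[Term]", paste0("id: ", k$id),
               if (nzchar(k$label)) paste0("name: ", k$label),
               vapply(k$synonyms, function(s) {
                 sprintf("synonym: \"%s\" EXACT []", gsub('"', "'", s))
               }, character(1L), USE.NAMES = FALSE),
               if (k$obsolete) "is_obsolete: true",
               "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a gold EQ statement
#'
#' The manually curated Entity-Quality decomposition of one phenotype
#' concept: a set of entity ids (anatomy or process concepts) and a non-empty
#' set of quality ids.
#'
#' @param phenotype_id CURIE of the phenotype concept.
#' @param entity_ids character vector of entity CURIEs (may be empty;
#'   quality-only statements exist in practice).
#' @param quality_ids character vector of quality CURIEs (at least one).
#' @return object of class `gold_eq`.
#' @export
gold_eq <- function(phenotype_id, entity_ids, quality_ids) {
  entity_ids <- unique(as.character(entity_ids))
  quality_ids <- unique(as.character(quality_ids))
  if (!is_curie(phenotype_id)) stop("not a CURIE: ", phenotype_id)
  if (!length(quality_ids)) {
    stop("gold EQ statement for ", phenotype_id, " has no quality id")
  }
  bad <- c(entity_ids, quality_ids)[!is_curie(c(entity_ids, quality_ids))]
  if (length(bad)) stop("not a CURIE in gold statement: ", bad[1L])
  structure(
    list(phenotype_id = phenotype_id, entity_ids = entity_ids,
         quality_ids = quality_ids),
    class = "gold_eq"
  )
}

.looks_like_obo <- function(path) {
  head <- readLines(path, n = 50L, encoding = "UTF-8", warn = FALSE)
  any(grepl("^\\[Term\\]", head)) || any(grepl("^format-version:", head))
}

.parse_gold_obo <- function(path) {
  # OBO logical definitions: genus quality via plain intersection_of, entity
  # via an inheres_in (or inheres_in_part_of / RO:0000052) relation
  lines <- .obo_strip_comment(readLines(path, encoding = "UTF-8",
                                        warn = FALSE))
  out <- list()
  cur_id <- NA_character_
  ent <- character(0)
  qual <- character(0)
  in_term <- FALSE
  flush <- function() {
    if (!is.na(cur_id) && (length(ent) || length(qual))) {
      if (!length(qual)) {
        stop("gold logical definition for ", cur_id, " has no quality genus")
      }
      out[[length(out) + 1L]] <<- gold_eq(cur_id, ent, qual)
    }
  }
  for (line in lines) {
    if (startsWith(line, "[")) {
      flush()
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_
      ent <- character(0)
      qual <- character(0)
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur_id <- trimws(sub("^id:", "", line))
    } else if (grepl("^intersection_of:", line)) {
      parts <- strsplit(trimws(sub("^intersection_of:", "", line)),
                        "[[:space:]]+")[[1L]]
      if (length(parts) == 1L) {
        qual <- c(qual, parts)
      } else if (parts[1L] %in% c("inheres_in", "inheres_in_part_of",
                                  "RO:0000052", "OBO_REL:inheres_in")) {
        ent <- c(ent, parts[2L])
      }
    }
  }
  flush()
  out
}

#' Read a gold-standard EQ statement file
#'
#' Accepts two dialects: (1) a TSV with header columns `phenotype_id`,
#' `entity_ids` and `quality_ids` (multi-values pipe-separated, entities may
#' be empty); (2) an OBO file of logical definitions, where each `[Term]`
#' stanza's plain `intersection_of:` line names the quality genus and
#' `intersection_of: inheres_in <id>` lines name the entities. Rows sharing a
#' phenotype id are merged by set union of entities and of qualities.
#'
#' @param path path to the gold file.
#' @return list of [gold_eq()] records, one per phenotype id. Statements with
#'   no entity are kept and reported via a warning.
#' @export
parse_gold_eq <- function(path) {
  if (!file.exists(path)) stop("gold EQ file not found: ", path)
  if (.looks_like_obo(path)) {
    gold <- .parse_gold_obo(path)
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character", quote = "",
                             check.names = FALSE, na.strings = NULL,
                             fileEncoding = "UTF-8")
    for (col in c("phenotype_id", "entity_ids", "quality_ids")) {
      if (!col %in% names(tab)) {
        stop("gold EQ file is missing mandatory column '", col, "': ", path)
      }
    }
    gold <- lapply(seq_len(nrow(tab)), function(i) {
      ent <- strsplit(tab$entity_ids[i], "|", fixed = TRUE)[[1L]]
      qual <- strsplit(tab$quality_ids[i], "|", fixed = TRUE)[[1L]]
      gold_eq(tab$phenotype_id[i], ent[nzchar(ent)], qual[nzchar(qual)])
    })
  }
  # merge duplicate phenotype ids by set union
  ids <- vapply(gold, function(g) g$phenotype_id, character(1L))
  merged <- lapply(split(gold, factor(ids, levels = unique(ids))), function(gs) {
    gold_eq(gs[[1L]]$phenotype_id,
            unique(unlist(lapply(gs, function(g) g$entity_ids))),
            unique(unlist(lapply(gs, function(g) g$quality_ids))))
  })
  merged <- unname(merged)
  n_empty <- sum(vapply(merged, function(g) length(g$entity_ids) == 0L,
                        logical(1L)))
  if (n_empty > 0L) {
    warning(n_empty, " gold statement(s) have no entity (quality-only)")
  }
  merged
}

#' Write gold-format EQ statements
#'
#' Writes a list of [gold_eq()] or generated `eq_statement` records to the
#' gold TSV dialect. Generated statements gain a `provenance` column.
#'
#' @param statements list of `gold_eq` or `eq_statement` records.
#' @param path output path.
#' @param provenance logical; include a provenance column (default: `TRUE`
#'   when any record carries one).
#' @return the path, invisibly.
#' @export
write_gold_eq <- function(statements, path, provenance = NULL) {
  has_prov <- vapply(statements, function(s) !is.null(s$provenance),
                     logical(1L))
  if (is.null(provenance)) provenance <- any(has_prov)
  header <- c("phenotype_id", "entity_ids", "quality_ids",
              if (provenance) "provenance")
  rows <- vapply(statements, function(s) {
    paste(c(s$phenotype_id,
            paste(sort(s$entity_ids), collapse = "|"),
            paste(sort(s$quality_ids), collapse = "|"),
            if (provenance) {
              if (is.null(s$provenance)) "gold" else s$provenance
            }),
          collapse = "\t")
  }, character(1L))
  writeLines(c(paste(header, collapse = "\t"), unname(rows)), path,
             useBytes = TRUE)
  invisible(path)
}

#' Restrict a gold corpus to structure and process phenotypes
#'
#' The decomposition method only supports phenotypes whose gold statement is
#' built from anatomy or process entities plus qualities. A statement is kept
#' iff every entity id's prefix lies in `anatomy_ns` or `process_ns` and
#' every quality id's prefix equals `quality_ns`. The result is a subset of
#' the input and the operation is idempotent.
#'
#' @param gold list of [gold_eq()] records.
#' @param anatomy_ns character vector of anatomy namespaces (e.g. `"MA"`).
#' @param process_ns character vector of process namespaces (e.g. `"GO"`).
#' @param quality_ns single quality namespace (e.g. `"PATO"`).
#' @return filtered list of `gold_eq` records (possibly empty).
#' @export
select_structure_process <- function(gold, anatomy_ns, process_ns,
                                     quality_ns) {
  stopifnot(length(anatomy_ns) > 0L, length(process_ns) > 0L,
            length(quality_ns) == 1L)
  if (length(intersect(c(anatomy_ns, process_ns), quality_ns)) ||
      length(intersect(anatomy_ns, process_ns))) {
    stop("namespace sets must be disjoint")
  }
  keep <- vapply(gold, function(g) {
    all(curie_prefix(g$entity_ids) %in% c(anatomy_ns, process_ns)) &&
      all(curie_prefix(g$quality_ids) == quality_ns)
  }, logical(1L))
  gold[keep]
}
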