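# Lexicon building, subsequence annotation, containment filtering.

test_that("build_lexicon keys entries by joined stems", {
  lex <- build_lexicon(mini_pato())
  key <- paste(porter_stem("decreased"), collapse = " ")
  expect_identical(lex$entries[[key]]$id, "PATO:0001997")
  expect_identical(lex$entries[[key]]$origin, "label")
  # synonym-origin entry
  syn_key <- porter_stem("enlarged")
  expect_identical(lex$entries[[syn_key]]$id, "PATO:0000584")
  expect_identical(lex$entries[[syn_key]]$origin, "synonym")
  # empty ontology -> empty lexicon
  expect_length(build_lexicon(ontology())$entries, 0L)
})

test_that("build_lexicon excludes obsolete concepts and empty terms", {
  ont <- make_ont(c("TX:1", "TX:2", "TX:3"),
                  c("kidney", "liver", "of the"),
                  obsolete = c(FALSE, TRUE, FALSE))
  expect_warning(lex <- build_lexicon(ont), "empty")
  ids <- unlist(lapply(lex$entries, `[[`, "id"))
  expect_identical(unname(ids), "TX:1")
})

test_that("a shared synonym maps one key to two concept ids", {
  ont <- make_ont(c("TX:1", "TX:2"), c("alpha", "beta"),
                  synonyms = list("shared term", "shared term"))
  lex <- build_lexicon(ont)
  key <- paste(porter_stem(c("shared", "term")), collapse = " ")
  expect_setequal(lex$entries[[key]]$id, c("TX:1", "TX:2"))
})

test_that("annotate finds overlapping mentions across lexicons", {
  nt <- normalize_label("enlarged dorsal root ganglion")
  ann <- annotate(nt, mini_lexicons(), "MP:0008490")
  # the anatomy term, its embedded quality, and the synonym-matched quality
  expect_true(any(ann$concept_id == "MA:0000232" & ann$start == 1 &
                    ann$end == 4))
  expect_true(any(ann$concept_id == "PATO:0001233" & ann$start == 1 &
                    ann$end == 2))
  expect_true(any(ann$concept_id == "PATO:0000584" & ann$start == 0 &
                    ann$end == 1 & ann$origin == "synonym"))
  expect_true(all(ann$phenotype_id == "MP:0008490"))
  expect_true(all(ann$start >= 0 & ann$start < ann$end &
                    ann$end <= length(nt$tokens)))
  expect_identical(ann$namespace, curie_prefix(ann$concept_id))
})

test_that("annotate returns nothing without hits and one span for a full label", {
  expect_identical(nrow(annotate(normalize_label("xyzzy frobnitz"),
                                 mini_lexicons())), 0L)
  ann <- annotate(normalize_label("lumbar vertebra"), mini_lexicons())
  expect_identical(ann$concept_id, "MA:0000312")
  expect_identical(c(ann$start, ann$end), c(0L, 2L))
})

test_that("annotate agrees with a brute-force subsequence oracle", {
  dir <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 11, n_phenotypes = 25,
                                noise = "shared_synonym"), dir)
  fx <- load_fixture(dir)
  sw <- default_stop_words()
  lexicons <- list(build_lexicon(fx$anatomy, TRUE, sw),
                   build_lexicon(fx$quality, TRUE, sw))
  labels <- vapply(fx$phenotypes$concepts, `[[`, character(1), "label")
  for (lab in labels) {
    nt <- normalize_label(lab, sw)
    expect_lte(length(nt$tokens), 12L)
    got <- annotate(nt, lexicons, "MPX:0000000")
    # oracle: test every contiguous subsequence against every lexicon key
    want <- list()
    n <- length(nt$stems)
    if (n > 0) {
      for (i in seq_len(n)) for (j in i:n) {
        key <- paste(nt$stems[i:j], collapse = " ")
        for (lex in lexicons) {
          hit <- lex$entries[[key]]
          if (!is.null(hit)) {
            want[[length(want) + 1L]] <-
              data.frame(phenotype_id = "MPX:0000000", start = i - 1L,
                         end = j, concept_id = hit$id,
                         namespace = lex$namespace, origin = hit$origin,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
    want <- if (length(want)) unique(do.call(rbind, want)) else got[0, ]
    want <- want[order(want$start, want$end, want$namespace,
                       want$concept_id), , drop = FALSE]
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("annotations without synonyms are a subset of those with", {
  dir <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 13, n_phenotypes = 30,
                                noise = "synonym_label_swap"), dir)
  fx <- load_fixture(dir)
  sw <- default_stop_words()
  with_syn <- list(build_lexicon(fx$anatomy, TRUE, sw),
                   build_lexicon(fx$quality, TRUE, sw))
  without <- list(build_lexicon(fx$anatomy, FALSE, sw),
                  build_lexicon(fx$quality, FALSE, sw))
  subset_rows <- function(a, b) {
    if (!nrow(a)) return(TRUE)
    key <- function(d) paste(d$start, d$end, d$concept_id)
    all(key(a) %in% key(b))
  }
  for (k in fx$phenotypes$concepts) {
    nt <- normalize_label(k$label, sw)
    expect_true(subset_rows(annotate(nt, without), annotate(nt, with_syn)))
  }
})

test_that("filter_contained drops spans strictly inside longer ones", {
  ann <- annotate(normalize_label("enlarged dorsal root ganglion"),
                  mini_lexicons(), "MP:0008490")
  out <- filter_contained(ann)
  expect_true("MA:0000232" %in% out$concept_id)
  expect_false("PATO:0001233" %in% out$concept_id)  # dorsal, inside [1,4)
  expect_true("PATO:0000584" %in% out$concept_id)   # enlarged, not contained

  one <- ann[1, , drop = FALSE]
  expect_identical(filter_contained(one), one)
})

test_that("nested spans collapse to the outermost annotation", {
  mk <- function(start, end, id) {
    data.frame(phenotype_id = "MPX:1", start = start, end = end,
               concept_id = id, namespace = "PATX", origin = "label",
               stringsAsFactors = FALSE)
  }
  nested <- rbind(mk(0L, 4L, "PATX:1"), mk(0L, 2L, "PATX:2"),
                  mk(0L, 1L, "PATX:3"))
  expect_identical(filter_contained(nested)$concept_id, "PATX:1")
  # identical spans all survive
  twins <- rbind(mk(0L, 2L, "PATX:1"), mk(0L, 2L, "PATX:2"))
  expect_identical(nrow(filter_contained(twins)), 2L)
})

test_that("containment filtering is sound and idempotent on random spans", {
  for (seed in 0:9) {
    set.seed(seed)
    n <- sample(2:15, 1)
    start <- sample(0:8, n, replace = TRUE)
    len <- sample(1:5, n, replace = TRUE)
    ann <- data.frame(phenotype_id = "MPX:1", start = start,
                      end = start + len,
                      concept_id = sprintf("PATX:%07d", seq_len(n)),
                      namespace = "PATX", origin = "label",
                      stringsAsFactors = FALSE)
    out <- filter_contained(ann)
    # O(n^2) soundness scan: no remaining span strictly inside another
    for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
      if (i == j) next
      strict <- out$start[j] <= out$start[i] && out$end[i] <= out$end[j] &&
        (out$end[j] - out$start[j]) > (out$end[i] - out$start[i])
      expect_false(strict)
    }
    expect_identical(filter_contained(out), out)
    # only containment removals: survivors are original rows
    expect_true(all(out$concept_id %in% ann$concept_id))
  }
})

test_that("duplicated_spans flags identical spans across namespaces", {
  ann <- rbind(
    data.frame(phenotype_id = "HPX:1", start = 0L, end = 1L,
               concept_id = "GOX:0005694", namespace = "GOX",
               origin = "label", stringsAsFactors = FALSE),
    data.frame(phenotype_id = "HPX:1", start = 0L, end = 1L,
               concept_id = "FMX:0067093", namespace = "FMX",
               origin = "label", stringsAsFactors = FALSE)
  )
  dup <- duplicated_spans(ann)
  expect_identical(nrow(dup), 1L)
  expect_identical(dup$concept_ids, "FMX:0067093|GOX:0005694")
  expect_identical(nrow(duplicated_spans(ann[1, ])), 0L)
})
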