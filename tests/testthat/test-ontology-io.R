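# OBO / tabular parsing, gold EQ files, structure/process selection.

obo_lines <- function(...) {
  f <- withr::local_tempfile(lines = c("format-version: 1.2", "", ...),
                             .local_envir = parent.frame())
  f
}

test_that("parse_obo builds concepts from [Term] stanzas", {
  f <- obo_lines(
    "[Term]", "id: PATO:0001472", "name: decreased depth",
    "synonym: \"reduced depth\" EXACT []", "",
    "[Term]", "id: PATO:0000462", "name: absent",
    "is_obsolete: false", "",
    "[Typedef]", "id: part_of", "name: part of"
  )
  ont <- parse_obo(f)
  expect_length(ont, 2L)
  k <- ont$concepts[["PATO:0001472"]]
  expect_identical(k$label, "decreased depth")
  expect_identical(k$synonyms, "reduced depth")
  expect_identical(k$namespace, "PATO")
  expect_false(ont$concepts[["PATO:0000462"]]$obsolete)
})

test_that("parse_obo handles empty files, obsolete terms and errors", {
  expect_length(parse_obo(obo_lines()), 0L)

  # 10 terms, 3 obsolete, counted stanza by stanza in the generator
  ids <- sprintf("TX:%07d", 1:10)
  obsolete <- seq_along(ids) %in% c(2, 5, 9)
  stanzas <- unlist(lapply(seq_along(ids), function(i) {
    c("[Term]", paste0("id: ", ids[i]), paste0("name: term", i),
      if (obsolete[i]) "is_obsolete: true", "")
  }))
  ont <- parse_obo(obo_lines(stanzas))
  expect_length(ont, 10L)
  expect_identical(sum(vapply(ont$concepts, `[[`, logical(1), "obsolete")),
                   3L)

  expect_error(parse_obo(obo_lines("[Term]", "name: no id")), "missing id")
  expect_error(
    parse_obo(obo_lines("[Term]", "id: TX:1", "name: a", "",
                        "[Term]", "id: TX:1", "name: b")),
    "duplicate"
  )
  expect_error(parse_obo(obo_lines("[Term]", "id: TX:1", "name: a",
                                   "not a tag line")),
               "line 6")
})

test_that("parse_obo ignores trailing comments but not quoted bangs", {
  f <- obo_lines("[Term]", "id: TX:1",
                 "name: big head ! inline comment",
                 "synonym: \"loud!noise\" EXACT []")
  k <- parse_obo(f)$concepts[["TX:1"]]
  expect_identical(k$label, "big head")
  expect_identical(k$synonyms, "loud!noise")
})

test_that("tbl dialect round-trips and validates columns", {
  f <- withr::local_tempfile(lines = c(
    "id\tname\tsynonyms\tobsolete",
    "MP:0002895\tabnormal otolithic membrane\t\tfalse",
    "TX:0000002\ttwo syns\ta|b\tfalse"
  ))
  ont <- parse_tbl(f)
  expect_identical(ont$concepts[["MP:0002895"]]$label,
                   "abnormal otolithic membrane")
  expect_identical(ont$concepts[["TX:0000002"]]$synonyms, c("a", "b"))

  out <- withr::local_tempfile()
  write_tbl(ont, out)
  expect_identical(parse_tbl(out), ont)

  # empty ontology -> header-only file that reparses empty
  empty <- withr::local_tempfile()
  write_tbl(ontology(), empty)
  expect_identical(readLines(empty), "id\tname\tsynonyms\tobsolete")
  expect_length(parse_tbl(empty), 0L)

  bad <- withr::local_tempfile(lines = c("id\tname\tobsolete",
                                         "TX:1\ta\tfalse"))
  expect_error(parse_tbl(bad), "synonyms")
})

test_that("write_tbl sanitizes tab and pipe characters in terms", {
  ont <- ontology(list(concept("TX:1", "label", "syn\twith|bars")))
  f <- withr::local_tempfile()
  write_tbl(ont, f)
  re <- parse_tbl(f)
  expect_identical(re$concepts[["TX:1"]]$synonyms, "syn with bars")
})

test_that("write_obo round-trips through parse_obo", {
  dir <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 3, n_phenotypes = 20), dir)
  ont <- parse_obo(file.path(dir, "quality.obo"), "PATX")
  f <- withr::local_tempfile()
  write_obo(ont, f)
  expect_identical(parse_obo(f, "PATX"), ont)
})

test_that("parse_gold_eq reads the TSV dialect and merges duplicates", {
  f <- withr::local_tempfile(lines = c(
    "phenotype_id\tentity_ids\tquality_ids",
    "MP:0004650\tMA:0000312\tPATO:0002001",
    "MP:0000001\tMA:0000001\tPATO:0000001",
    "MP:0000001\tMA:0000002|MA:0000001\tPATO:0000460"
  ))
  gold <- parse_gold_eq(f)
  expect_length(gold, 2L)
  first <- gold[[1L]]
  expect_identical(first$phenotype_id, "MP:0004650")
  expect_identical(first$entity_ids, "MA:0000312")
  expect_identical(first$quality_ids, "PATO:0002001")
  merged <- gold[[2L]]
  expect_setequal(merged$entity_ids, c("MA:0000001", "MA:0000002"))
  expect_setequal(merged$quality_ids, c("PATO:0000001", "PATO:0000460"))

  empty <- withr::local_tempfile(lines = "phenotype_id\tentity_ids\tquality_ids")
  expect_length(parse_gold_eq(empty), 0L)

  noq <- withr::local_tempfile(lines = c(
    "phenotype_id\tentity_ids\tquality_ids", "MP:1\tMA:1\t"))
  expect_error(parse_gold_eq(noq), "no quality")
})

test_that("parse_gold_eq reads OBO logical definitions", {
  f <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "",
    "[Term]", "id: MP:0004650",
    "intersection_of: PATO:0002001",
    "intersection_of: inheres_in MA:0000312", "",
    "[Term]", "id: MP:0000002",
    "intersection_of: PATO:0000460",
    "intersection_of: RO:0000052 MA:0000005"
  ))
  gold <- parse_gold_eq(f)
  expect_length(gold, 2L)
  expect_identical(gold[[1L]]$entity_ids, "MA:0000312")
  expect_identical(gold[[1L]]$quality_ids, "PATO:0002001")
  expect_identical(gold[[2L]]$entity_ids, "MA:0000005")
})

test_that("quality-only gold statements load with a warning", {
  f <- withr::local_tempfile(lines = c(
    "phenotype_id\tentity_ids\tquality_ids", "MP:1\t\tPATO:1"))
  expect_warning(gold <- parse_gold_eq(f), "quality-only")
  expect_length(gold[[1L]]$entity_ids, 0L)
  expect_true(all(is_curie(c(gold[[1L]]$phenotype_id,
                             gold[[1L]]$quality_ids))))
})

test_that("select_structure_process filters by namespace prefixes", {
  gold <- list(
    gold_eq("MP:1", "MA:1", "PATO:1"),
    gold_eq("MP:2", "CHEBI:1", "PATO:1"),
    gold_eq("MP:3", c("MA:2", "GO:1"), "PATO:2"),
    gold_eq("MP:4", "MA:3", "BFO:1"),
    gold_eq("MP:5", "GO:2", "PATO:3"),
    gold_eq("MP:6", "FMA:1", "PATO:1"),
    gold_eq("MP:7", "MA:9", c("PATO:1", "PATO:2")),
    gold_eq("MP:8", "UBERON:1", "PATO:1"),
    gold_eq("MP:9", "MA:1", c("PATO:1", "CHEBI:9")),
    gold_eq("MP:10", character(0), "PATO:5")
  )
  kept <- select_structure_process(gold, "MA", "GO", "PATO")
  # manual prefix check: MP:1, MP:3, MP:5, MP:7 and the quality-only MP:10
  expect_identical(vapply(kept, `[[`, character(1), "phenotype_id"),
                   c("MP:1", "MP:3", "MP:5", "MP:7", "MP:10"))
  # subset of the input and idempotent
  expect_true(all(vapply(kept, function(g) {
    any(vapply(gold, identical, logical(1), g))
  }, logical(1))))
  expect_identical(select_structure_process(kept, "MA", "GO", "PATO"), kept)
  expect_error(select_structure_process(gold, "MA", "MA", "PATO"),
               "disjoint")
})
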