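# Match tiers, corpus evaluation and mismatch sampling.

test_that("match_eq distinguishes exact, relaxed, partial and disjoint", {
  gen <- eq_statement("MP:1", "MA:0000232", "PATO:0001233")
  gold <- gold_eq("MP:1", "MA:0000232", "PATO:0001233")
  expect_identical(match_eq(gen, gold, "exact")$category, "exact")

  # quality replaced by a curator convention: generated and gold qualities
  # differ, entities agree -> not exact, degrades to partial
  gen2 <- eq_statement("MP:0006038", "GO:0000001", "PATO:0000470")
  gold2 <- gold_eq("MP:0006038", "GO:0000001", "PATO:0000912")
  m2 <- match_eq(gen2, gold2, "exact")
  expect_false(m2$category == "exact")
  expect_identical(m2$category, "partial")
  expect_identical(m2$shared_entities, "GO:0000001")
  expect_length(m2$shared_qualities, 0L)

  expect_error(match_eq(gen, gold_eq("MP:2", "MA:1", "PATO:1")), "mismatch")
})

test_that("relaxed matching is exactly the gold-subset relation", {
  # enumerate all generated subsets over a 2-entity/2-quality universe and
  # compare with independently computed set relations
  ents <- c("MA:1", "MA:2")
  quals <- c("PATO:1", "PATO:2")
  gold <- gold_eq("MP:1", "MA:1", "PATO:1")
  for (ei in 0:3) for (qi in 0:3) {
    gen_e <- ents[which(bitwAnd(ei, 1:2) > 0)]
    gen_q <- quals[which(bitwAnd(qi, 1:2) > 0)]
    gen <- eq_statement("MP:1", gen_e, gen_q)
    m <- match_eq(gen, gold, "relaxed")
    want <- if (all(gold$entity_ids %in% gen_e) &&
                all(gold$quality_ids %in% gen_q)) {
      "relaxed"
    } else if (length(intersect(gen_e, gold$entity_ids)) ||
               length(intersect(gen_q, gold$quality_ids))) {
      "partial"
    } else {
      "disjoint"
    }
    expect_identical(m$category, want)
    # exact implies relaxed, never the other way around for proper supersets
    if (match_eq(gen, gold, "exact")$category == "exact") {
      expect_identical(want, "relaxed")
    }
  }
  strict_superset <- eq_statement("MP:1", c("MA:1", "MA:2"), "PATO:1")
  expect_identical(match_eq(strict_superset, gold, "relaxed")$category,
                   "relaxed")
  expect_false(match_eq(strict_superset, gold, "exact")$category == "exact")
})

test_that("a fully correct corpus scores 100 percent exact", {
  gen <- list()
  gold <- list()
  for (i in 1:10) {
    id <- sprintf("MPX:%07d", i)
    gen[[id]] <- eq_statement(id, sprintf("MAX:%07d", i),
                              sprintf("PATX:%07d", i))
    gold[[i]] <- gold_eq(id, sprintf("MAX:%07d", i), sprintf("PATX:%07d", i))
  }
  rep <- evaluate_corpus(gen, gold)
  expect_identical(rep$counts[["exact"]], 10L)
  expect_identical(unname(rep$pct_of_selected[["exact"]]), 100)
  expect_identical(rep$n_transformed, 10L)
})

test_that("evaluate_corpus recovers a hand-planted category mix", {
  mk <- function(i, e, q) {
    eq_statement(sprintf("MPX:%07d", i), e, q)
  }
  gd <- function(i, e, q) gold_eq(sprintf("MPX:%07d", i), e, q)
  gen <- list()
  syn <- list()
  # 3 exact
  for (i in 1:3) gen[[sprintf("MPX:%07d", i)]] <- mk(i, "MAX:1", "PATX:1")
  # 2 synonym-only: label decomposition wrong, synonym candidate exact
  for (i in 4:5) {
    gen[[sprintf("MPX:%07d", i)]] <- mk(i, "MAX:2", "PATX:1")
    syn[[sprintf("MPX:%07d", i)]] <- list(mk(i, "MAX:1", "PATX:1"))
  }
  # 2 relaxed-only: one extra entity
  for (i in 6:7) {
    gen[[sprintf("MPX:%07d", i)]] <- mk(i, c("MAX:1", "MAX:9"), "PATX:1")
  }
  # 1 partial: shares only the quality
  gen[["MPX:0000008"]] <- mk(8, "MAX:7", "PATX:1")
  # 1 disjoint
  gen[["MPX:0000009"]] <- mk(9, "MAX:8", "PATX:8")
  # 1 not transformed (absent from the map)
  gold <- c(lapply(1:9, function(i) gd(i, "MAX:1", "PATX:1")),
            list(gd(10, "MAX:1", "PATX:1")))
  rep <- evaluate_corpus(gen, gold, synonyms_generated = syn)
  expect_identical(unname(rep$counts),
                   c(3L, 2L, 2L, 1L, 1L, 1L))
  expect_identical(sum(rep$counts), length(gold))
  # every phenotype lands in exactly one category
  expect_identical(sort(rep$results$phenotype_id),
                   sort(vapply(gold, `[[`, character(1), "phenotype_id")))
  # deterministic
  expect_identical(evaluate_corpus(gen, gold, synonyms_generated = syn),
                   rep)
})

test_that("tier counts are cumulative and monotone across fixture seeds", {
  for (seed in 0:4) {
    dir <- withr::local_tempdir()
    generate_fixture(fixture_spec(seed = seed, n_phenotypes = 30), dir)
    run <- run_fixture_pipeline(dir, use_synonyms = TRUE)
    counts <- run$report$counts
    cum <- cumsum(counts[c("exact", "exact_synonym", "relaxed")])
    expect_true(all(diff(cum) >= 0))
    expect_identical(sum(counts), length(run$fx$gold))
    # the synonym tier augments, never replaces, label-based exact matches
    no_syn <- evaluate_corpus(run$dec$statements, run$fx$gold)
    expect_identical(no_syn$counts[["exact"]], counts[["exact"]])
  }
})

test_that("sample_mismatches is seeded, bounded and restores the RNG", {
  gen <- list()
  gold <- list()
  for (i in 1:100) {
    id <- sprintf("MPX:%07d", i)
    gen[[id]] <- eq_statement(id, "MAX:900", "PATX:900")
    gold[[i]] <- gold_eq(id, sprintf("MAX:%07d", i), sprintf("PATX:%07d", i))
  }
  rep <- evaluate_corpus(gen, gold)
  expect_identical(rep$counts[["disjoint"]], 100L)
  s1 <- sample_mismatches(rep, 50, seed = 9)
  s2 <- sample_mismatches(rep, 50, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 50L)
  expect_false(identical(s1, sample_mismatches(rep, 50, seed = 10)))
  # n larger than the population returns everything
  expect_identical(nrow(sample_mismatches(rep, 500, seed = 1)), 100L)
  # no disjoint results -> empty sample
  rep0 <- evaluate_corpus(gen[1], gold[1])
  allgen <- evaluate_corpus(
    list("MPX:0000001" = eq_statement("MPX:0000001", "MAX:0000001",
                                      "PATX:0000001")),
    gold[1])
  expect_identical(nrow(sample_mismatches(allgen, 50, seed = 1)), 0L)
  # caller RNG state is untouched
  set.seed(123)
  before <- .Random.seed
  invisible(sample_mismatches(rep, 10, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("write_evaluation emits a commented summary and data rows", {
  dir <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 2, n_phenotypes = 20), dir)
  run <- run_fixture_pipeline(dir)
  f <- withr::local_tempfile()
  write_evaluation(run$report, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# selected_phenotypes\t20", lines)))
  tab <- read.delim(f, comment.char = "#", colClasses = "character")
  expect_identical(nrow(tab), 20L)
  expect_setequal(unique(tab$category),
                  names(run$report$counts[run$report$counts > 0]))
})
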