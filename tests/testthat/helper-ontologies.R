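# In-code builders for small ontologies used across the tests. Ids reuse
# real PATO/MA numbering for the worked examples; everything else uses
# synthetic prefixes.

make_ont <- function(ids, labels, synonyms = NULL, obsolete = NULL,
                     namespace = NULL) {
  ontology(lapply(seq_along(ids), function(i) {
    concept(ids[i], labels[i],
            synonyms = if (is.null(synonyms)) character(0) else synonyms[[i]],
            obsolete = if (is.null(obsolete)) FALSE else obsolete[i])
  }), namespace)
}

# quality ontology covering the worked examples: a composite quality and its
# components, the absent/lacks-all-parts pair, and the increased family
mini_pato <- function() {
  make_ont(
    ids = c("PATO:0001472", "PATO:0001997", "PATO:0001595", "PATO:0001233",
            "PATO:0000470", "PATO:0000912", "PATO:0000462", "PATO:0002000",
            "PATO:0002001", "PATO:0000584"),
    labels = c("decreased depth", "decreased", "depth", "dorsal",
               "increased", "increased rate", "absent",
               "lacks all parts of type", "has extra parts of type",
               "hypertrophied"),
    synonyms = c(rep(list(character(0)), 9), list("enlarged"))
  )
}

mini_ma <- function() {
  make_ont(
    ids = c("MA:0000232", "MA:0000312", "MA:0000248"),
    labels = c("dorsal root ganglion", "lumbar vertebra", "palate")
  )
}

mini_lexicons <- function(stop_words = default_stop_words(), stem = TRUE) {
  list(build_lexicon(mini_ma(), TRUE, stop_words, stem),
       build_lexicon(mini_pato(), TRUE, stop_words, stem))
}

# normalized component view of a cross-product map, for comparison with the
# brute-force oracle
cp_components <- function(cp) {
  lapply(cp[sort(names(cp))], function(x) x$component_ids)
}

# standard pipeline over a fixture directory
run_fixture_pipeline <- function(dir, use_synonyms = TRUE, stem = TRUE,
                                 rules = list()) {
  fx <- load_fixture(dir)
  sw <- default_stop_words()
  lex <- list(build_lexicon(fx$anatomy, TRUE, sw, stem),
              build_lexicon(fx$process, TRUE, sw, stem),
              build_lexicon(fx$quality, TRUE, sw, stem))
  cp <- derive_cross_products(fx$quality, sw, stem = stem)
  dec <- decompose_ontology(fx$phenotypes, lex, cp, rules,
                            use_synonyms = use_synonyms, stop_words = sw,
                            stem = stem)
  list(fx = fx, dec = dec, report = evaluate_corpus(dec, fx$gold))
}
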