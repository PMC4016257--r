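Package: eqcompose
Title: Decompose Pre-Composed Phenotype Labels into Entity-Quality Statements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatically decomposes pre-composed phenotype ontology concept
    labels (MP/HPO-style) into post-composed Entity-Quality (EQ) statements.
    Concept labels and synonyms are normalized (special-character filtering,
    stop-word removal, Porter stemming), matched against dictionary lexicons
    built from anatomy, process and quality ontologies, filtered for span
    containment, and composite quality concepts are recovered through
    stem-subset cross products. Quality replacement rules (unconditional and
    conditional) rewrite qualities to curator conventions. An evaluation
    harness grades generated statements against manually curated gold EQ
    statements in exact, synonym-augmented and relaxed tiers, and a
    deterministic fixture generator builds toy corpora with planted match
    categories for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
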