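---
title: "Decomposing pre-composed phenotype labels into Entity-Quality statements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing pre-composed phenotype labels into Entity-Quality statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqcompose)
```

## The problem

Species-specific phenotype ontologies (the Mammalian Phenotype Ontology,
the Human Phenotype Ontology, and their relatives) are *pre-composed*:
each phenotype is a single named concept such as *decreased body weight*.
Cross-species integration instead uses *post-composed* Entity-Quality (EQ)
statements, where a phenotype is an **entity** — an anatomical structure
(MA/FMA) or a biological process (GO) — described by a **quality** (PATO),
e.g. entity *body* plus quality *decreased weight*. Curated EQ statements
exist for only part of these ontologies, are expensive to maintain, and
drift as the ontologies evolve.

`eqcompose` implements a purely lexical decomposition pipeline that proposes
EQ statements directly from concept labels, plus an evaluation harness that
grades proposals against curated gold statements. The intended user is a
curator or ontology engineer who wants candidate EQ statements and a
transparent, reproducible account of where the automation agrees and
disagrees with manual curation. The method is deliberately restricted to
*structure and process* phenotypes — those whose gold statement uses only
anatomy or process entities plus qualities — because purely lexical matching
has no purchase on the remaining phenotype classes.

## The pipeline

For each phenotype label (and optionally each of its synonyms):

1. **Character filtering.** Every character outside `[a-zA-Z0-9]` becomes a
   space; the result is lowercased. A closed rule was preferred over an open
   list of punctuation because it removes an entire error class (differently
   hyphenated or percent-marked labels) at once. Numerals survive: labels
   like *epiphysis of the 4th finger* need them.
2. **Stop-word removal.** Tokens found in the stop-word list are dropped.
   The bundled default list (`the of in a an to and or with for on by`) is
   deliberately small and pinned — matching results are sensitive to this
   list, so reproducibility demands a fixed default; a custom file can be
   supplied (`read_stop_words()`).
3. **Porter stemming.** Each token is stemmed with the classic Porter
   algorithm, implemented in the package (`porter_stem()`). Stemming is what
   collapses *abnormality*/*abnormalities* and most plural/singular pairs;
   it is applied identically to dictionary terms and to phenotype labels, so
   matching is always stem-to-stem. Stemming can be disabled
   (`stem = FALSE`) to measure its contribution.
4. **Dictionary annotation.** One lexicon per ontology maps each normalized
   term (label, and synonyms when enabled) to its concept ids. Every
   contiguous stem subsequence of the label is looked up in every lexicon;
   spans are token-indexed, 0-based, half-open. Ambiguous phrases produce
   one annotation per mapped concept, all retained — downstream curation,
   not the annotator, resolves ambiguity.
5. **Containment filtering.** An annotation is discarded when another
   annotation's span contains it strictly (`filter_contained()`). This stops
   *dorsal* (a quality) from leaking out of *dorsal root ganglion* (an
   anatomy term). Filtering is applied uniformly to every namespace,
   including the process lexicon: restricting it to particular ontologies is
   an implementation accident of annotation-server architectures, not part
   of the method.
6. **Cross-product combination.** Composite qualities such as *decreased
   depth* are registered by `derive_cross_products()`: B is a component of A
   when the stem set of one of B's terms is a non-empty subset of the stem
   set of one of A's terms. At annotation time, a group of quality
   annotations whose stem sets exactly cover a whole's stem set — no stem
   missing, none left over — is replaced by a single annotation for the
   whole, so *decreased* + *depth* on *decreased palatal depth* becomes one
   *decreased depth* annotation spanning the phrase.
7. **Statement assembly and replacement rules.** Surviving annotations are
   split by source namespace into entities and qualities
   (`compose_eq()`); a phenotype with no annotations at all counts as *not
   transformed*. Replacement rules then rewrite qualities to curator
   conventions (`apply_replacements()`).

```{r example}
lexicons <- list(
  build_lexicon(ontology(list(
    concept("MA:0000232", "dorsal root ganglion")))),
  build_lexicon(ontology(list(
    concept("PATO:0001233", "dorsal"),
    concept("PATO:0000584", "hypertrophied", synonyms = "enlarged")))))
nt <- normalize_label("enlarged dorsal root ganglion")
filter_contained(annotate(nt, lexicons, "MP:0008490"))
```

## Design choices that were genuinely open

**Exact cover at combination time.** The cross-product registry records
*every* stem-subset component, but combination demands an exact cover of the
whole's stem set by the annotations it consumes. Requiring only a partial
cover would let a lone *decreased* annotation generalize into *decreased
depth*, inventing information the label does not carry. The registry/cover
split keeps the registry faithful to the subset definition while the
combiner stays conservative.

**Greedy largest-whole-first combination.** When wholes of different sizes
compete for the same components, the largest exactly-covered whole wins and
consumes its components; equally sized wholes that are each exactly covered
are all emitted as alternative annotations (ambiguity is retained for the
curator, mirroring the annotator's behaviour). Ties are ordered by concept
id for determinism.

**Replacement rules.** The bundled unconditional rule rewrites *absent*
(PATO:0000462) to *lacks all parts of type* (PATO:0002000), the curated
convention. A second, optional rule set is conditional on the label: a label
containing the phrase *increased activity* has its *increased* quality
(PATO:0000470) rewritten to *increased rate* (PATO:0000912), and a label
matching *increased … number* to *has extra parts of type* (PATO:0002001).
Patterns are token sequences with at most one `*` gap wildcard; the gap
stands for **one or more** tokens (a zero-width gap would make *increased
number* and *increased … number* indistinguishable), and matching runs on
stems so plural variants of pattern words still fire. The mirrored
*decreased* patterns ship trigger-only — no curated target ids are bundled
for them — and stay inert until the user supplies a replacement id. Rules
apply in file order; rule files are validated against the quality ontology
at load time (ids from a different quality namespace are left unchecked,
since they can never fire on that corpus).

**Synonym handling.** Ontology-term synonyms are first-class dictionary
entries regardless of their scope tag (EXACT/BROAD/...); the scope
distinction buys little for matching and costs a configuration surface.
Phenotype-concept synonyms are decomposed separately when
`use_synonyms = TRUE`; all synonym-derived candidate statements are kept
alongside the label-based one, and the evaluation decides which tier they
satisfy. The synonym tier *augments* the exact tier — a label-based exact
match never degrades because a synonym disagrees.

**Gold files.** Two dialects are accepted: a simple TSV
(`phenotype_id`, pipe-separated `entity_ids`, `quality_ids`) and OBO
logical-definition stanzas (`intersection_of:` genus for the quality,
`intersection_of: inheres_in <id>` for entities), since historical EQ
corpora were distributed as logical definitions. Duplicate rows for one
phenotype merge by set union — matching is set-based per phenotype, so this
is the only merge consistent with the comparison. Quality-only gold
statements are legal but flagged with a warning.

## Evaluation tiers

Every selected phenotype lands in exactly one category:

| category | meaning |
|---|---|
| `exact` | label-based statement equals gold (entities and qualities as sets) |
| `exact_synonym` | not exact, but some synonym-derived candidate is |
| `relaxed` | gold entities ⊆ generated and gold qualities ⊆ generated |
| `partial` | some entity or quality shared, but relaxed fails |
| `disjoint` | a statement exists but shares nothing with gold |
| `not_transformed` | no annotation found on label or synonyms |

The relaxed tier reflects curation practice: extra assigned concepts are
cheap for a curator to strike out, whereas missing ones require research.
Headline percentages are reported over **two denominators** — all selected
phenotypes and transformed phenotypes only — because the two are easily
conflated and differ substantially; `write_evaluation()` labels both.
`sample_mismatches()` draws a seeded uniform sample of disjoint cases for
the manual audit step, without disturbing the caller's RNG.

## The synthetic corpus generator

No real ontology content ships with the package; `generate_fixture()`
builds toy corpora whose ids use synthetic prefixes (`MAX`, `GOX`, `PATX`,
`MPX`). The generator emulates the lexical phenomena the method must
survive: labels composed as quality-phrase + entity-phrase, synonyms,
multi-word anatomy terms that lexically embed a quality term (the *dorsal
root ganglion* situation), composite qualities whose label concatenates
their components (guaranteeing the stem-subset property), plural-suffix
divergence between phenotype and anatomy vocabularies, contracted anatomy
terms, shared synonyms, and the same label existing in two ontologies.
Evaluation categories are *planted*: each phenotype is constructed so the
pipeline, run with synonyms enabled and noise flags off, must place it in
its planted category — which is what the end-to-end tests assert.

The vocabulary is pronounceable CVCCVC nonsense, drawn deterministically
from the spec's seed and filtered so that no word is a stop word, no word
ends in *s* (plural noise must stay reversible), stems are pairwise
distinct, and every word's stem is a fixed point of the stemmer. The last
filter matters: the classic Porter algorithm is *not* idempotent on general
English (*decrease* → *decreas* → *decrea*), and the pipeline therefore
stems every token exactly once; restricting the fixture vocabulary to
fixed-point words keeps re-normalization properties testable without
misrepresenting the stemmer.

What the generator does **not** emulate: real ontology scale and term-length
distributions, is_a graph structure (the method never reads it),
abbreviations and naming-convention clashes (*2nd finger* vs *index
finger*), and genuinely irregular plurals (*phalanx*/*phalanges*) beyond
recording that stemming does not resolve them. Passing the planted-recovery
tests therefore demonstrates mechanical correctness of the pipeline, not
the match rates to expect on real MP or HPO corpora — those depend on the
ontology versions and the curated gold set in use.

## Numerical and procedural choices

- Stem comparison uses **sets** (duplicates collapsed), the simplest
  faithful reading of subset-of-stemmed-words; annotation spans use token
  indices so containment stays well-defined after stop-word removal.
- Tests and the acceptance script run corpora of 200 phenotypes with
  ontologies of tens of concepts, and property checks over seeds 0–9;
  the pipeline is linear in corpus size, and these sizes already exercise
  every code path (all planted categories, all noise flags, all rule
  kinds).
- Degenerate inputs are defined, not errors: empty ontologies produce empty
  lexicons and header-only exports; labels normalizing to nothing are
  counted as not transformed; dictionary terms normalizing to nothing are
  skipped with a warning.
- All randomness (fixture vocabulary, plural-suffix choice, mismatch
  sampling) flows from explicit seeds, and the helpers save and restore the
  caller's RNG state, so identical configs give byte-identical outputs.

## Known limitations

- Purely lexical: no fuzzy matching, no learned recognizer, no use of the
  ontology graph. Terms absent from the dictionaries are invisible.
- Relational qualities with a second entity (E-Q-E2, *towards* relations)
  are out of scope, as are ontology-specific rewrite families (e.g.
  *irregular* → *irregular density* for HPO).
- The stop-word list and stemmer variant materially affect match rates;
  both are pinned and configurable, but results are only comparable across
  runs that share them.
- Cross-namespace duplicate concepts (the same term in two entity
  ontologies) are annotated in both and surfaced as duplication warnings
  rather than resolved.
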