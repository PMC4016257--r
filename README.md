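# eqcompose

Automated decomposition of **pre-composed phenotype ontology labels** into
**post-composed Entity–Quality (EQ) statements**, with an evaluation harness
against curated gold statements.

Phenotype ontologies such as MP and HPO name each phenotype as a single
concept (*decreased body weight*). Cross-species phenomics instead wants the
compositional form E+Q: an **entity** — an anatomical structure (MA/FMA) or
biological process (GO) — qualified by a PATO **quality** (entity *body*,
quality *decreased weight*). `eqcompose` proposes such statements purely
lexically:

1. normalize labels and dictionary terms — special characters → spaces,
   stop-word removal, Porter stemming (`normalize_label()`);
2. recognize entity and quality mentions with per-ontology dictionary
   lexicons over stemmed token subsequences (`build_lexicon()`,
   `annotate()`);
3. drop annotations whose span is strictly contained in a longer one, so
   *dorsal* does not escape *dorsal root ganglion* (`filter_contained()`);
4. recover composite qualities via stem-subset **cross products**: quality
   B is a component of quality A when the stem set of one of B's terms is a
   subset of one of A's (`derive_cross_products()`); annotation groups that
   exactly cover a whole's stem set are merged into the whole
   (`combine_annotations()`);
5. assemble the EQ statement and apply quality replacement rules —
   unconditionally (*absent* PATO:0000462 → *lacks all parts of type*
   PATO:0002000) or conditioned on label patterns such as
   `increased * number` → *has extra parts of type* PATO:0002001
   (`compose_eq()`, `apply_replacements()`);
6. grade generated against gold statements in cumulative tiers — exact,
   exact-via-phenotype-synonym, relaxed (gold ⊆ generated) — plus partial /
   disjoint / not-transformed, with percentages over both sensible
   denominators (`evaluate_corpus()`).

A deterministic fixture generator (`generate_fixture()`) builds synthetic
corpora with planted evaluation categories and realistic lexical noise
(plural suffixes, contractions, shared synonyms, cross-ontology duplicate
terms), so the entire pipeline is testable without downloading any ontology.

## Worked example

```r
library(eqcompose)

lexicons <- list(
  build_lexicon(ontology(list(concept("MA:0000232", "dorsal root ganglion")))),
  build_lexicon(ontology(list(
    concept("PATO:0001233", "dorsal"),
    concept("PATO:0000584", "hypertrophied", synonyms = "enlarged")))))

nt <- normalize_label("enlarged dorsal root ganglion")
ann <- filter_contained(annotate(nt, lexicons, "MP:0008490"))
ann
#>   phenotype_id start end   concept_id namespace  origin
#> 1   MP:0008490     0   1 PATO:0000584      PATO synonym
#> 2   MP:0008490     1   4   MA:0000232        MA   label

compose_eq(concept("MP:0008490", "enlarged dorsal root ganglion"), ann, "PATO")
#> <eq_statement> MP:0008490 (generated/label)
#>   E: MA:0000232
#>   Q: PATO:0000584
```

The quality *dorsal*, lexically embedded in the anatomy term, was annotated
and then removed by containment filtering; *enlarged* matched through a
synonym and remains as the quality. On a full synthetic corpus:

```r
dir <- tempfile()
generate_fixture(fixture_spec(seed = 1), dir)
fx <- load_fixture(dir)
sw <- default_stop_words()
lexicons <- list(build_lexicon(fx$anatomy, TRUE, sw),
                 build_lexicon(fx$process, TRUE, sw),
                 build_lexicon(fx$quality, TRUE, sw))
cp <- derive_cross_products(fx$quality, sw)
dec <- decompose_ontology(fx$phenotypes, lexicons, cp,
                          rules = default_rules(), use_synonyms = TRUE)
evaluate_corpus(dec, fx$gold)
#> <eq_evaluation> 50 selected phenotypes, 45 transformed
#>   exact              21  ( 42.0% of selected)
#>   exact_synonym       7  ( 14.0% of selected)
#>   relaxed             7  ( 14.0% of selected)
#>   partial             6  ( 12.0% of selected)
#>   disjoint            4  (  8.0% of selected)
#>   not_transformed     5  ( 10.0% of selected)
#>   cumulative exact / +synonym / +relaxed: 21 / 28 / 35
```

The counts equal the fixture's planted category mix: the pipeline recovers
exactly what the corpus was built to contain. Real ontologies are consumed
the same way — point `parse_obo()` / `parse_tbl()` at MP/HPO, MA/FMA, GO
and PATO files and `parse_gold_eq()` at a curated EQ file (TSV or OBO
logical definitions), then restrict to structure/process phenotypes with
`select_structure_process()`.

## Command line

A thin front-end wraps the same functions:

```sh
Rscript inst/cli/eqcompose.R fixtures      --out_dir corpus --seed 4
Rscript inst/cli/eqcompose.R crossproducts --quality corpus/quality.obo --out_dir out
Rscript inst/cli/eqcompose.R decompose     --config run.yml
Rscript inst/cli/eqcompose.R evaluate      --config run.yml --use_synonyms true
```

Outputs are plain TSV (`crossproducts.tsv`, `generated_eq.tsv`,
`evaluation.tsv` with a commented summary block, `mismatch_sample.tsv`) and
are byte-identical across reruns with the same config and seed.

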