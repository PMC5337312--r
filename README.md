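# kgchains

Typed medical knowledge graphs from text: bootstrapped pattern-based
relation extraction, forward/backward chain inference, and contextual
pruning of meaningless inference chains — with a synthetic corpus
generator that makes the whole pipeline testable end to end, offline.

The package is tidyverse-native: tabular data (entities, relations,
patterns, chains, fold reports) are tibbles, models and reports have
`broom`-style `tidy()`/`glance()` methods and `ggplot2::autoplot()`
methods, and errors are classed `rlang` conditions under
`kgchains_error`.

## The model

* **Knowledge graph** (`kg_new()`, `kg_add_entities()`,
  `kg_add_relations()`): entities carry one of four concept classes
  (`BODILY_PART`, `SYMPTOM`, `DISEASE`, `TREATMENT`); relations are one
  of three typed schemas — `LOCATED_IN` (SYMPTOM→BODILY_PART), `CAUSE`
  (SYMPTOM→DISEASE), `CORRESPONDED_TO` (DISEASE→TREATMENT) — with
  domain/range validation, per-relation confidence, and sentence-level
  provenance. Export/import as RDF N-Triples
  (`kg_export_ntriples()` / `kg_import_ntriples()`).
* **Corpus** (`med_corpus()`): flat tibbles of tokens, dependency
  edges (validated as trees), and entity mentions. Dictionary
  recognition with greedy longest match (`recognize_entities()`),
  shortest dependency path between mentions (`shortest_dep_path()`).
* **Extraction** (`gather_patterns()`, `score_patterns()`,
  `harvest()`): lexicalized shortest-path patterns between typed
  mention pairs, confidence = seed hits / entity pairs, iterative
  bootstrapping, then a greedy weighted `consistency_filter()` and
  `sample_for_verification()`. Curated corrections are applied with
  `apply_fact_overrides()`.
* **Inference** (`enumerate_chains()`, `backward_chains()`):
  all simple entity paths following a schema path such as the default
  `LOCATED_IN⁻¹ · CAUSE · CORRESPONDED_TO` (bodily part → symptom →
  disease → treatment). `junction_fanout()` measures branching.
* **Pruning** (`train_pruner()`, `evaluate_pruning()`,
  `prune_chains()`): each chain is featurized from the *N contextual
  sentences* around every supporting sentence (a clipped window of up
  to 2N+1 sentences) as per-step document-term blocks plus entity-name
  blocks. Four classifiers (elastic-net logistic regression,
  multinomial naive Bayes, linear SVM, decision tree), stratified
  k-fold cross-validation, and a retain/discard partition.
* **Synthetic data** (`generate_bundle()`, `audit_bundle()`): a
  seeded generator producing a ground-truth graph, a supporting corpus
  with controllable contextual co-mention signal (`p_signal` for
  meaningful chains, `p_noise` for meaningless ones), seed facts, and a
  balanced labeled study set of 3-relation chains.

## Worked example

```r
library(kgchains)

kg <- kg_demo_graph()
kg
#> <med_kg> 6 entities, 5 relations
#>   entities: BODILY_PART=3, DISEASE=1, SYMPTOM=1, TREATMENT=1
#>   relations: CAUSE=1, CORRESPONDED_TO=1, LOCATED_IN=3

ch <- enumerate_chains(kg, "lung", default_schema_path())
ch$steps[[1]]
#> # A tibble: 3 × 5
#>   schema          traversal subject      object      provenance
#>   <chr>           <chr>     <chr>        <chr>       <list>
#> 1 LOCATED_IN      inverse   inflammation lung        <tibble [0 × 2]>
#> 2 CAUSE           forward   inflammation pneumonia   <tibble [0 × 2]>
#> 3 CORRESPONDED_TO forward   pneumonia    treatment_x <tibble [0 × 2]>
```

Generate the default study bundle (200 labeled chains, 100 meaningful /
100 meaningless), audit its planted signal, and cross-validate the
pruner:

```r
bundle <- generate_bundle(generator_config(seed = 1))
audit_bundle(bundle)
#> # A tibble: 2 × 5
#>   label         rate     n expected  sigma
#>   <chr>        <dbl> <int>    <dbl>  <dbl>
#> 1 meaningful  0.947    300     0.95 0.0126
#> 2 meaningless 0.0633   300     0.05 0.0126

ev <- evaluate_pruning(bundle$chains, bundle$corpus,
                       pruning_config(seed = 1))
glance(ev)
#> # A tibble: 1 × 6
#>   classifier          precision recall baseline_precision cv_folds     n
#>   <chr>                   <dbl>  <dbl>              <dbl>    <int> <int>
#> 1 logistic_regression     0.989   0.94                0.5        5   200

tidy(ev)
#> # A tibble: 5 × 7
#>    fold    tp    fp    tn    fn precision recall
#>   <int> <int> <int> <int> <int>     <dbl>  <dbl>
#> 1     1    16     0    20     4     1        0.8
#> 2     2    20     0    20     0     1        1
#> 3     3    20     1    19     0     0.952    1
#> 4     4    18     0    20     2     1        0.9
#> 5     5    20     0    20     0     1        1
```

`autoplot(ev)` plots per-fold precision/recall against the accept-all
baseline; `autoplot(model)` plots the strongest term coefficients;
`autoplot(kg)` summarizes the graph.

## Command-line pipeline

`exec/kgchains` drives the six stages over a shared output directory;
every stage is seeded and writes deterministic artifacts.

```text
$ kgchains generate --seed 1 --out-dir run
[generate] entities=414 relations=995 sentences=6979 chains=200 secs=17.2
$ kgchains extract --seed 1 --out-dir run
[extract] candidates=995 retained=995 secs=3.0
$ kgchains infer --seed 1 --out-dir run
[infer] starts=9 chains=16977 secs=78.8
$ kgchains evaluate --seed 1 --out-dir run
[evaluate] classifier=logistic_regression precision=0.9895 recall=0.94
           baseline_precision=0.5 secs=3.9
$ kgchains prune --seed 1 --out-dir run
[prune] retained=5964 discarded=11013
$ kgchains export --seed 1 --out-dir run
[export] triples=1409
```

Options: `--config FILE` (YAML/JSON), `--classifier nb|lr|svm|dt`,
`--context-range N`, `--folds K`, `--confidence-threshold T`,
`--iterations I`, `--overrides FILE` (curated add/remove fact TSV).
Exit codes: 0 success, 2 missing input artifact, 3 invariant violation,
1 usage or other error.

## Testing

```sh
R CMD INSTALL --no-docs .
Rscript -e 'testthat::test_dir("tests/testthat", package = "kgchains",
                               load_package = "installed")'
```

The suite includes property tests against independent oracles (BFS
path search, brute-force chain enumeration, exhaustive consistency
optimum) and an acceptance file with one block per acceptance
criterion. See `vignettes/methods.Rmd` for the design rationale.
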