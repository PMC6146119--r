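# autolit

Literature mining of autophagy–disease associations and positive-unlabeled
gene prioritization, as a tidyverse-native R package.

Curated biomedical literature can tell us which human diseases a cellular
process such as autophagy is entangled with, and which genes mediate that
entanglement — but the raw material is a pile of papers, a redundant disease
vocabulary, and a short list of experimentally confirmed genes. `autolit`
provides the analysis layer for this setting:

- **Lexicon and scanning** — merge a raw `(name, class)` disease vocabulary
  into a non-redundant lexicon with synonym tracking
  (`merge_lexicon()`), scan documents for disease mentions with
  word-boundary, longest-match-first dictionary matching
  (`scan_documents()`), and tally the per-class funnel
  (`filter_hit_documents()`, `tally_classes()`).
- **Class composition statistics** — for class *i* with *n<sub>i</sub>*
  lexicon diseases and *m<sub>i</sub>* of them hit in the corpus, the
  concentration ratio CR<sub>i</sub> = (m<sub>i</sub>/Σm) / (n<sub>i</sub>/Σn)
  (CR > 1: the class concentrates in the process-specific literature) and
  retention ratio RR<sub>i</sub> = m<sub>i</sub>/n<sub>i</sub> ∈ [0, 1]
  (`class_ratios()`, `rate_table()`).
- **Co-mention association** — the cumulative hypergeometric upper tail
  P(X ≥ n) for documents mentioning two disease classes, computed in log
  space (`hypergeom_upper_tail()`), in both the literal parameterization of
  the source analysis and the standard two-by-two form
  (`pairwise_association()`), with module extraction as connected components
  of the α-thresholded significance graph (`extract_modules()`).
- **ORFL gene scoring** — positive-unlabeled learning by bagged negative
  resampling: repeatedly sample pseudo-negatives from the unlabeled genes,
  fit a random forest against the known positives, and score each unlabeled
  gene by its frequency of positive calls over the iterations in which it
  was not a training point (`orfl_fit_score()`, `score_distribution()`,
  `threshold_groups()`).
- **Function-consistency validation** — Lin semantic similarity
  2·IC(MICA)/(IC(t₁)+IC(t₂)) over a minimal is-a ontology with explicit
  annotation propagation and information content IC(t) = −ln p(t)
  (`compute_ic()`, `lin_term_similarity()`, `gene_similarity()`), and
  group-versus-reference consistency summaries with a recomputed background
  (`group_consistency()`).
- **Synthetic data and pipeline** — seeded generators for corpora with
  planted co-mention structure, feature matrices with planted positive-set
  signal, and toy ontologies (`generate_corpus()`, `generate_features()`,
  `generate_toy_ontology()`); packaged count/gene-list fixtures
  (`load_fixture()`); an end-to-end runner with per-stage seeds, checksums
  and a JSON run report (`run_pipeline()`, `make_demo()`).

Results are tibbles that chain with the pipe; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

Which disease classes concentrate in the autophagy literature? The package
ships the curated per-class count table (22 classes; 6215-name vocabulary,
2557 merged diseases, 378 hit in autophagy papers):

```r
library(autolit)
library(dplyr)

t1 <- load_fixture("table1_counts")
ratios <- class_ratios(data.frame(class = t1$class,
                                  lexicon_count = t1$filtered_count,
                                  paper_count = t1$ad_count))
ratios |> select(class, lexicon_count, paper_count, cr, rr) |> arrange(desc(cr))
#> # A tibble: 22 × 5
#>   class              lexicon_count paper_count    cr    rr
#>   <chr>                      <int>       <int> <dbl> <dbl>
#> 1 Respiratory                   21           9  2.90 0.429
#> 2 Cancer                       159          65  2.77 0.409
#> 3 Urogenital disease             5           2  2.71 0.4
#> 4 Digestive system              40          14  2.37 0.35
#> 5 Muscular                      74          21  1.92 0.284
#> # ℹ 17 more rows
```

Respiratory disease, cancer, urogenital and digestive-system disease lead:
each holds a 2–3× larger share of the diseases found in autophagy papers
than of the lexicon (CR), and retains 35–43% of its lexicon diseases (RR),
against a global retention rate of 378/2557 ≈ 15%. `autoplot(ratios)` draws
both panels.

A full synthetic run — corpus with a planted co-mention module, PU scoring
against the packaged 61-gene positive set, ontology validation:

```r
dir <- tempfile()
cfg <- read_pipeline_config(make_demo(dir, seed = 7))
report <- run_pipeline(cfg)
report$stages$filter[c("n_documents_retained", "n_distinct_diseases_hit")]
#> $n_documents_retained
#> [1] 2000
#> $n_distinct_diseases_hit
#> [1] 176
```

with per-stage outputs (scan, counts, ratios, pair p-values, modules,
scores, consistency summaries) under `cfg$out_dir`.

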