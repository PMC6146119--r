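---
title: "From disease lexicon to gene scores: methods behind autolit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From disease lexicon to gene scores: methods behind autolit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autolit)
```

`autolit` implements a literature-driven pipeline for studying how a
biological process — autophagy, in the motivating application — relates to
human disease: a disease lexicon is matched against a document corpus,
class-composition statistics quantify which disease classes concentrate in
the process-specific literature, a cumulative hypergeometric test finds
disease-class pairs that are co-mentioned in excess of chance, a
positive-unlabeled (PU) random-forest procedure scores genes for membership
in a curated positive set, and information-content semantic similarity over
an ontology checks whether high-scoring genes are functionally consistent
with the known positives. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the procedure left genuine freedom.

## Lexicon merging and dictionary scanning

The lexicon is a set of diseases, each with one canonical name, a synonym
set, and one of 22 disease-class labels. Published disease vocabularies are
redundant (the packaged class-count table documents a 6215-name vocabulary
collapsing to 2557 diseases), but no published merge criterion exists, so
`merge_lexicon()` uses the simplest reproducible rule: names are case-folded,
possessive "'s" dropped, punctuation replaced by spaces and whitespace
collapsed, and names identical after normalization are merged. Everything
this rule cannot catch goes through an explicit synonym table, which also
arbitrates the one hard failure mode — a single normalized name recorded
under two classes. We make no claim that this rule reproduces the original
6215-to-2557 collapse from raw vocabulary input; the packaged counts are an
input fixture, not a target of the merge rule.

`scan_documents()` matches canonical names and synonyms case-insensitively
at word boundaries on normalized text, longest term first, suppressing
shorter terms nested inside an accepted match — "breast cancer" therefore
contributes one mention, not an additional "cancer". Documents with no hits
are kept by the scanner and removed only by `filter_hit_documents()`, so the
document funnel (papers in, papers with hits, distinct diseases hit) is
observable at each step. Gene-name recognition is deliberately not
implemented: corpora can carry pre-extracted gene lists in the scan dialect,
matching how an external named-entity recognizer would be used upstream.

## Concentration and retention ratios

With $n_i$ diseases of class $i$ in the lexicon and $m_i$ of them hit in the
corpus, the two composition statistics are

$$\mathrm{CR}_i = \frac{m_i/\sum_j m_j}{n_i/\sum_j n_j}, \qquad
  \mathrm{RR}_i = \frac{m_i}{n_i}.$$

CR compares a class's share of the hit diseases with its share of the
lexicon; 1 is the neutral value and CR > 1 means the class is
over-represented in the process-specific literature. RR is the within-class
survival fraction, bounded in $[0,1]$. Two algebraic identities make useful
self-checks and are asserted on random tables in the test suite: the
lexicon-share-weighted mean of CR is exactly 1, and CR$_i > 1$ holds exactly
when RR$_i$ exceeds the global retention rate $\sum m / \sum n$. Ratios for
classes with $n_i = 0$ are reported as explicitly undefined (`NA`), never as
zero, because "no lexicon entries" and "nothing retained" are different
statements. Printed rate tables round half-up to two decimals
(`round_half_up()`); base R's round-half-even would disagree on exact ties.
Both statistics operate on any counts table whose rows are the unit of
interest, so per-disease rather than per-class ratios need no separate mode.

## Co-mention association and modules

For disease classes $a$ and $b$, let $M$ documents mention $a$, $n$ mention
both, and $N$ mention $a$ or $b$. The association statistic is the
cumulative hypergeometric upper tail

$$P \;=\; 1-\sum_{i=0}^{n-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}
  \;=\; P(X \ge n),$$

computed in log space (log-gamma binomial coefficients, direct upper-tail
summation) so corpus-scale counts neither overflow nor lose accuracy at
small $p$. This *literal* parameterization draws $n$ items from the
$a$-or-$b$ documents with the $a$-documents marked; it is unusual — the draw
size equals the observed overlap and the model is asymmetric in $(a,b)$.
Because the asymmetry cannot be resolved from first principles, the package
implements it exactly as stated (reporting both directions and their
conservative maximum) *and* provides the standard two-by-two alternative
(`parameterization = "universe"`: $N$ = all documents, draw size = documents
about $b$), which is symmetric and has controlled type-I error. The literal
form is the default for fidelity; the universe form is what the calibration
property tests use and what we recommend for new analyses. No
multiple-testing correction is applied by default across the 231 class
pairs, matching the original analysis; Benjamini–Hochberg is available
behind a flag.

Modules are connected components, with at least two members, of the graph
whose edges are pairs with $p < \alpha$. The original figure says only
"after clustering", so the package also emits an average-linkage ordering of
the significance matrix for heatmap display, while membership is defined by
the components; the choice is recorded in the result metadata.

## Positive-unlabeled gene scoring

The gene scorer addresses the standard PU setting: a small curated positive
set (61 genes in the motivating study), no curated negatives, and a large
unlabeled pool described by numeric features (histone-modification and
TFBS-derived signals in the original data). Each iteration draws a
pseudo-negative sample uniformly from the unlabeled genes — balanced to the
positive-set size by default, the conventional PU-bagging choice since the
original description leaves the size unstated — fits a probability random
forest (100 trees, $\sqrt{p}$ features per split), and classifies every
unlabeled gene *outside* the iteration's negative sample. A gene's
*possibility score* is the fraction of its eligible iterations that called
it positive (forest vote fraction at or above `vote_threshold`, default
majority). Excluding an iteration's own training negatives from scoring
avoids resubstitution bias; their denominator counts only eligible
iterations. Known positives define the labels and receive no score.

Defaults follow the original scale where stated — `n_iterations` defaults to
100 000 — while tests, examples and the acceptance analyses run at 500–2000
iterations: a score is a binomial frequency, so its standard error at $B$
iterations is at most $1/(2\sqrt{B})$, about 0.016 at $B = 1000$, ample for
rank-based evaluation. The headline property is parameter recovery on
synthetic data: with 1000 genes, 60 positives of which 20 are hidden among
the unlabeled, 10 of 50 features shifted by 2 SD in positives, and 1000
iterations, hidden positives are ranked above background with AUC well above
0.9, while a zero-effect design stays at chance. Score analysis mirrors the
original displays: `score_distribution()` histograms `[0,1]` and the refined
`[0.9,1]` window and reports local maxima; `threshold_groups()` partitions
genes into left-closed intervals with a closed top group, so the default
cutpoints (0.999, 0.9997, 1) give `[0.999,0.9997)`, `[0.9997,1)` and `{1}`,
and a score of exactly 0.9997 falls in the middle group.

## Function-consistency via Lin similarity

Annotations are propagated to ancestors explicitly (`propagate_annotations()`,
the true-path rule), then each term's information content is
$\mathrm{IC}(t) = -\ln(g_t/g_{\mathrm{root}})$ with $g_t$ the number of genes
annotated to $t$. Term similarity is Lin's measure,
$2\,\mathrm{IC}(\mathrm{MICA})/(\mathrm{IC}(t_1)+\mathrm{IC}(t_2))$, where
the MICA is the common ancestor (reflexively including the terms) with
maximal IC; the value is 0 by convention when both terms carry no
information. Gene-level similarity combines term similarities by the
symmetric best-match average — the most common default, since the original
analysis names only a software package and not a combination rule —
with `funSimMax` available behind a flag; the choice is recorded in result
metadata. Zero-annotation terms have undefined IC and are excluded from
MICA candidacy rather than assigned infinite IC. Only single-namespace,
single-root DAGs are accepted; multi-namespace inputs must be pre-split.

The IC corpus is always the supplied annotation set itself, never an
external ontology release, so results are self-contained and reproducible.
Consequently `group_consistency()` recomputes its background value — the
mean similarity of random annotated-gene pairs, with a bootstrap CI — on
the annotation universe in use. A background constant from any particular
ontology release (such as the 0.3861 reported in the motivating study)
is specific to that release and is not comparable across corpora, which is
why the package never hard-codes one.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage can be tested end to end with known
ground truth:

- `generate_corpus()` draws per-document mention counts from a
  zero-truncated Poisson (`mentions_per_doc` is the pre-truncation rate,
  default 2.5 — a realistic handful of disease mentions for an abstract, and
  truncation reflects a corpus pre-filtered to disease-mentioning papers),
  assigns each mention's class from normalized weights and the disease
  uniformly within class. A co-mention boost $b$ for a class pair forces
  both classes into a document with probability $(b-1)\,p_{\mathrm{joint}}$,
  making the pair's joint frequency about $b$ times its independence
  baseline while leaving marginals approximately intact.
- `generate_features()` plants `n_informative` Gaussian features shifted by
  `effect_size` SD in a random positive set (a Bernoulli mode exists behind
  a flag; forests are insensitive to the distinction, and the Gaussian form
  gives effect size a clean meaning).
- `generate_toy_ontology()` builds a perfect is-a tree and annotates genes
  to random leaves, giving closed-form IC values for similarity tests.

One calibration property deserves note. Under the zero-truncated-Poisson
corpus model, two classes' presence indicators are mildly *negatively*
associated within a document (mentions compete for a finite number of
slots), so class co-occurrence is slightly sub-hypergeometric and the
universe-parameterization test runs conservative on null corpora: across 50
null corpora of 5000 documents the observed fraction of pairs below
$p = 0.05$ is around 0.006. The acceptance property asserted is therefore
one-sided type-I *control* — the significant fraction must not exceed
$\alpha$ beyond binomial noise — which is the property that matters for not
declaring spurious modules. Users should expect conservative, not exact,
null behavior from discrete co-occurrence tests on such corpora.

The generators do not emulate real MEDLINE text (the raw-dialect scanner is
exercised on constructed documents), real ChIP-seq peak calling, or any
particular genome's annotation corpus. Passing tests therefore demonstrate
that the machinery is correct and well calibrated under its stated model,
not that the original study's genome-wide score list or its figure-level
constants (score peaks at particular values, a specific background
similarity) would be reproduced — those depend on undistributed feature
data and a specific ontology release.

## Numerical and interface choices

- Hypergeometric tails sum the upper tail directly on the log scale;
  equivalence with exhaustive subset enumeration is asserted to $10^{-10}$
  over the full $N \le 12$ grid.
- Undefined quantities (ratios with empty classes, IC of unannotated terms,
  similarity of unannotated genes, scores of never-eligible genes) are `NA`
  with a documented meaning, never silent zeros.
- Errors are classed (`autolit_config_error`, `autolit_validation_error`,
  `autolit_parse_error`, ...) so callers can dispatch on failure kind;
  parse errors carry line numbers.
- `run_pipeline()` derives per-stage seeds from the global seed by a fixed
  hash, writes TSV/JSON outputs per stage, and records seeds, funnel counts
  and per-output checksums in `report.json`; a failing stage aborts with its
  name after marking the report `FAILED`, retaining completed outputs.
  `make_demo()` writes a byte-deterministic miniature input set (including
  the packaged 61-gene positive list) sized to run the whole pipeline in
  well under two minutes.
- Test and acceptance problem sizes — corpora of 2000–10 000 documents,
  feature matrices of 1000 genes, 500–2000 PU iterations, ontologies of at
  most a few dozen terms — were chosen as the smallest scales at which the
  asserted statistical properties are stable, and are stated alongside each
  check.

## Known limitations

- The lexicon merge rule is intentionally minimal; real vocabularies need a
  curated synonym table for anything beyond spelling variants.
- The literal co-mention parameterization is reported for fidelity but its
  draw model is hard to justify; use the universe form for inference.
- PU possibility scores are relative to the feature panel and positive set;
  they are not calibrated probabilities of disease involvement.
- Gene-level similarity uses direct annotations for the best-match average;
  propagated annotations enter only through IC, which is one of several
  defensible conventions.
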