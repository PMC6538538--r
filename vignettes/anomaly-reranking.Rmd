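---
title: "Re-ranking literature-based discovery with anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-ranking literature-based discovery with anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Open literature-based discovery (LBD) proposes a hidden knowledge pair
(A, C) whenever some source records a relation A→B and another records B→C,
but no source records A→C directly.  The classic example is Raynaud disease
(A) — blood viscosity (B) — fish oil (C).  Run over a full biomedical
thesaurus or a predication database, this closure produces millions of
pairs, the vast majority of which are correct but uninteresting (generally
known, or trivial vocabulary artifacts).  `lbdrank` implements the whole
pipeline — ingestion, filtering, closure, featurization — and then treats
the *interesting* pairs as statistical anomalies: a small subpopulation
whose feature signature differs from the bulk, to be surfaced by outlier
detectors rather than hand-made rules.

## The pipeline and its assumptions

1. **Ingestion** (`readRRFRelations()`, `readPredications()`,
   `readSemTypes()`): directed subject–predicate–object triples with
   occurrence counts, plus one or more broad semantic types per concept.
   Concepts without any semantic type cannot occupy a feature slot and are
   dropped.  Duplicate rows aggregate their counts; both supported dialects
   repeat rows per provenance.
2. **ISA merging** (`mergeIsaClasses()`): hierarchically related concepts
   are collapsed (undirected grouping, lexicographically smallest member as
   representative, semantic types unioned) because an A–C pair that differs
   from a known pair only by a hierarchy step is not a discovery.
3. **Filtering** (`applyFilters()`): in order, (i) minimum relation
   frequency (default 10, boundary-inclusive — the threshold that reduces a
   full thesaurus release to a few dozen usable relation labels), (ii) a
   relation blacklist plus negated-predication removal, (iii) removal of
   concepts whose outdegree strictly exceeds 5000, and (iv) an automatic
   stoplist of linking terms that link strictly more than 10000 candidate
   pairs in a first-pass closure.  The stoplist counting unit is the number
   of distinct (A, C) pairs a term links — "occurrences as a linking term"
   only exist relative to proposed pairs — which is why the closure runs
   twice.  Cheap per-triple filters run before the expensive closure-based
   one.  The outdegree filter counts distinct out-neighbours and does not
   cascade.
4. **Closure** (`abcClosure()`): ordered pairs, following stored triple
   direction; relation labels are carried along as witnesses but ignored by
   the closure itself.  Stoplisted concepts are excluded from the B role
   only.  Enumeration is lexicographic, so outputs are reproducible.
5. **Featurization** (`computePageRank()`, `buildLayout()`,
   `featurizeBatch()`): described below.
6. **Anomaly models** (`fitIsolationForest()`, `fitOneClass()`): described
   below.
7. **Evaluation** (`runTimesliceExperiment()`): three-date timeslicing.
   Hidden knowledge generated up to date1 is labelled against date2 (pairs
   that became known are the training outliers); models trained there score
   the hidden knowledge generated up to date2; the gold standard is the
   pairs present at date3 but absent at date2.  All three snapshots pass
   through identical merging and filtering, otherwise vocabulary churn
   floods the gold set.  Because date2 candidates are by definition unknown
   at date2, they are disjoint from the date2-confirmed training outliers;
   the orchestrator asserts this no-leakage property on every run.

## Feature vectors

Each candidate pair becomes one row of a sparse matrix with layout

```
[ n | A semantic types | C semantic types | LT semantic types | relations ]
```

* slot 1: `n`, the number of distinct linking terms — hypothesised to be
  *inversely* related to interestingness (trivial knowledge has many
  routes);
* A block: A's PageRank written into every semantic-type slot A carries
  (multi-typed concepts repeat their full weight; no splitting — this
  preserves the block-sum law below);
* C block: likewise for C;
* LT block: for each distinct linking term B, B's PageRank added into each
  of B's type slots;
* relation block: for each path witness (B, rel_AB, rel_BC), B's PageRank
  added to both relation slots — so a B linking through two relation pairs
  counts once in the LT block but once per witness here.

PageRank (damping 0.85, L1 tolerance 1e-8, at most 200 iterations; uniform
teleport; dangling mass redistributed uniformly; distinct unweighted edges)
supplies the concept weights.  These are canonical PageRank settings,
recorded in run provenance; the graph is the filtered concept-relation
graph of the snapshot itself, directed as stored — the one graph the
pipeline necessarily has.  The block sums obey exact conservation laws
(A-block sum = PageRank(A)·|types(A)|, relation-block sum = 2·Σ witness
PageRanks), which the test suite checks to accumulation precision; they are
useful invariants when extending the featurizer.

Feature values are deliberately **not** standardised: the PageRank
magnitudes are the weighting signal.

Train and test snapshots share a layout built from the union of their
semantic-type and relation inventories (`combineLayouts()`), so slot
meanings are identical across dates; training vectors use date1 PageRank,
test vectors date2 PageRank.

## Anomaly detectors

**Isolation forest** (built in this package): 100 trees, subsample 256,
uniformly random axis-parallel splits, score `2^(-E[h]/c(psi))`.  It is
trained *unsupervised* on all date1 candidate vectors, with the
contamination parameter set to the observed date2-confirmed outlier
fraction — the forest's native framing needs no labels, and the observed
fraction is the only data-driven threshold available.  A seed is mandatory;
the forest is bit-reproducible given it.  Fitting memory depends on the
subsample size, not the candidate count.

**One-class SVM** (via `e1071`): radial basis kernel, trained on the
*normal* (not-confirmed) vectors only, `nu = max(outlier fraction, 0.01)`,
kernel width `1/(p·var(X))`.  One-class SVMs need the dense training matrix
in memory — at predication-database scale this famously runs to hundreds of
gigabytes — so the fit checks the projected matrix size against a memory
budget first and raises a typed resource error naming the matrix size
instead of crashing.

Rankings sort by decreasing score with ties broken by pair id (stable).
The selected subset uses each model's native threshold by default
(forest: the contamination-implied training-score quantile; SVM: the sign
of the decision value); a top-k policy is also available.
`inspectDecisionPoints()` counts split features near the tree roots, named
through the layout, to show which attributes the forest considers decisive.

## The synthetic generator

No public corpus accompanies the method, so `generateFixture()` builds
three dated snapshots with the statistical structure the pipeline assumes,
plus complete ground truth.  Design choices, and what they emulate:

* **Topic clusters** (default: clusters of 20 concepts, within-cluster edge
  probability 0.6, 2000 concepts in all): locally dense neighbourhoods make
  the typical hidden pair reachable through several linking terms (median
  around 5), as in real thesauri where related concepts share many
  intermediates.  Every member carries its cluster's dominant semantic type
  plus up to two Zipf-weighted extras, so background source/target type
  pairings are frequent.
* **Promiscuous terms**: three hubs with 250 out-edges exceed the (fixture-
  scaled) outdegree threshold; two "stop-hubs" bridge whole clusters —
  below the outdegree threshold but linking ~1600 candidate pairs each,
  exactly the population the automatic stoplist exists for.  Bridging whole
  clusters (rather than random endpoints) keeps their own endpoint
  candidates rich in linking terms, so they do not distort the linking-term
  distribution.
* **Disused and negated relations**: 10% of background triples get counts
  below 10 and 5% get `NEG_`-prefixed predicates, exercising the per-triple
  filters.
* **Growth**: each date step adds ~1% of the triple count as new direct
  links sampled from *high*-linking-term candidates — the uninteresting
  confirmations that dominate real growth.
* **Planted interesting links** (default 25): drawn from a pool of 120
  "periphery" pairs — rare-typed source and target concepts joined by a
  dedicated single-purpose bridge concept, their endpoints' only candidate.
  Each planted pair therefore has exactly one linking term (below the
  background 10th percentile) and a semantic-type combination occurring in
  under 1% of background candidates.  "Rare combination" is evaluated over
  realised (source-type, target-type) pairs: a candidate qualifies only if
  *every* type pairing it realises is rare — exact type-set strings are
  combinatorially diverse and would make most ordinary pairs "rare" by
  accident.  Planted links are absent at date2, appear at date3, and are
  verified at generation time to be discoverable candidates of the filtered
  date2 snapshot; generation fails loudly if the requested signature cannot
  be realised (for example when the periphery would exceed 1% of
  candidates).

What the generator does **not** emulate: real citation dynamics, text, the
long-tailed degree distributions of a full metathesaurus, relation
semantics, or concept vocabularies that change between releases.  A passing
end-to-end test therefore shows that the machinery — filters, closure,
features, models, timeslicing — behaves as designed and can recover a
planted anomalous subpopulation; it does not show that real interesting
discoveries carry this exact signature.

## Numerical and procedural choices

* Thresholds follow the wording: "exceeding"/"more than" are strict,
  "minimum frequency of 10" is inclusive.
* ISA grouping treats the hierarchy as undirected (merging is an
  equivalence operation); representatives are lexicographically smallest
  ids, so results are input-order independent.
* Pairs are ordered end to end (closure, gold standard, evaluation):
  sources are directed triples, and an unordered convention would silently
  merge distinct claims.
* The paired t-test over per-split F values is **one-sided** by default.
  Recomputing the published five-split comparisons from their printed
  (4-decimal) F columns gives one-sided p ≈ 0.0014 / 0.019 / 0.0089 against
  the reported 0.0015 / 0.018 / 0.0094; the two-sided values would be about
  twice the reported ones, so the one-sided convention is the one that
  reproduces them.  `scripts/acceptance.R` recomputes all three.
* Degenerate inputs fail loudly: an empty snapshot cannot be closed, an
  empty gold standard cannot be evaluated, a zero-variance training set
  cannot define an SVM boundary, a single distinct vector cannot grow a
  forest, and zero-variance F differences cannot be tested.
* Isolation-tree splits that land on a boundary are forced to produce a
  proper two-sided partition; leaf path lengths use the standard
  `c(n)` adjustment.
* `withSeed()` scopes every seeded computation, restoring the caller's RNG
  state.

## Problem sizes

The default synthetic study uses 2000 concepts, 20 semantic types, 15
relation labels and seed 7, giving roughly 22k triples at date1 and ~15k
hidden candidates at date2 — enough for the filters, the stoplist, and both
models to operate in their intended regimes while a full experiment runs in
about a minute.  The structural test suite uses an 800-concept variant of
the same design.

## Limitations

* The isolation forest surfaces vectors that are *extreme* in individual
  features.  Low-mass candidates are only separable when some of their
  feature columns are rarely occupied by the background — which is exactly
  what a rare semantic-type combination provides.  Signatures that consist
  solely of having *less* of everything (fewer linking terms, smaller
  weights) rank poorly in any axis-parallel isolation scheme.
* The one-class SVM's training cost and memory grow with the candidate
  count; the resource guard turns the worst case into a typed error, not a
  workaround.
* Closed discovery (finding B terms for a suspected A–C pair) and
  multi-hop chains are out of scope.
* Symmetric relations contribute paths only in their stored direction.
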