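# lbdrank

Anomaly-based re-ranking for open literature-based discovery (LBD).

## What problem this solves

Open LBD follows Swanson's A-B-C model: if one source records a relation
A→B and another records B→C, but no source connects A and C directly, the
ordered pair (A, C) is proposed as *hidden knowledge* (the canonical case:
Raynaud disease — blood viscosity — fish oil).  Run over a full
metathesaurus release or a predication database, the closure yields millions
of pairs, almost all of them valid but uninteresting.  `lbdrank` is for
researchers building or evaluating LBD systems: it implements the full
pipeline and then *re-ranks* the candidates with anomaly detection, on the
hypothesis that interesting pairs are outliers among a vast background of
trivial ones.

Each candidate (A, C) with linking terms B₁…Bₙ becomes a sparse feature
vector

```
[ n | A semtype block | C semtype block | LT semtype block | relation block ]
```

where semantic-type slots carry the concepts' PageRank weights from the
filtered concept-relation graph: slot 1 is n (the number of linking terms),
the A/C blocks hold PR(A) and PR(C) in their types' slots, the LT block
accumulates PR(Bᵢ) over distinct linking terms, and the relation block adds
PR(Bᵢ) for both legs of every path witness.  Two detectors rank the
vectors: an isolation forest (100 random partition trees, subsample 256;
score 2^(−E[h]/c(ψ)), short average path = anomalous) trained unsupervised
on all training-window candidates, and a one-class SVM (RBF kernel) trained
on the uninteresting majority only.  Evaluation uses three-date
timeslicing: train on hidden knowledge from date₁ labelled against date₂,
score the hidden knowledge from date₂, and compare with the gold standard
of pairs that newly appeared by date₃, reporting precision, recall, F₁ and
paired-t significance across splits.

## Worked example

The package ships a synthetic-data generator that builds three nested dated
snapshots with ground truth: topic-clustered background growth plus a small
planted subpopulation of interesting links (one linking term, rare
semantic-type combination).

```r
library(lbdrank)

fx <- generateFixture()          # default study conditions, seed 7
fx$snapshots$date1
#> KnowledgeSnapshot 'date1': 1985 concepts, 19608 triples, 30 predicates, 20 semantic types

report <- runTimesliceExperiment(
  fx$snapshots$date1, fx$snapshots$date2, fx$snapshots$date3,
  config = fx$filterConfig, forestParams = list(seed = 1L))

report$evaluations$orig
#> EvaluationResult: |HK| 14876, |GS| 223, tp 223, P 0.01499, R 1, F1 0.02954
report$evaluations$iso
#> EvaluationResult: |HK| 231, |GS| 223, tp 12, P 0.05195, R 0.05381, F1 0.05286
report$evaluations$one
#> EvaluationResult: |HK| 2343, |GS| 223, tp 78, P 0.03329, R 0.3498, F1 0.0608
```

Reading the numbers: the unranked closure proposes 14,876 hidden pairs, of
which 223 actually appear by date₃ — perfect recall, precision 1.5%,
F₁ 0.030.  The isolation forest's selected subset is 64× smaller and
doubles precision (F₁ 0.053); the one-class SVM reaches F₁ 0.061.  Both
re-ranked F₁ values beat the unranked baseline, with the one-class SVM
ahead of the forest — the same ordering the method reports on real
thesaurus releases — and the planted interesting links rank in the
forest's top 5% of anomaly scores.

A thin command-line front-end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","lbd.R",package="lbdrank"))') \
    generate --out fixture/ --seed 7
Rscript ... discover --relations fixture/relations_date1.rrf \
    --semtypes fixture/semtypes.rrf --out run/
Rscript ... experiment --dir fixture/ --out run/ --seed 1
```

## Package tour

| Stage | Functions |
|---|---|
| Ingestion | `readRRFRelations`, `readPredications`, `readSemTypes`, `buildSnapshot` |
| ISA merging | `mergeIsaClasses`, `mergeSemTypes` |
| Filtering | `filterConfig`, `applyFilters`, `buildLinkingStoplist`, `applySemtypeRestriction` |
| Discovery | `abcClosure`, `knownPairs`, `writeCandidates` |
| Features | `computePageRank`, `buildLayout`, `featurizeBatch`, `writeFeatureMatrix` |
| Anomaly | `fitIsolationForest`, `fitOneClass`, `scorePairs`, `selectAnomalies`, `inspectDecisionPoints` |
| Evaluation | `buildGoldStandard`, `labelTrainingOutliers`, `evaluateF1`, `pairedTTest`, `runTimesliceExperiment` |
| Synthetic data | `syntheticSpec`, `generateFixture`, `writeFixtureFiles`, `readFixtureFiles` |

The methods vignette (`vignettes/anomaly-reranking.Rmd`) documents the
model, the parameter choices, the synthetic generator's design, and known
limitations.
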