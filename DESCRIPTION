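Package: lbdrank
Title: Anomaly-Based Re-Ranking for Literature-Based Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Open (A-B-C) literature-based discovery over dated snapshots of
    concept-relation triples, with anomaly-detection re-ranking of the
    proposed hidden-knowledge pairs. Provides readers for metathesaurus-style
    pipe-delimited relation and semantic-type files and for predication
    tables, ISA-class merging, frequency/outdegree/stoplist/relation
    filtering, the A-B-C closure, PageRank concept weighting, semantic-type
    feature vectors, isolation-forest and one-class-SVM scoring, and a
    three-date timeslicing evaluation protocol with paired-t significance
    testing. Includes a synthetic snapshot generator with planted
    "interesting" links for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table (>= 1.14),
    Matrix,
    igraph,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
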