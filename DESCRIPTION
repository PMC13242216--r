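Package: PhenoGDA
Title: Inductive Phenotype-Based Gene-Disease Association Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate genes for a query disease from phenotype
    ontology annotations. Ontology axioms (subsumptions, existential
    restrictions, cross-species equivalences) are projected to a labeled
    directed graph; knowledge-graph embeddings of phenotype terms are
    trained on that graph (TransE, TransH, TransD, ConvKB, optionally
    with a supervised gene-disease signal); genes are then scored against
    any novel disease by aggregating pairwise phenotype-embedding
    similarities with best-match-average, which makes the ranking
    inductive. Classical information-content measures (Resnik, Lin,
    SimGIC with BMA/BMM aggregation) are provided as baselines, together
    with disease-split cross-validation, ranked-retrieval metrics, and a
    synthetic two-species phenome generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'ontology.R'
    'io.R'
    'semsim.R'
    'kge.R'
    'ranking.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
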