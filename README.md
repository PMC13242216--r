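# PhenoGDA

Inductive gene–disease association (GDA) ranking from phenotype
ontologies.

## What problem this solves, and for whom

Clinical gene prioritisation asks: given a disease described only by a
set of human phenotype terms, which genes are most likely causative?
Mouse mutant phenotypes supply most of the evidence, so the comparison
runs across species through a bridging phenotype ontology.  Classical
semantic-similarity measures (Resnik, Lin, SimGIC with best-match
aggregation) handle *novel* diseases but use only the taxonomy;
knowledge-graph-embedding methods use all axioms plus known GDAs as a
supervised signal, but are transductive — a disease absent from the
training graph cannot be scored.

PhenoGDA is for researchers who want both: it learns embeddings of
**phenotype terms** (a fixed vocabulary) from a projected ontology graph
that can include gene, disease and GDA edges, then scores a gene
against *any* phenotype set by aggregating pairwise phenotype
similarities

    sim_e(p1, p2) = sigma(<p1, p2>)
    simBMA_e(Pg, Pd) = 1/2 ( mean_i max_j sim_e(pg_i, pd_j)
                           + mean_j max_i sim_e(pg_i, pd_j) )

so the disease itself never needs an embedding.  The package implements
the full pipeline: a restricted ontology dialect and its structural
graph projection, six graph variants (G1–G4 inductive, G3T/G4T
transductive) with leakage guards, TransE/TransH/TransD/ConvKB scoring
functions trained with margin-ranking or soft-margin losses, the
IC-based baselines, disease-split cross-validation with
duplicate-profile filtering, MR/MRR/Hits@k/AUC metrics, a Wilcoxon
paired comparison, and a seeded synthetic two-species phenome generator
so every stage is testable offline.

## Worked example

Generate a synthetic phenome (two bridged species trees, 60 genes, 30
diseases, one planted causative gene each), hold out a fold of
diseases, train TransD on the supervised graph G4, and rank genes for a
held-out disease the model has never seen:

```r
library(PhenoGDA)

phe <- generatePhenome(synthConfig(seed = 42))
dis <- names(profiles(phe$gdaAssoc))
fold <- diseaseFolds(dis, k = 5, seed = 42)[[1]]
gdaTrain <- associationTable("associated_with",
                             profiles(phe$gdaAssoc)[fold$train])

g4 <- buildGraphVariant(phe$ontology, phe$geneAssoc, phe$diseaseAssoc,
                        gdaTrain, "G4", testDiseases = fold$test)
g4
#> LabeledGraph: 327 nodes, 904 edges
#> associated_with   has_phenotype     has_symptom      subClassOf
#>              24             363             141             376

emb <- trainEmbeddings(g4, trainConfig("transd", d = 32, epochs = 150,
                                       seed = 42))
scorer <- gdaScorer("bma_e", embedding = emb)
d <- fold$test[1]
rankGenes(scorer, phe$geneAssoc,
          query = profiles(phe$diseaseAssoc)[[d]], disease = d)
#> RankedList for DIS:0004: 60 candidates
#>        gene     score
#> 1 GENE:0010 0.6270581
#> 2 GENE:0016 0.6242258
#> 3 GENE:0058 0.6174038
#> 4 GENE:0028 0.6133129
#> 5 GENE:0022 0.6116357
```

The planted causative gene of `DIS:0004` is `GENE:0016`: it ranks 2nd
of 60 candidates even though `DIS:0004` contributed no edges to the
training graph.  Scoring every held-out disease of the fold and
summarising the tie-averaged ranks of the true genes:

```r
recs <- do.call(rbind, lapply(fold$test, function(d) {
  rl <- rankGenes(scorer, phe$geneAssoc,
                  query = profiles(phe$diseaseAssoc)[[d]], disease = d)
  s <- setNames(rankedEntries(rl)$score, rankedEntries(rl)$gene)
  rankRecords(s, profiles(phe$gdaAssoc)[[d]], disease = d)
}))
rankingMetrics(recs)
#> MetricsReport over 6 records
#>   MR 9.00 | MRR 0.2030 | AUC 0.8644
#>   Hits@k: 1=0.000 10=0.667 100=1.000
```

MR is the mean rank of the true genes, MRR the mean reciprocal rank,
Hits@k the fraction ranked in the top k, and AUC the probability that a
true gene outranks a random non-associated candidate (here 0.86 versus
0.5 for chance).  `runExperiment()` wraps this whole loop — fold
splitting, duplicate filtering, per-fold training with leakage guards,
and mean ± SD aggregation — for any mix of embedding scorers and
IC-based baselines.

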