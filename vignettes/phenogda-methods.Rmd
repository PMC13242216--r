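---
title: "Phenotype-embedding methods for inductive gene–disease ranking"
author: "PhenoGDA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-embedding methods for inductive gene-disease ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoGDA)
```

## The problem

Candidate-gene prioritisation for Mendelian disease can be cast as ranked
retrieval: given a query disease described by a set of human phenotype
terms, rank genes by the similarity between the disease's phenotype
profile and the phenotypes observed in mouse mutants of each gene.  The
two species' vocabularies (MP-like and HPO-like terms) are made
comparable by a cross-species ontology whose axioms bridge corresponding
phenotype classes.

Classical similarity measures for this task are *inductive* — they work
for any disease expressible in known phenotype terms — but handcrafted:
they use only the taxonomy and an information-content weighting.
Embedding methods can exploit all axioms plus a supervised signal from
known gene–disease associations (GDAs), but scoring an entity requires
its embedding, which makes them *transductive*: a disease absent from
the training graph cannot be scored.  PhenoGDA implements the middle
road: embeddings are learned for *phenotype terms* (a fixed vocabulary),
and genes/diseases are compared by aggregating pairwise phenotype
similarities, so novel diseases — novel *combinations* of known terms —
are scored without retraining.  Genuinely novel phenotype terms remain
out of reach and are rejected with an explicit error.

## From axioms to a labeled graph

An ontology is a signature (classes, roles, individuals) plus axioms in
a deliberately restricted dialect: named subsumptions `C SubClassOf D`,
existential restrictions `C SubClassOf R some D`, and named equivalences
`C EquivalentTo D`.  Associations are converted to restriction axioms
(`gene SubClassOf has_phenotype some term`, `disease SubClassOf
has_symptom some term`, `disease SubClassOf associated_with some gene`);
phenotype targets missing from the ontology are dropped with a logged
count.  The structural projection rewrites axioms as labeled edges:

* `C SubClassOf D` → `(C, subClassOf, D)`
* `C SubClassOf R some D` → `(C, R, D)`
* `C EquivalentTo D` → reciprocal `subClassOf` edges, which makes
  equivalent (cross-species bridged) terms mutual ancestors for both the
  graph models and the IC measures.

Nested class expressions and the lexical/annotation channel of richer
projection schemes are intentionally unsupported and rejected at parse
time; no inverse edges are materialised by default (a flag exists), so
the base graph stays a pure taxonomy-plus-restriction graph.

Six graph variants control what the embeddings may see.  G1 is the
projected ontology alone; G2 adds gene–phenotype edges; G3 adds
*training*-disease phenotype edges; G4 adds training GDA edges (the
supervised signal).  G3T/G4T are transductive controls that additionally
contain the *test* diseases' phenotype edges — never their GDAs.
Construction enforces two guards: test-disease identifiers cannot occur
in G1–G4 at all, and a GDA involving a test disease anywhere in the
input is a hard error rather than a silent filter, because that is the
one leak that would invalidate every downstream number.

## Embedding models

Four scoring functions are trained on the edge multiset, with
entity/relation tables and manual gradients in base R (the models are
small; determinism matters more than throughput here):

* TransE: `f = -||h + r - t||_p`, `p ∈ {1, 2}` (default 2);
* TransH: `f = -||(h - w_r^T h w_r) + r - (t - w_r^T t w_r)||²` with
  `||w_r|| = 1`, re-normalised after every update;
* TransD: `f = -||(w_r w_h^T + I)h + r - (w_r w_t^T + I)t||²`, with a
  rectangular identity when the projection dimension `k` differs from
  `d` (default `k = d`);
* ConvKB: τ width-3 filters convolved over the stacked `[h, r, t]`
  matrix, ReLU, and a linear readout; entity/relation tables are
  initialised from a pretrained TransE ("convkb") or TransD
  ("convkb_d") run, which in practice is where these models start from.

Losses follow each model's original formulation, since the choice is
otherwise open: margin ranking loss `max(0, γ - f(pos) + f(neg))` for
the translational models and soft-margin logistic loss with an L2
penalty on the readout weights for ConvKB.  Negatives corrupt head or
tail (probability ½ each) with a uniform entity, unfiltered by default;
optimisation is Adam (SGD available) with Xavier-uniform
initialisation; entity norms are clamped to 1 after each epoch for the
translational models.  All randomness flows from one integer seed
through a documented congruential mixing function (`deriveSeed`), so a
single-threaded run is bit-reproducible; multi-threaded BLAS may break
that contract and is not used by these code paths.

Desk-scale defaults (`d = 32`, 200 epochs, batch 256, margin 1, 2
negatives, learning rate 0.01) train a ~300-node graph in a couple of
seconds; the release-scale search grid that a full-size run would
enumerate is kept in `kgeGrid()` for reference, not used by tests.

## Similarity measures

**IC baselines.**  Information content is computed over the
gene-annotation corpus (optionally genes + diseases): annotation counts
are propagated to all ancestors through the reflexive subsumption
closure before frequencies are taken — the standard corpus construction
— and `IC(p) = -ln(count(p)/n)` in nats.  Terms never observed even
after propagation get `ln(n)`, the maximal IC a single annotation could
attain; this keeps Lin and SimGIC finite on sparse desk-scale corpora
instead of introducing infinities.  Resnik similarity is the IC of the
most informative common ancestor (MICA, searched over subsumption edges
only — restriction edges are not subsumptions); Lin normalises it,
defined as 0 when both terms have zero IC.  Profile measures are
best-match average (BMA: mean of the two directional best-match means),
best-match maximum (BMM: their maximum, hence `BMM ≥ BMA` always), and
SimGIC, the IC-weighted Jaccard of the reflexive ancestor closures
(reflexivity is what makes `simgic(P, P) = 1`).

**Embedding similarity.**  Pairwise phenotype similarity is
`σ(⟨p₁, p₂⟩)` on the *unnormalised* embeddings (an L2-normalising flag
yields cosine behaviour); profiles are aggregated with the same BMA/BMM
machinery.  Two facts worth stating plainly: at the pairwise level the
sigmoid is strictly monotone, so orderings equal raw dot-product
orderings and positive rescaling cannot change them; after BMA/BMM
aggregation this is no longer exactly true, because a mean of sigmoids
is not a monotone transform of a mean of dot products.  The package
documents this rather than hiding it, and the invariance is tested at
the level where it holds.

## Ranking and evaluation

A scorer bundles a strategy with its context.  `bma_e`/`bmm_e`
(phenotype-embedding aggregation) and the IC baselines are inductive;
`entity_sim` (`σ(⟨g, d⟩)`) and `triple_score` (`f(d, associated_with,
g)`) are transductive and fail with an unknown-entity error on unseen
diseases — by design, as that error *is* the transductive limitation.
The default scorer is BMA-based, which outperformed BMM in both measure
families here and in prior experience with these aggregations.
Candidates are all genes with at least one phenotype annotation; output
lists are sorted by score with lexicographic tie-breaks for stable
output, while evaluation uses tie-averaged fractional ranks.

Evaluation follows a disease-split protocol: diseases are partitioned
uniformly into k folds (default 10); test diseases duplicating a
training disease in *both* phenotype profile and gene set are removed
(either alone is kept — the conjunction is what makes a test case
trivially memorisable); each surviving test disease contributes one
record per true gene.  Metrics are MR, MRR, Hits@k and AUC computed per
record as the normalised rank `(n - rank)/(n - 1)` (probability that the
true gene outranks a random non-associated candidate; 1 when `n = 1`),
aggregated as mean ± sample SD across folds.  Ranking is unfiltered by
default (co-true genes stay in the candidate list); the filtered mode,
which can only improve a true gene's rank, is available since the choice
is a convention.  Paired method comparison uses the two-sided Wilcoxon
signed-rank test on rank pairs aligned by (disease, gene), dropping
zero differences and reporting the signed-rank statistic centred at its
null expectation so that swapping the arguments flips its sign.

## The synthetic phenome

The generator emulates the *shapes* of the real inputs, not their
statistics: two complete 3-ary trees of depth 4 (81 leaves, 121 terms
per species — mouse-like `MPX:` and human-like `HPX:`) under a shared
root; leaves partitioned into 6 aligned modules; aligned leaf pairs
bridged by equivalence axioms at rate 0.9; 60 genes and 30 diseases
annotated with 4–8 leaf terms drawn from one module, 10% redrawn
off-module as noise; one planted causative gene per disease from the
disease's own module.  Module-structured annotation is the minimal
generative story under which both IC-based and embedding-based
similarity should recover the planted GDAs; the depth/branching pair is
the smallest that supports the annotation range within single modules
without replacement.  The bridge and noise rates are fixed once as
plausible desk-scale conditions — high but imperfect cross-species
coverage, modest annotation error — and the noise dial demonstrably
degrades recovery in expectation, which is what a difficulty dial is
for.

What passing on this data does and does not show: it validates the
machinery end to end (projection, leakage guards, training, inductive
scoring, metrics) and the qualitative orderings (supervised G4 at least
matches G3; BMA at least matches BMM; planted signal far above a
label-permuted control).  It does not certify performance on real
MGI/HPO-scale corpora, whose annotation-frequency imbalances,
granularity differences between species, and multi-gene diseases the
generator deliberately does not model.

## Numerical choices and degenerate inputs

Natural logarithms throughout (Lin and SimGIC are base-invariant;
Resnik values are in nats).  Empty profiles are errors, not zeros;
SimGIC returns 0 on a vanishing denominator; Lin returns 0 when both
ICs are 0; a disconnected term pair falls back to the unique root (two
disconnected roots are an error).  A non-finite training loss aborts
with a diagnostic pointing at the learning rate.  Iteration orders are
fixed lexicographically wherever they could leak into randomised
downstream steps.  Test and acceptance runs use the preset sizes above
with `d = 32` and 100–150 epochs — sizes chosen so the full
planted-signal block trains ~10 embedding models in well under a
minute on one core, which keeps the whole pipeline honest to rerun
rather than cached.

## Limitations

No OWL 2 parsing or DL reasoning: the dialect covers exactly the three
axiom forms the pipeline uses, and a real cross-species release can
only be ingested after conversion to that dialect (an OBO-subset reader
is provided but not validated against any release).  The aggregation
function is fixed (BMA/BMM), not learned.  Embedding training is plain
R and sized for desk-scale graphs, not for release-scale corpora.
Variant- or patient-level inputs (VCFs, pathogenicity scores) are out
of scope.
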