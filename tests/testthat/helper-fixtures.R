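## Shared fixtures: the 6-term toy DAG with its 4-gene corpus, and small
## builders used across tests.

toyOntology <- function() {
  ontology(data.frame(
    subject = c("P_A1", "P_A2", "P_B1", "P_A", "P_B"),
    kind = "SubClassOf", relation = NA_character_,
    object = c("P_A", "P_A", "P_B", "ROOT", "ROOT"),
    stringsAsFactors = FALSE))
}

toyCorpus <- function() {
  associationTable("has_phenotype",
                   list(g1 = "P_A1", g2 = "P_A2", g3 = "P_B1", g4 = "P_B1"))
}

## minimal diamond ontology plus associations for graph-variant tests
variantFixture <- function() {
  ont <- ontology(data.frame(
    subject = c("P1", "P2", "Q1"), kind = "SubClassOf",
    relation = NA_character_, object = c("P", "P", "Q"),
    stringsAsFactors = FALSE),
    classes = c("P", "Q", "ROOT"))
  ont <- ontology(rbind(axioms(ont), data.frame(
    subject = c("P", "Q"), kind = "SubClassOf", relation = NA_character_,
    object = "ROOT", stringsAsFactors = FALSE)))
  list(
    ont = ont,
    gene = associationTable("has_phenotype",
                            list(g1 = c("P1", "P2"), g2 = "Q1")),
    disease = associationTable("has_symptom",
                               list(d1 = "P1", d2 = "Q1", d3 = "P2")),
    gda = associationTable("associated_with", list(d1 = "g1", d2 = "g2")))
}

## deterministic random embedding set for ranking tests
randomEmbedding <- function(ids, d = 4L, seed = 1L, model = "transe") {
  set.seed(seed)
  ent <- matrix(rnorm(length(ids) * d), length(ids), d,
                dimnames = list(ids, NULL))
  rel <- matrix(rnorm(d), 1, d, dimnames = list("associated_with", NULL))
  embeddingSet(model, ent, rel)
}
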