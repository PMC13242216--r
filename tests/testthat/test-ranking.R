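test_that("entity similarity is the sigmoid of the dot product", {
  ent <- matrix(c(2, 0, 3, 0, 0, 1), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  emb <- embeddingSet("transe", ent,
                      matrix(0, 1, 2, dimnames = list("r", NULL)))
  expect_equal(entitySim(emb, "a", "c"), 0.5)           # orthogonal
  expect_equal(entitySim(emb, "a", "b"), plogis(6))
  expect_equal(entitySim(emb, "a", "b"), entitySim(emb, "b", "a"))
  expect_error(entitySim(emb, "a", "zz"), "unknown entity 'zz'")
})

test_that("profile similarity aggregates the sigmoid kernel like BMA/BMM", {
  ## engineered 2x1 kernel: sim(p1,q) = 0.9, sim(p2,q) = 0.5
  ent <- matrix(c(qlogis(0.9), 0, 1), 3, 1,
                dimnames = list(c("p1", "p2", "q"), NULL))
  emb <- embeddingSet("transe", ent,
                      matrix(0, 1, 1, dimnames = list("r", NULL)))
  expect_equal(profileSim(emb, c("p1", "p2"), "q", "bma"),
               ((0.9 + 0.5) / 2 + 0.9) / 2)
  expect_equal(profileSim(emb, c("p1", "p2"), "q", "bmm"), 0.9)
  ## singleton profiles reduce to the pairwise similarity
  expect_equal(profileSim(emb, "p1", "q", "bma"), entitySim(emb, "p1", "q"))
  expect_equal(profileSim(emb, "p1", "q", "bmm"), entitySim(emb, "p1", "q"))
  expect_error(profileSim(emb, "p1", "zz"), "missing from embedding")

  ## bmm >= bma on random profiles
  set.seed(8)
  for (i in 1:20) {
    ids <- sprintf("t%02d", 1:10)
    emb <- randomEmbedding(ids, d = 5L, seed = i)
    pg <- sample(ids, 3)
    pd <- sample(ids, 4)
    expect_gte(profileSim(emb, pg, pd, "bmm"),
               profileSim(emb, pg, pd, "bma"))
    expect_equal(profileSim(emb, pg, pd, "bma"),
                 profileSim(emb, pd, pg, "bma"))
  }
})

test_that("gene ordering under the sigmoid kernel equals raw dot-product order", {
  ## the sigmoid is strictly monotone, so at the pairwise level (and for
  ## singleton profiles, where aggregation reduces to one pair) the
  ## ordering it induces is exactly the raw dot-product ordering, and
  ## positive rescaling of the embeddings cannot change it either
  for (s in 1:10) {
    ids <- c(sprintf("g%02d", 1:8), "query")
    emb <- randomEmbedding(ids, d = 5L, seed = s)
    E <- entityVectors(emb)
    sc <- gdaScorer("entity_sim", embedding = emb)
    prof <- setNames(as.list(ids[1:8]), ids[1:8])  # candidates need profiles
    rl <- rankGenes(sc, prof, disease = "query")
    raw <- drop(E[ids[1:8], ] %*% E["query", ])
    rawOrd <- names(sort(raw, decreasing = TRUE))
    expect_identical(rankedEntries(rl)$gene, rawOrd)

    ## singleton-profile BMA reduces to the pairwise kernel
    rlB <- rankGenes(gdaScorer("bma_e", embedding = emb), prof,
                     query = "query")
    expect_identical(rankedEntries(rlB)$gene, rawOrd)

    ## positive scaling changes scores, never the pairwise ordering
    emb2 <- embeddingSet("transe", E * 3, relationVectors(emb))
    rl2 <- rankGenes(gdaScorer("entity_sim", embedding = emb2), prof,
                     disease = "query")
    expect_identical(rankedEntries(rl2)$gene, rankedEntries(rl)$gene)
    expect_false(isTRUE(all.equal(rankedEntries(rl2)$score,
                                  rankedEntries(rl)$score)))
  }
})

test_that("ranking is deterministic under permutation and breaks ties lexicographically", {
  set.seed(3)
  terms <- sprintf("P%02d", 1:8)
  emb <- randomEmbedding(terms, d = 4L, seed = 5L)
  prof <- list(gB = terms[1:2], gA = terms[1:2], gC = terms[3:5])
  query <- terms[c(2, 6)]
  rl <- rankGenes(gdaScorer("bma_e", embedding = emb), prof, query = query)
  perm <- rankGenes(gdaScorer("bma_e", embedding = emb),
                    prof[c(3, 1, 2)],
                    query = rev(query))
  expect_identical(rankedEntries(rl), rankedEntries(perm))
  ## gA and gB share a profile hence a score; gA must precede gB
  en <- rankedEntries(rl)
  expect_lt(which(en$gene == "gA"), which(en$gene == "gB"))
  expect_equal(en$score[en$gene == "gA"], en$score[en$gene == "gB"])
})

test_that("inductive scorers handle novel diseases; transductive ones refuse", {
  fx <- variantFixture()
  test <- "d3"
  g4 <- buildGraphVariant(fx$ont, fx$gene, fx$disease,
                          associationTable("associated_with",
                                           profiles(fx$gda)),
                          "G4", testDiseases = test)
  emb <- trainEmbeddings(g4, trainConfig("transd", d = 8L, epochs = 20L,
                                         seed = 1L))
  query <- profiles(fx$disease)[[test]]
  rl <- rankGenes(gdaScorer("bma_e", embedding = emb), fx$gene,
                  query = query, disease = test)
  expect_s4_class(rl, "RankedList")
  expect_setequal(rankedEntries(rl)$gene, c("g1", "g2"))

  expect_error(rankGenes(gdaScorer("entity_sim", embedding = emb),
                         fx$gene, disease = test),
               "unknown entity 'd3'")
  expect_error(rankGenes(gdaScorer("triple_score", embedding = emb),
                         fx$gene, disease = test),
               "unknown entity")

  ## a query containing an unknown phenotype term is refused even for
  ## the inductive scorer: the phenotype vocabulary is fixed
  expect_error(rankGenes(gdaScorer("bma_e", embedding = emb), fx$gene,
                         query = "P_NOVEL"),
               "missing from embedding")
})

test_that("semantic-baseline scorer ranks through IC similarity", {
  ont <- toyOntology()
  ic <- computeIC(ont, toyCorpus())
  prof <- list(gNear = "P_A1", gFar = "P_B1")
  sc <- gdaScorer("semantic_baseline", ic = ic, ontology = ont,
                  measure = "resnik", aggregation = "bma")
  rl <- rankGenes(sc, prof, query = "P_A2")
  en <- rankedEntries(rl)
  expect_identical(en$gene, c("gNear", "gFar"))
  expect_equal(en$score, c(log(2), 0))
  sg <- gdaScorer("semantic_baseline", ic = ic, ontology = ont,
                  aggregation = "simgic")
  expect_equal(rankedEntries(rankGenes(sg, prof, query = "P_A2"))$gene[1],
               "gNear")
  expect_error(rankGenes(sc, prof, query = "P_NOVEL"), "unknown phenotype")
})
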