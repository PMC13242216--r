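## Hand-computable scoring fixtures use tiny explicit embedding sets.

twoDimEmb <- function(model, ent, rel, ...) {
  embeddingSet(model,
               matrix(unlist(ent), ncol = 2, byrow = TRUE,
                      dimnames = list(names(ent), NULL)),
               matrix(unlist(rel), ncol = 2, byrow = TRUE,
                      dimnames = list(names(rel), NULL)), ...)
}

test_that("TransE scores are negative translation distances", {
  emb <- twoDimEmb("transe", list(a = c(1, 0), b = c(1, 1)),
                   list(r = c(0, 1)))
  expect_equal(scoreTriple(emb, "a", "r", "b"), 0)
  expect_equal(scoreTriple(emb, "b", "r", "a"), -2)          # ||(0,2)||_2
  expect_equal(scoreTriple(emb, "b", "r", "a", normOrder = 1L), -2)
  emb2 <- twoDimEmb("transe", list(a = c(1, 0), b = c(3, 1)),
                    list(r = c(0, 0)))
  expect_equal(scoreTriple(emb2, "a", "r", "b", normOrder = 1L), -3)
  expect_equal(scoreTriple(emb2, "a", "r", "b"), -sqrt(5))
  expect_error(scoreTriple(emb, "nope", "r", "b"), "unknown entity")
})

test_that("TransH projects onto the relation hyperplane before translating", {
  ## w_r = (1, 0): h = (2, 3) and t = (0, 3) both project to (0, 3)
  emb <- twoDimEmb("transh", list(h = c(2, 3), t = c(0, 3)),
                   list(r = c(0, 0)),
                   relationNormals = matrix(c(1, 0), 1, 2,
                                            dimnames = list("r", NULL)))
  expect_equal(scoreTriple(emb, "h", "r", "t"), 0)
  ## zero normal reduces to the squared-L2 translational score
  emb0 <- twoDimEmb("transh", list(h = c(1, 2), t = c(0, 1)),
                    list(r = c(1, 0)),
                    relationNormals = matrix(0, 1, 2,
                                             dimnames = list("r", NULL)))
  expect_equal(scoreTriple(emb0, "h", "r", "t"), -(2^2 + 1^2))
})

test_that("TransD with zero projection vectors reduces to squared-L2 TransE", {
  ids <- c("h", "t")
  ent <- matrix(c(1, 2, 0, 1), 2, 2, byrow = TRUE,
                dimnames = list(ids, NULL))
  rel <- matrix(c(1, 0), 1, 2, dimnames = list("r", NULL))
  emb <- embeddingSet("transd", ent, rel,
                      relationNormals = matrix(0, 1, 2,
                                               dimnames = list("r", NULL)),
                      entityProjections = matrix(0, 2, 2,
                                                 dimnames = list(ids, NULL)))
  u <- c(1, 2) + c(1, 0) - c(0, 1)
  expect_equal(scoreTriple(emb, "h", "r", "t"), -sum(u^2))

  ## degenerate projections give the same triple ordering as TransE L2^2
  set.seed(42)
  n <- 8L
  ids <- sprintf("e%02d", 1:n)
  ent <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, NULL))
  rel <- matrix(rnorm(3), 1, 3, dimnames = list("r", NULL))
  trd <- embeddingSet("transd", ent, rel,
                      relationNormals = matrix(0, 1, 3,
                                               dimnames = list("r", NULL)),
                      entityProjections = matrix(0, n, 3,
                                                 dimnames = list(ids, NULL)))
  tre <- embeddingSet("transe", ent, rel)
  triples <- expand.grid(head = ids, tail = ids,
                         stringsAsFactors = FALSE)
  triples <- triples[triples$head != triples$tail, ]
  triples$relation <- "r"
  sD <- scoreTriples(trd, triples)
  sE <- scoreTriples(tre, triples)          # -L2; squaring is monotone
  expect_identical(order(sD), order(-(-sE)^2))
})

test_that("ConvKB scoring matches the direct formula", {
  ids <- c("h", "t")
  ent <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE,
                dimnames = list(ids, NULL))
  rel <- matrix(c(1, 1), 1, 2, dimnames = list("r", NULL))
  zero <- embeddingSet("convkb", ent, rel,
                       convFilters = matrix(0, 2, 3),
                       convWeight = rep(1, 4), convBias = 0)
  expect_equal(scoreTriple(zero, "h", "r", "t"), 0)

  ## one filter (1, 1, -1), w = 1s, b = 0: v = relu(h + r - t) summed
  emb <- embeddingSet("convkb", ent, rel,
                      convFilters = matrix(c(1, 1, -1), 1, 3),
                      convWeight = c(1, 1), convBias = 0)
  v <- pmax(c(1, 2) + c(1, 1) - c(3, 4), 0)
  expect_equal(scoreTriple(emb, "h", "r", "t"), sum(v))
  ## negative pre-activations are clipped by the ReLU
  expect_equal(scoreTriple(emb, "t", "r", "h"),
               sum(pmax(c(3, 4) + c(1, 1) - c(1, 2), 0)))
})

test_that("negative sampling corrupts one slot, deterministically", {
  g <- new("LabeledGraph", nodes = c("a", "b"),
           edges = data.frame(head = "a", relation = "r", tail = "b"))
  neg <- sampleNegatives(g, graphEdges(g), nNeg = 5L, seed = 3L)
  for (i in seq_len(nrow(neg))) {
    changed <- (neg$head[i] != "a") + (neg$tail[i] != "b")
    expect_lte(changed, 1L)
  }
  expect_identical(sampleNegatives(g, graphEdges(g), 5L, seed = 3L), neg)
  expect_equal(nrow(sampleNegatives(g, graphEdges(g), 0L, seed = 3L)), 0L)
  g1 <- new("LabeledGraph", nodes = "a",
            edges = data.frame(head = character(), relation = character(),
                               tail = character()))
  expect_error(sampleNegatives(g1, graphEdges(g), 1L), "at least 2")
})

test_that("training reduces the loss and is reproducible under a seed", {
  edges <- data.frame(head = c("a", "b", "c"), relation = "r",
                      tail = c("b", "c", "a"))
  g <- new("LabeledGraph", nodes = c("a", "b", "c"), edges = edges)
  cfg <- trainConfig("transe", d = 8L, epochs = 200L, batchSize = 4L,
                     seed = 5L)
  emb <- trainEmbeddings(g, cfg)
  h <- attr(emb, "history")
  expect_lt(h[length(h)], h[1])
  expect_true(all(sqrt(rowSums(entityVectors(emb)^2)) <= 1 + 1e-6))

  emb2 <- trainEmbeddings(g, cfg)
  expect_identical(entityVectors(emb), entityVectors(emb2))

  for (model in c("transh", "transd", "convkb")) {
    cfgM <- trainConfig(model, d = 4L, epochs = 30L, batchSize = 4L,
                        seed = 5L, allowRandomConvInit = TRUE)
    hM <- attr(trainEmbeddings(g, cfgM), "history")
    expect_lt(mean(tail(hM, 5)), hM[1])
  }
})

test_that("ConvKB initialisation validates its pretrained source", {
  edges <- data.frame(head = c("a", "b"), relation = "r", tail = c("b", "a"))
  g <- new("LabeledGraph", nodes = c("a", "b"), edges = edges)
  pre8 <- trainEmbeddings(g, trainConfig("transd", d = 8L, epochs = 5L,
                                         seed = 1L))
  expect_error(trainEmbeddings(g, trainConfig("convkb_d", d = 16L,
                                              epochs = 5L, seed = 1L,
                                              initFrom = pre8)),
               "dimension mismatch")
  expect_error(trainEmbeddings(g, trainConfig("convkb", d = 8L,
                                              epochs = 5L, seed = 1L,
                                              initFrom = pre8)),
               "pretrained transe")
  expect_error(trainConfig("convkb", d = 8L), "initFrom")
  ok <- trainEmbeddings(g, trainConfig("convkb_d", d = 8L, epochs = 5L,
                                       seed = 1L, initFrom = pre8))
  expect_s4_class(ok, "EmbeddingSet")
})

test_that("TransD recovers planted cluster structure", {
  ## two entity clusters connected only within clusters
  set.seed(2)
  nodes <- c(sprintf("A%02d", 1:8), sprintf("B%02d", 1:8))
  within <- function(ids) {
    pairs <- t(combn(ids, 2))
    data.frame(head = pairs[, 1], relation = "linked", tail = pairs[, 2],
               stringsAsFactors = FALSE)
  }
  edges <- rbind(within(nodes[1:8]), within(nodes[9:16]))
  g <- new("LabeledGraph", nodes = nodes, edges = edges)
  emb <- trainEmbeddings(g, trainConfig("transd", d = 8L, epochs = 100L,
                                        batchSize = 32L, seed = 9L))
  E <- entityVectors(emb)
  E <- E / sqrt(rowSums(E^2))
  S <- E %*% t(E)
  inA <- startsWith(rownames(E), "A")
  intra <- mean(c(S[inA, inA][upper.tri(S[inA, inA])],
                  S[!inA, !inA][upper.tri(S[!inA, !inA])]))
  inter <- mean(S[inA, !inA])
  expect_gt(intra, inter)
})

test_that("embedding sets round-trip through TSV + manifest export", {
  edges <- data.frame(head = c("a", "b"), relation = "r", tail = c("b", "a"))
  g <- new("LabeledGraph", nodes = c("a", "b"), edges = edges)
  for (model in c("transe", "transh", "transd")) {
    emb <- trainEmbeddings(g, trainConfig(model, d = 4L, epochs = 3L,
                                          seed = 2L))
    dir <- withr::local_tempdir()
    writeEmbeddings(emb, dir)
    back <- readEmbeddings(dir)
    expect_equal(embeddingModel(back), model)
    expect_equal(entityVectors(back), entityVectors(emb))
    expect_equal(relationVectors(back), relationVectors(emb))
  }
  pre <- trainEmbeddings(g, trainConfig("transe", d = 4L, epochs = 3L,
                                        seed = 2L))
  emb <- trainEmbeddings(g, trainConfig("convkb", d = 4L, epochs = 3L,
                                        seed = 2L, initFrom = pre))
  dir <- withr::local_tempdir()
  writeEmbeddings(emb, dir)
  back <- readEmbeddings(dir)
  tr <- data.frame(head = "a", relation = "r", tail = "b")
  expect_equal(scoreTriples(back, tr), scoreTriples(emb, tr))
})
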