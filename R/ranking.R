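## Gene-disease scoring from phenotype embeddings: sigmoid dot-product
## similarity, BMA/BMM aggregation over phenotype profiles (the inductive
## scorers), the transductive comparison scorers f(h,r,t) and
## sigma(<g, d>), and ranked gene-list construction.

#' Sigmoid dot-product similarity between two embedded entities
#'
#' \code{sigma(<a, b>)}, in (0, 1), symmetric.  Embeddings are used
#' unnormalised; set \code{normalize = TRUE} for a cosine-style kernel.
#' This is the transductive failure mode by construction: an identifier
#' absent from the embedding vocabulary is an error naming the id.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param a,b entity identifiers.
#' @param normalize L2-normalise vectors before the dot product.
#' @return Similarity in (0, 1).
#' @export
entitySim <- function(emb, a, b, normalize = FALSE) {
  E <- emb@entities
  for (id in c(a, b))
    if (!id %in% rownames(E)) .err("unknown entity '%s'", id)
  va <- E[a, ]; vb <- E[b, ]
  if (normalize) {
    va <- va / max(sqrt(sum(va^2)), .Machine$double.eps)
    vb <- vb / max(sqrt(sum(vb^2)), .Machine$double.eps)
  }
  stats::plogis(sum(va * vb))
}

## sigma(<p, q>) matrix between two term sets; errors on unknown terms
.simEMatrix <- function(emb, termsA, termsB, normalize = FALSE) {
  E <- emb@entities
  miss <- setdiff(unique(c(termsA, termsB)), rownames(E))
  if (length(miss))
    .err("phenotype term(s) missing from embedding vocabulary: %s",
         paste(utils::head(miss, 3), collapse = ", "))
  A <- E[termsA, , drop = FALSE]
  B <- E[termsB, , drop = FALSE]
  if (normalize) {
    A <- .rowNormalize(A)
    B <- .rowNormalize(B)
  }
  stats::plogis(A %*% t(B))
}

#' Embedding-based profile similarity
#'
#' Aggregates the pairwise sigmoid dot-product similarities between two
#' phenotype profiles with best-match average or best-match maximum.
#' Novel diseases are fine -- only the phenotype terms must be in the
#' embedding vocabulary.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param pg,pd non-empty character vectors of phenotype terms.
#' @param aggregation \code{"bma"} or \code{"bmm"}.
#' @param normalize L2-normalise embeddings first.
#' @return Similarity in (0, 1).
#' @export
profileSim <- function(emb, pg, pd, aggregation = c("bma", "bmm"),
                       normalize = FALSE) {
  aggregation <- match.arg(aggregation)
  if (!length(pg) || !length(pd)) .err("empty annotation profile")
  M <- .simEMatrix(emb, pg, pd, normalize = normalize)
  .bestMatchAggregate(M, aggregation)
}

#' Construct a gene-disease scorer
#'
#' @param kind scorer kind; see \linkS4class{GDAScorer}.
#' @param embedding \linkS4class{EmbeddingSet} (embedding kinds).
#' @param ic \linkS4class{ICTable} (semantic baseline).
#' @param ontology \linkS4class{Ontology} (semantic baseline).
#' @param relation relation scored by \code{triple_score}.
#' @param measure pairwise measure for the semantic baseline.
#' @param aggregation \code{"bma"}, \code{"bmm"} or (semantic baseline
#'   only) \code{"simgic"}.
#' @return A \linkS4class{GDAScorer}.
#' @export
gdaScorer <- function(kind = c("bma_e", "bmm_e", "entity_sim",
                               "triple_score", "semantic_baseline"),
                      embedding = NULL, ic = NULL, ontology = NULL,
                      relation = "associated_with",
                      measure = c("resnik", "lin"),
                      aggregation = c("bma", "bmm", "simgic")) {
  kind <- match.arg(kind)
  new("GDAScorer", kind = kind, relation = relation, embedding = embedding,
      ic = ic, ontology = ontology, measure = match.arg(measure),
      aggregation = match.arg(aggregation))
}

#' Rank candidate genes for a query phenotype profile
#'
#' Scores every candidate gene (all genes with a non-empty phenotype
#' profile) against the query and returns them sorted by non-increasing
#' score, ties broken lexicographically by gene id so output is
#' reproducible (tie-aware fractional ranks are computed in evaluation,
#' not here).
#'
#' Inductive scorers (\code{bma_e}, \code{bmm_e},
#' \code{semantic_baseline}) accept any query composed of known phenotype
#' terms -- the disease itself need never have been seen.  Transductive
#' scorers (\code{entity_sim}, \code{triple_score}) score the disease
#' entity directly and therefore fail with an unknown-entity error when
#' the query disease was not embedded.
#'
#' @param scorer a \linkS4class{GDAScorer}.
#' @param geneProfiles an \linkS4class{AssociationTable} (or named list)
#'   of gene phenotype profiles; genes with empty profiles are excluded.
#' @param query character vector of query phenotype terms (inductive
#'   kinds); ignored for transductive kinds.
#' @param disease query disease identifier (required for transductive
#'   kinds; label otherwise).
#' @return A \linkS4class{RankedList}.
#' @export
rankGenes <- function(scorer, geneProfiles, query = character(),
                      disease = "query") {
  prof <- if (is(geneProfiles, "AssociationTable")) geneProfiles@profiles
          else geneProfiles
  prof <- prof[lengths(prof) > 0L]
  if (!length(prof)) .err("no candidate genes with non-empty profiles")
  genes <- sort(names(prof))
  prof <- prof[genes]
  kind <- scorer@kind
  if (kind %in% c("bma_e", "bmm_e")) {
    if (!length(query)) .err("empty query profile")
    emb <- scorer@embedding
    allTerms <- unique(unlist(prof, use.names = FALSE))
    M <- .simEMatrix(emb, allTerms, unique(query))   # errors on novel terms
    rownames(M) <- allTerms
    agg <- if (kind == "bma_e") "bma" else "bmm"
    scores <- vapply(prof, function(p)
      .bestMatchAggregate(M[p, , drop = FALSE], agg), numeric(1))
  } else if (kind == "semantic_baseline") {
    if (!length(query)) .err("empty query profile")
    ont <- scorer@ontology
    icTab <- scorer@ic
    allTerms <- unique(c(unlist(prof, use.names = FALSE), query))
    unknown <- setdiff(allTerms, ont@classes)
    if (length(unknown))
      .err("unknown phenotype term(s): %s",
           paste(utils::head(unknown, 3), collapse = ", "))
    anc <- ancestorClosure(ont, allTerms)
    if (scorer@aggregation == "simgic") {
      scores <- vapply(prof, function(p)
        groupSim(ont, icTab, p, query, aggregation = "simgic", anc = anc),
        numeric(1))
    } else {
      M <- .termSimMatrix(ont, icTab,
                          unique(unlist(prof, use.names = FALSE)),
                          unique(query), measure = scorer@measure,
                          anc = anc)
      scores <- vapply(prof, function(p)
        .bestMatchAggregate(M[p, , drop = FALSE], scorer@aggregation),
        numeric(1))
    }
  } else if (kind == "entity_sim") {
    scores <- vapply(genes, function(g)
      entitySim(scorer@embedding, g, disease), numeric(1))
  } else {                               # triple_score
    emb <- scorer@embedding
    triples <- data.frame(head = disease, relation = scorer@relation,
                          tail = genes, stringsAsFactors = FALSE)
    scores <- scoreTriples(emb, triples)
    names(scores) <- genes
  }
  ord <- order(-scores, genes)
  new("RankedList", disease = disease,
      entries = data.frame(gene = genes[ord], score = unname(scores[ord]),
                           stringsAsFactors = FALSE))
}
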