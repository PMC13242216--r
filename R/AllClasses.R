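#' @import methods
#' @importFrom stats setNames
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

## Relation names with fixed meaning across the package. `subClassOf` labels
## taxonomy edges produced by projection; the other three label association
## axioms added on top of the ontology.
.RESERVED_RELATIONS <- c("subClassOf", "has_phenotype", "has_symptom",
                         "associated_with")

.AXIOM_KINDS <- c("SubClassOf", "SubClassOfSome", "EquivalentTo")

#' Ontology: signature plus axiom set
#'
#' An ontology is a signature (class, role and individual names) together
#' with a sequence of axioms in a restricted dialect: named-class
#' subsumptions (\code{SubClassOf}), existential restrictions
#' (\code{SubClassOfSome}, carrying a role) and named-class equivalences
#' (\code{EquivalentTo}).  The subsumption relation restricted to classes
#' must be acyclic.
#'
#' @slot classes character vector of class identifiers.
#' @slot roles character vector of role (relation) identifiers.
#' @slot individuals character vector of individual identifiers.
#' @slot axioms data.frame with columns \code{subject}, \code{kind},
#'   \code{relation} (\code{NA} unless \code{kind == "SubClassOfSome"})
#'   and \code{object}.
#' @exportClass Ontology
setClass("Ontology",
  representation(classes = "character", roles = "character",
                 individuals = "character", axioms = "data.frame"))

setValidity("Ontology", function(object) {
  ax <- object@axioms
  need <- c("subject", "kind", "relation", "object")
  if (!all(need %in% names(ax)))
    return(sprintf("axioms must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ax)) {
    if (!all(ax$kind %in% .AXIOM_KINDS))
      return("unknown axiom kind")
    some <- ax$kind == "SubClassOfSome"
    if (any(some & is.na(ax$relation)))
      return("SubClassOfSome axiom without a relation")
    if (any(!some & !is.na(ax$relation)))
      return("relation present on a non-restriction axiom")
    if (any(some & ax$subject == ax$relation, na.rm = TRUE))
      return("axiom subject equals its relation")
    sig <- c(object@classes, object@individuals)
    terms <- c(ax$subject, ax$object)
    if (!all(terms %in% sig))
      return(sprintf("axiom term(s) missing from signature: %s",
                     paste(utils::head(setdiff(terms, sig), 3), collapse = ", ")))
    if (!all(ax$relation[some] %in% object@roles))
      return("restriction role missing from signature roles")
    cyc <- .findSubsumptionCycle(ax)
    if (!is.null(cyc))
      return(sprintf("subsumption cycle: %s", paste(cyc, collapse = " -> ")))
  }
  if (any(!nzchar(c(object@classes, object@roles, object@individuals))))
    return("empty identifier in signature")
  TRUE
})

#' Labeled directed graph obtained by ontology projection
#'
#' Nodes are term identifiers; edges are (head, relation, tail) triples.
#' This is the training substrate for the knowledge-graph embedding models.
#'
#' @slot nodes character vector of node identifiers.
#' @slot edges data.frame with columns \code{head}, \code{relation},
#'   \code{tail}.
#' @exportClass LabeledGraph
setClass("LabeledGraph",
  representation(nodes = "character", edges = "data.frame"))

setValidity("LabeledGraph", function(object) {
  ed <- object@edges
  if (!all(c("head", "relation", "tail") %in% names(ed)))
    return("edges must have columns head, relation, tail")
  if (nrow(ed)) {
    if (!all(c(ed$head, ed$tail) %in% object@nodes))
      return("edge endpoint not in node set")
    if (any(ed$relation == "subClassOf" & ed$head == ed$tail))
      return("self-loop under subClassOf")
  }
  TRUE
})

#' Entity-to-term association table
#'
#' Maps entities (genes or diseases) to non-empty sets of ontology terms
#' under a single relation (\code{has_phenotype}, \code{has_symptom} or
#' \code{associated_with}).
#'
#' @slot relation single relation name.
#' @slot profiles named list; each element a non-empty character vector of
#'   target term identifiers, names are entity identifiers.
#' @exportClass AssociationTable
setClass("AssociationTable",
  representation(relation = "character", profiles = "list"))

setValidity("AssociationTable", function(object) {
  if (length(object@relation) != 1L || !nzchar(object@relation))
    return("relation must be a single non-empty string")
  pr <- object@profiles
  if (length(pr)) {
    if (is.null(names(pr)) || any(!nzchar(names(pr))) ||
        anyDuplicated(names(pr)))
      return("profiles must be uniquely named by entity")
    if (!all(vapply(pr, function(p) is.character(p) && length(p) > 0L,
                    logical(1))))
      return("each profile must be a non-empty character vector")
  }
  TRUE
})

#' Information-content table
#'
#' Per-term information content in nats, computed from an annotation corpus
#' with counts propagated through the subsumption closure.
#'
#' @slot ic named numeric vector, IC per term (nats, non-negative).
#' @slot corpusSize number of annotated entities in the corpus.
#' @exportClass ICTable
setClass("ICTable",
  representation(ic = "numeric", corpusSize = "integer"))

setValidity("ICTable", function(object) {
  if (is.null(names(object@ic))) return("ic must be named by term")
  if (any(object@ic < 0)) return("negative information content")
  if (object@corpusSize < 1L) return("corpusSize must be positive")
  TRUE
})

#' Trained knowledge-graph embedding set
#'
#' Holds entity and relation embedding tables for one of the supported
#' scoring models, plus the model-specific parameter blocks: relation
#' normals (TransH/TransD), entity projection vectors (TransD) and the
#' convolution parameters (ConvKB).
#'
#' @slot model one of \code{"transe"}, \code{"transh"}, \code{"transd"},
#'   \code{"convkb"}, \code{"convkb_d"}.
#' @slot entities numeric matrix, one row per entity (rownames are ids),
#'   \code{d} columns.
#' @slot relations numeric matrix, one row per relation; \code{d} columns
#'   (TransE/TransH/ConvKB) or \code{k} (TransD).
#' @slot relationNormals optional matrix \code{w_r} (TransH: d, TransD: k).
#' @slot entityProjections optional matrix of per-entity projection vectors
#'   \code{w_h}/\code{w_t} (TransD), \code{d} columns.
#' @slot convFilters optional tau-by-3 filter matrix (ConvKB).
#' @slot convWeight optional weight vector of length tau*d (ConvKB).
#' @slot convBias optional scalar bias (ConvKB).
#' @slot d embedding dimension.
#' @slot k projection dimension (TransD; equals \code{d} otherwise).
#' @exportClass EmbeddingSet
setClass("EmbeddingSet",
  representation(model = "character", entities = "matrix",
                 relations = "matrix", relationNormals = "matrixOrNULL",
                 entityProjections = "matrixOrNULL",
                 convFilters = "matrixOrNULL", convWeight = "numericOrNULL",
                 convBias = "numericOrNULL", d = "integer", k = "integer"))

setValidity("EmbeddingSet", function(object) {
  m <- object@model
  if (!m %in% c("transe", "transh", "transd", "convkb", "convkb_d"))
    return("unknown model")
  if (ncol(object@entities) != object@d)
    return("entity matrix width must equal d")
  rdim <- if (m == "transd") object@k else object@d
  if (ncol(object@relations) != rdim)
    return("relation matrix width inconsistent with model")
  if (m %in% c("transh", "transd") && is.null(object@relationNormals))
    return(sprintf("%s requires relationNormals", m))
  if (m == "transd" && is.null(object@entityProjections))
    return("transd requires entityProjections")
  if (m %in% c("convkb", "convkb_d")) {
    if (is.null(object@convFilters) || ncol(object@convFilters) != 3L)
      return("convkb requires tau-by-3 convFilters")
    if (is.null(object@convWeight) ||
        length(object@convWeight) != nrow(object@convFilters) * object@d)
      return("convWeight must have length tau*d")
    if (is.null(object@convBias) || length(object@convBias) != 1L)
      return("convkb requires a scalar convBias")
  }
  if (is.null(rownames(object@entities)) || is.null(rownames(object@relations)))
    return("entity and relation matrices must have rownames")
  TRUE
})

#' Training configuration for embedding models
#'
#' @slot model scoring model name.
#' @slot d embedding dimension.
#' @slot k projection dimension (TransD only; defaults to \code{d}).
#' @slot batchSize mini-batch size.
#' @slot lr learning rate.
#' @slot epochs number of passes over the edge set.
#' @slot margin margin gamma of the ranking loss (translational models).
#' @slot nNeg negatives sampled per positive.
#' @slot normOrder TransE norm order, 1 or 2.
#' @slot nFilters convolution filter count tau (ConvKB).
#' @slot seed integer seed; all training randomness derives from it.
#' @slot initFrom optional pretrained \linkS4class{EmbeddingSet} used to
#'   initialise ConvKB entity/relation tables.
#' @slot optimizer \code{"adam"} or \code{"sgd"}.
#' @slot normalizeEntities clamp entity norms to 1 after each epoch
#'   (translational models).
#' @slot lambda L2 penalty on the ConvKB weight vector.
#' @slot allowRandomConvInit permit ConvKB without pretrained init.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(model = "character", d = "integer", k = "integer",
                 batchSize = "integer", lr = "numeric", epochs = "integer",
                 margin = "numeric", nNeg = "integer", normOrder = "integer",
                 nFilters = "integer", seed = "integer", initFrom = "ANY",
                 optimizer = "character", normalizeEntities = "logical",
                 lambda = "numeric", allowRandomConvInit = "logical"))

setValidity("TrainConfig", function(object) {
  pos <- c(d = object@d, k = object@k, batchSize = object@batchSize,
           epochs = object@epochs, nNeg = object@nNeg + 1L,
           nFilters = object@nFilters)
  if (any(pos <= 0L)) return("all size parameters must be positive")
  if (object@lr <= 0 || object@margin < 0) return("lr must be > 0, margin >= 0")
  if (!object@normOrder %in% c(1L, 2L)) return("normOrder must be 1 or 2")
  if (!object@model %in% c("transe", "transh", "transd", "convkb", "convkb_d"))
    return("unknown model")
  if (!object@optimizer %in% c("adam", "sgd")) return("unknown optimizer")
  if (object@model %in% c("convkb", "convkb_d") &&
      is.null(object@initFrom) && !object@allowRandomConvInit)
    return("convkb models require initFrom (or allowRandomConvInit = TRUE)")
  if (!is.null(object@initFrom) && !is(object@initFrom, "EmbeddingSet"))
    return("initFrom must be an EmbeddingSet")
  TRUE
})

#' Gene-disease scorer
#'
#' Bundles a scoring strategy with its context.  Inductive kinds
#' (\code{bma_e}, \code{bmm_e}, \code{semantic_baseline}) only require the
#' query's phenotype terms to be known; transductive kinds
#' (\code{entity_sim}, \code{triple_score}) require the query entity itself
#' to have been embedded.
#'
#' @slot kind one of \code{"triple_score"}, \code{"entity_sim"},
#'   \code{"bma_e"}, \code{"bmm_e"}, \code{"semantic_baseline"}.
#' @slot relation relation used by \code{triple_score}.
#' @slot embedding \linkS4class{EmbeddingSet} context (embedding kinds).
#' @slot ic \linkS4class{ICTable} context (semantic baseline).
#' @slot ontology \linkS4class{Ontology} context (semantic baseline).
#' @slot measure pairwise measure for the semantic baseline
#'   (\code{"resnik"}, \code{"lin"}, \code{"simgic"}).
#' @slot aggregation \code{"bma"} or \code{"bmm"} (ignored for simgic).
#' @exportClass GDAScorer
setClass("GDAScorer",
  representation(kind = "character", relation = "character",
                 embedding = "ANY", ic = "ANY", ontology = "ANY",
                 measure = "character", aggregation = "character"))

setValidity("GDAScorer", function(object) {
  k <- object@kind
  if (!k %in% c("triple_score", "entity_sim", "bma_e", "bmm_e",
                "semantic_baseline"))
    return("unknown scorer kind")
  if (k %in% c("triple_score", "entity_sim", "bma_e", "bmm_e") &&
      !is(object@embedding, "EmbeddingSet"))
    return("embedding scorers need an EmbeddingSet context")
  if (k == "semantic_baseline" &&
      (!is(object@ic, "ICTable") || !is(object@ontology, "Ontology")))
    return("semantic_baseline needs ICTable and Ontology context")
  TRUE
})

#' Ranked gene list for one query disease
#'
#' @slot disease query disease identifier.
#' @slot entries data.frame with columns \code{gene}, \code{score}, sorted
#'   by non-increasing score (ties broken lexicographically by gene id).
#' @exportClass RankedList
setClass("RankedList",
  representation(disease = "character", entries = "data.frame"))

setValidity("RankedList", function(object) {
  en <- object@entries
  if (!all(c("gene", "score") %in% names(en)))
    return("entries must have columns gene, score")
  if (nrow(en)) {
    if (anyDuplicated(en$gene)) return("duplicate gene in ranking")
    if (any(diff(en$score) > 1e-12)) return("scores must be non-increasing")
  }
  TRUE
})

#' Ranked-retrieval metrics report
#'
#' @slot mr mean rank of true associations.
#' @slot mrr mean reciprocal rank.
#' @slot hits named numeric vector, fraction of ranks <= k per cutoff.
#' @slot auc mean normalised rank, i.e. the probability that a true
#'   association outranks a random non-association.
#' @slot nRecords number of rank records summarised.
#' @slot perFold optional list of per-fold MetricsReport objects.
#' @slot foldSD named numeric vector of across-fold sample standard
#'   deviations (aggregate reports only).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(mr = "numeric", mrr = "numeric", hits = "numeric",
                 auc = "numeric", nRecords = "integer", perFold = "list",
                 foldSD = "numeric"))

setValidity("MetricsReport", function(object) {
  if (object@mr < 1) return("mean rank below 1")
  if (object@mrr <= 0 || object@mrr > 1) return("mrr outside (0, 1]")
  if (length(object@hits) && is.unsorted(object@hits[order(as.numeric(names(object@hits)))]))
    return("hits must be non-decreasing in k")
  if (object@auc < 0 || object@auc > 1) return("auc outside [0, 1]")
  TRUE
})

## -- show methods ------------------------------------------------------------

setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology: %d classes, %d roles, %d individuals, %d axioms\n",
              length(object@classes), length(object@roles),
              length(object@individuals), nrow(object@axioms)))
  if (nrow(object@axioms))
    print(table(object@axioms$kind))
})

setMethod("show", "LabeledGraph", function(object) {
  cat(sprintf("LabeledGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges))
    print(table(object@edges$relation))
})

setMethod("show", "AssociationTable", function(object) {
  n <- length(object@profiles)
  cat(sprintf("AssociationTable <%s>: %d entities, %d pairs\n",
              object@relation, n,
              if (n) sum(lengths(object@profiles)) else 0L))
})

setMethod("show", "ICTable", function(object) {
  cat(sprintf("ICTable: %d terms, corpus of %d entities, max IC %.4f nats\n",
              length(object@ic), object@corpusSize, max(object@ic)))
})

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet <%s>: %d entities, %d relations, d = %d%s\n",
              object@model, nrow(object@entities), nrow(object@relations),
              object@d,
              if (object@model == "transd") sprintf(", k = %d", object@k) else ""))
})

setMethod("show", "GDAScorer", function(object) {
  cat(sprintf("GDAScorer <%s>%s\n", object@kind,
              if (object@kind == "semantic_baseline")
                sprintf(" [%s/%s]", object@measure, object@aggregation)
              else ""))
})

setMethod("show", "RankedList", function(object) {
  cat(sprintf("RankedList for %s: %d candidates\n",
              object@disease, nrow(object@entries)))
  print(utils::head(object@entries, 5))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d records\n", object@nRecords))
  cat(sprintf("  MR %.2f | MRR %.4f | AUC %.4f\n",
              object@mr, object@mrr, object@auc))
  if (length(object@hits))
    cat("  Hits@k:", paste(sprintf("%s=%.3f", names(object@hits),
                                   object@hits), collapse = " "), "\n")
})

## -- accessors ---------------------------------------------------------------

#' Accessors for PhenoGDA classes
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
ontologyClasses <- function(x) x@classes

#' @rdname accessors
#' @export
ontologyRoles <- function(x) x@roles

#' @rdname accessors
#' @export
axioms <- function(x) x@axioms

#' @rdname accessors
#' @export
graphNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
graphEdges <- function(x) x@edges

#' @rdname accessors
#' @export
profiles <- function(x) x@profiles

#' @rdname accessors
#' @export
relationName <- function(x) x@relation

#' @rdname accessors
#' @export
icValues <- function(x) x@ic

#' @rdname accessors
#' @export
corpusSize <- function(x) x@corpusSize

#' @rdname accessors
#' @export
entityVectors <- function(x) x@entities

#' @rdname accessors
#' @export
relationVectors <- function(x) x@relations

#' @rdname accessors
#' @export
embeddingModel <- function(x) x@model

#' @rdname accessors
#' @export
rankedEntries <- function(x) x@entries

#' @rdname accessors
#' @export
queryDisease <- function(x) x@disease

#' @rdname accessors
#' @export
meanRank <- function(x) x@mr

#' @rdname accessors
#' @export
meanReciprocalRank <- function(x) x@mrr

#' @rdname accessors
#' @export
hitsAtK <- function(x) x@hits

#' @rdname accessors
#' @export
rankingAUC <- function(x) x@auc

#' @rdname accessors
#' @export
foldSD <- function(x) x@foldSD

#' @rdname accessors
#' @export
perFold <- function(x) x@perFold
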