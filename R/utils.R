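## Internal helpers shared across modules.

#' @importFrom igraph graph_from_data_frame is_dag components V
NULL

## Detect a cycle in the SubClassOf relation restricted to classes.
## Returns NULL when acyclic, otherwise the node names of one strongly
## connected component witnessing the cycle.
.findSubsumptionCycle <- function(ax) {
  sub <- ax[ax$kind == "SubClassOf" & ax$subject != ax$object, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  g <- igraph::graph_from_data_frame(sub[, c("subject", "object")],
                                     directed = TRUE)
  if (igraph::is_dag(g)) return(NULL)
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1L]
  sort(names(comp$membership)[comp$membership == big])
}

#' Reflexive ancestor closure of ontology classes
#'
#' Computes, for each requested class, the set of classes reachable through
#' \code{SubClassOf} axioms, treating \code{EquivalentTo} axioms as mutual
#' subsumption (so equivalent terms -- e.g. cross-species bridged phenotype
#' classes -- are mutual ancestors).  The closure is reflexive: every term
#' is its own ancestor.  Existential-restriction axioms are not
#' subsumptions and are ignored.
#'
#' @param ontology an \linkS4class{Ontology}.
#' @param terms character vector of terms to close over; default all
#'   classes.
#' @return Named list of character vectors of ancestor ids.
#' @export
ancestorClosure <- function(ontology, terms = NULL) {
  cls <- sort(ontology@classes)
  if (is.null(terms)) terms <- cls
  stopifnot(all(terms %in% cls))
  ax <- ontology@axioms
  up <- ax[ax$kind == "SubClassOf", c("subject", "object"), drop = FALSE]
  eq <- ax[ax$kind == "EquivalentTo", c("subject", "object"), drop = FALSE]
  if (nrow(eq))
    up <- rbind(up, eq, stats::setNames(eq[, 2:1], c("subject", "object")))
  idx <- seq_along(cls)
  names(idx) <- cls
  ## parent adjacency restricted to classes (association subjects may be
  ## individuals or entity classes; those are included via `cls` already)
  keep <- up$subject %in% cls & up$object %in% cls
  up <- up[keep, , drop = FALSE]
  adj <- split(unname(idx[up$object]), idx[up$subject])
  nAdj <- vector("list", length(cls))
  nAdj[as.integer(names(adj))] <- adj
  res <- lapply(terms, function(t) {
    start <- idx[[t]]
    seen <- logical(length(cls))
    seen[start] <- TRUE
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(nAdj[frontier], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    cls[seen]
  })
  names(res) <- terms
  res
}

#' Derive a component seed from a master seed
#'
#' All randomised components (fold splits, embedding initialisation,
#' negative sampling, synthetic data) draw their seeds from one master seed
#' through this mixing function, so a single integer reproduces an entire
#' experiment.  The map is a fixed-multiplier congruential hash modulo
#' 2^31 - 1; distinct stream indices give well-separated seeds.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream index.
#' @return A positive integer seed below 2^31.
#' @export
deriveSeed <- function(master, stream = 0L) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 69069 + as.numeric(stream) * 104729 + 12345) %% m
  x <- (x * 69069 + 1) %% m
  as.integer(x + 1)
}

## stop() with a consistent prefix-free message, sprintf-style
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## message-level logging to stderr
.logmsg <- function(fmt, ...) message(sprintf(fmt, ...))
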