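## Classical IC-based similarity baselines: information content over an
## annotation corpus, MICA, Resnik, Lin, and the groupwise aggregations
## BMA, BMM and SimGIC.

#' Compute information content from an annotation corpus
#'
#' Annotation counts are propagated through the reflexive subsumption
#' closure: an entity annotated to a term counts once for the term and for
#' each of its ancestors.  The term frequency is then
#' \code{P(p) = count(p) / n}, with \code{n} the number of annotated
#' entities, and \code{IC(p) = -ln P(p)} in nats.  Terms with zero
#' propagated count receive the maximal attainable single-annotation IC,
#' \code{ln(n)}, keeping Lin and SimGIC finite on sparse corpora.
#'
#' The corpus is typically the gene-phenotype table alone; pass a list of
#' tables to pool genes and diseases.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param corpus an \linkS4class{AssociationTable} or a list of them.
#' @return An \linkS4class{ICTable} covering every ontology class.
#' @export
computeIC <- function(ont, corpus) {
  if (is(corpus, "AssociationTable")) corpus <- list(corpus)
  prof <- do.call(c, lapply(corpus, function(x) x@profiles))
  if (!length(prof)) .err("empty annotation corpus")
  allTerms <- unique(unlist(prof, use.names = FALSE))
  unknown <- setdiff(allTerms, ont@classes)
  if (length(unknown))
    .err("corpus references term(s) absent from the ontology: %s",
         paste(utils::head(unknown, 3), collapse = ", "))
  anc <- ancestorClosure(ont, allTerms)
  counts <- stats::setNames(numeric(length(ont@classes)),
                            sort(ont@classes))
  for (p in prof) {
    hit <- unique(unlist(anc[p], use.names = FALSE))
    counts[hit] <- counts[hit] + 1
  }
  n <- length(prof)
  ic <- ifelse(counts > 0, -log(counts / n), log(n))
  new("ICTable", ic = ic, corpusSize = as.integer(n))
}

#' Most informative common ancestor
#'
#' Returns the common ancestor (under the reflexive subsumption closure)
#' of two terms maximising information content; the IC value of the MICA
#' is unique even when several ancestors attain it.  If the terms share no
#' ancestor, the single ontology root is returned with IC 0 when one
#' exists; multiple disconnected roots are an error.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param ic an \linkS4class{ICTable}.
#' @param p1,p2 class identifiers.
#' @param anc optional precomputed \code{\link{ancestorClosure}}.
#' @return list with elements \code{term} and \code{ic}.
#' @export
mica <- function(ont, ic, p1, p2, anc = NULL) {
  if (is.null(anc)) anc <- ancestorClosure(ont, unique(c(p1, p2)))
  common <- intersect(anc[[p1]], anc[[p2]])
  if (!length(common)) {
    root <- .ontologyRoots(ont)
    if (length(root) != 1L)
      .err("no common ancestor of %s and %s and no unique root", p1, p2)
    return(list(term = root, ic = 0))
  }
  vals <- ic@ic[common]
  best <- which.max(vals)
  list(term = common[best], ic = unname(vals[best]))
}

.ontologyRoots <- function(ont) {
  ax <- ont@axioms
  up <- ax[ax$kind == "SubClassOf" & ax$subject != ax$object, ]
  sort(setdiff(ont@classes, up$subject))
}

#' Pairwise term similarity (Resnik, Lin)
#'
#' Resnik similarity is the IC of the most informative common ancestor;
#' Lin similarity normalises it by the mean IC of the two terms,
#' \code{2 IC(MICA) / (IC(p1) + IC(p2))}, defined as 0 when the
#' denominator vanishes.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param ic an \linkS4class{ICTable}.
#' @param p1,p2 class identifiers.
#' @param measure \code{"resnik"} or \code{"lin"}.
#' @param anc optional precomputed ancestor closure.
#' @return A similarity value; Resnik in \code{[0, ln corpusSize]} nats,
#'   Lin in \code{[0, 1]}.
#' @export
termSim <- function(ont, ic, p1, p2, measure = c("resnik", "lin"),
                    anc = NULL) {
  measure <- match.arg(measure)
  m <- mica(ont, ic, p1, p2, anc = anc)
  if (measure == "resnik") return(m$ic)
  denom <- ic@ic[[p1]] + ic@ic[[p2]]
  if (denom == 0) 0 else 2 * m$ic / denom
}

## Pairwise similarity matrix between two term sets (rows: A, cols: B),
## sharing one ancestor-closure computation.
.termSimMatrix <- function(ont, ic, termsA, termsB,
                           measure = c("resnik", "lin"), anc = NULL) {
  measure <- match.arg(measure)
  terms <- unique(c(termsA, termsB))
  if (is.null(anc)) anc <- ancestorClosure(ont, terms)
  icv <- ic@ic
  M <- matrix(0, length(termsA), length(termsB),
              dimnames = list(termsA, termsB))
  ancB <- anc[termsB]
  for (i in seq_along(termsA)) {
    ai <- anc[[termsA[i]]]
    for (j in seq_along(termsB)) {
      common <- intersect(ai, ancB[[j]])
      M[i, j] <- if (length(common)) max(icv[common]) else 0
    }
  }
  if (measure == "lin") {
    denom <- outer(icv[termsA], icv[termsB], `+`)
    M <- ifelse(denom == 0, 0, 2 * M / denom)
  }
  M
}

## Directional best-match aggregation of a pairwise similarity matrix.
## bma: mean of the two directional best-match averages; bmm: their max.
.bestMatchAggregate <- function(M, aggregation = c("bma", "bmm")) {
  aggregation <- match.arg(aggregation)
  rowBest <- mean(apply(M, 1, max))
  colBest <- mean(apply(M, 2, max))
  if (aggregation == "bma") (rowBest + colBest) / 2 else max(rowBest, colBest)
}

#' Groupwise similarity between two annotation profiles
#'
#' For \code{aggregation} \code{"bma"}/\code{"bmm"}, the pairwise Resnik
#' or Lin matrix between the two term sets is reduced by best-match
#' average (mean of the two directional best-match means) or best-match
#' maximum (their maximum).  For \code{aggregation = "simgic"} the
#' IC-weighted Jaccard of the reflexive ancestor closures of the two sets
#' is returned (the pairwise measure is ignored); a vanishing denominator
#' yields 0.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param ic an \linkS4class{ICTable}.
#' @param pg,pd non-empty character vectors of class identifiers (the two
#'   annotation profiles).
#' @param measure pairwise kernel for bma/bmm: \code{"resnik"} or
#'   \code{"lin"}.
#' @param aggregation \code{"bma"}, \code{"bmm"} or \code{"simgic"}.
#' @param anc optional precomputed ancestor closure.
#' @return A similarity value.
#' @export
groupSim <- function(ont, ic, pg, pd, measure = c("resnik", "lin"),
                     aggregation = c("bma", "bmm", "simgic"), anc = NULL) {
  aggregation <- match.arg(aggregation)
  if (!length(pg) || !length(pd)) .err("empty annotation profile")
  if (aggregation == "simgic") {
    if (is.null(anc)) anc <- ancestorClosure(ont, unique(c(pg, pd)))
    cg <- unique(unlist(anc[pg], use.names = FALSE))
    cd <- unique(unlist(anc[pd], use.names = FALSE))
    icv <- ic@ic
    denom <- sum(icv[union(cg, cd)])
    if (denom == 0) return(0)
    return(sum(icv[intersect(cg, cd)]) / denom)
  }
  M <- .termSimMatrix(ont, ic, pg, pd, measure = measure, anc = anc)
  .bestMatchAggregate(M, aggregation)
}

#' Write / read an IC table as TSV
#'
#' @param ic an \linkS4class{ICTable}.
#' @param path file path.
#' @return \code{path} (write) or an \linkS4class{ICTable} (read; the
#'   corpus size is stored in a comment line).
#' @export
writeICTable <- function(ic, path) {
  lines <- c(sprintf("# corpus_size\t%d", ic@corpusSize), "term\tic",
             paste(names(ic@ic), formatC(ic@ic, digits = 17, format = "g"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeICTable
#' @export
readICTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cs <- as.integer(sub("^# corpus_size\t", "", lines[1]))
  tab <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE)
  new("ICTable", ic = stats::setNames(tab$ic, tab$term),
      corpusSize = cs)
}
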