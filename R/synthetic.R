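## Desk-scale synthetic two-species phenome: a mouse-like and a human-like
## phenotype tree bridged by cross-species equivalence axioms, with
## module-structured gene/disease annotations and planted gene-disease
## associations, so every pipeline stage is testable without external
## downloads.

#' Synthetic phenome configuration
#'
#' The default preset is desk-scale: two complete 3-ary trees of depth 4
#' (81 leaves, 121 terms per species) under a shared root, 6 aligned
#' cross-species leaf modules, 60 genes and 30 diseases annotated with
#' 4-8 mostly-within-module leaf terms, one planted causative gene per
#' disease, 90% of aligned leaf pairs bridged by an equivalence axiom and
#' 10% off-module annotation noise.
#'
#' @param nModules number of aligned cross-species modules.
#' @param depth tree depth (levels below each species root).
#' @param branching children per internal node.
#' @param nGenes,nDiseases entity counts.
#' @param annotationsPerEntity integer range (min, max) of annotations
#'   drawn per gene/disease.
#' @param bridgeRate probability that an aligned leaf pair is bridged by
#'   an equivalence axiom.
#' @param annotationNoise fraction of annotations redrawn from
#'   off-module leaves.
#' @param gdaPerDisease planted causative genes per disease.
#' @param seed integer seed.
#' @return A validated config list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(nModules = 6L, depth = 4L, branching = 3L,
                        nGenes = 60L, nDiseases = 30L,
                        annotationsPerEntity = c(4L, 8L),
                        bridgeRate = 0.9, annotationNoise = 0.1,
                        gdaPerDisease = 1L, seed = 1L) {
  cfg <- list(nModules = as.integer(nModules), depth = as.integer(depth),
              branching = as.integer(branching),
              nGenes = as.integer(nGenes),
              nDiseases = as.integer(nDiseases),
              annotationsPerEntity = as.integer(annotationsPerEntity),
              bridgeRate = bridgeRate, annotationNoise = annotationNoise,
              gdaPerDisease = as.integer(gdaPerDisease),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("nModules", "depth", "branching", "nGenes",
                         "nDiseases", "gdaPerDisease")])
  if (any(counts <= 0L)) .err("all counts must be positive")
  if (length(cfg$annotationsPerEntity) != 2L ||
      any(cfg$annotationsPerEntity <= 0L) ||
      cfg$annotationsPerEntity[1] > cfg$annotationsPerEntity[2])
    .err("annotationsPerEntity must be an increasing positive pair")
  if (cfg$bridgeRate < 0 || cfg$bridgeRate > 1 ||
      cfg$annotationNoise < 0 || cfg$annotationNoise > 1)
    .err("rates must be in [0, 1]")
  class(cfg) <- "SynthConfig"
  cfg
}

## complete branching^depth tree; returns list(axioms rows, leaves, all ids)
.speciesTree <- function(prefix, depth, branching) {
  root <- sprintf("%s:%07d", prefix, 0L)
  ids <- root
  levels <- list(root)
  counter <- 0L
  subj <- obj <- character()
  for (lev in seq_len(depth)) {
    parents <- levels[[lev]]
    children <- character()
    for (p in parents) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("%s:%07d", prefix, counter)
        children <- c(children, id)
        subj <- c(subj, id)
        obj <- c(obj, p)
      }
    }
    levels[[lev + 1L]] <- children
    ids <- c(ids, children)
  }
  list(root = root, ids = ids, leaves = levels[[depth + 1L]],
       subj = subj, obj = obj)
}

#' Generate a synthetic two-species phenome
#'
#' Builds two disjoint rooted phenotype trees ("MPX:" mouse-like, "HPX:"
#' human-like) under a shared root, partitions the leaves into aligned
#' cross-species modules, bridges aligned leaf pairs with equivalence
#' axioms at the bridge rate, annotates genes with MPX leaves and
#' diseases with HPX leaves mostly within one module (with off-module
#' noise), and plants each disease's causative genes inside its own
#' module.  Genes and diseases are assigned to modules round-robin.
#' Byte-identical output under a fixed seed.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list with elements \code{ontology}, \code{geneAssoc},
#'   \code{diseaseAssoc}, \code{gdaAssoc} and \code{modules} (the module
#'   assignment bookkeeping, useful in tests).
#' @export
generatePhenome <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  mp <- .speciesTree("MPX", config$depth, config$branching)
  hp <- .speciesTree("HPX", config$depth, config$branching)
  root <- "UPX:0000000"
  subj <- c(mp$subj, hp$subj, mp$root, hp$root)
  obj <- c(mp$obj, hp$obj, root, root)
  kind <- rep("SubClassOf", length(subj))
  rel <- rep(NA_character_, length(subj))

  nLeaves <- length(mp$leaves)
  if (nLeaves < config$nModules) .err("fewer leaves than modules")
  moduleOf <- rep(seq_len(config$nModules), length.out = nLeaves)
  moduleOf <- sort(moduleOf)                 # contiguous aligned blocks
  minModule <- min(table(moduleOf))
  annMax <- config$annotationsPerEntity[2]
  if (annMax > minModule)
    .err("module too small for requested annotations (%d leaves < %d)",
         minModule, annMax)

  bridged <- stats::runif(nLeaves) < config$bridgeRate
  if (any(bridged)) {
    subj <- c(subj, mp$leaves[bridged])
    obj <- c(obj, hp$leaves[bridged])
    kind <- c(kind, rep("EquivalentTo", sum(bridged)))
    rel <- c(rel, rep(NA_character_, sum(bridged)))
  }
  ont <- ontology(data.frame(subject = subj, kind = kind, relation = rel,
                             object = obj, stringsAsFactors = FALSE))

  drawProfile <- function(leaves) {
    nAnn <- sample(seq(config$annotationsPerEntity[1],
                       config$annotationsPerEntity[2]), 1L)
    moduleLeaves <- leaves
    terms <- sample(moduleLeaves, nAnn)
    noisy <- stats::runif(nAnn) < config$annotationNoise
    if (any(noisy)) {
      pool <- setdiff(if (startsWith(leaves[1], "MPX")) mp$leaves
                      else hp$leaves, moduleLeaves)
      terms[noisy] <- sample(pool, sum(noisy))
    }
    sort(unique(terms))
  }

  geneModule <- rep(seq_len(config$nModules), length.out = config$nGenes)
  genes <- sprintf("GENE:%04d", seq_len(config$nGenes))
  geneProf <- lapply(seq_len(config$nGenes), function(i)
    drawProfile(mp$leaves[moduleOf == geneModule[i]]))
  names(geneProf) <- genes

  diseaseModule <- rep(seq_len(config$nModules),
                       length.out = config$nDiseases)
  diseases <- sprintf("DIS:%04d", seq_len(config$nDiseases))
  diseaseProf <- lapply(seq_len(config$nDiseases), function(i)
    drawProfile(hp$leaves[moduleOf == diseaseModule[i]]))
  names(diseaseProf) <- diseases

  gdaProf <- lapply(seq_len(config$nDiseases), function(i) {
    pool <- genes[geneModule == diseaseModule[i]]
    if (length(pool) < config$gdaPerDisease)
      .err("module %d has too few genes for %d associations per disease",
           diseaseModule[i], config$gdaPerDisease)
    sort(sample(pool, config$gdaPerDisease))
  })
  names(gdaProf) <- diseases

  list(ontology = ont,
       geneAssoc = associationTable("has_phenotype", geneProf),
       diseaseAssoc = associationTable("has_symptom", diseaseProf),
       gdaAssoc = associationTable("associated_with", gdaProf),
       modules = list(leafModule = moduleOf, geneModule = geneModule,
                      diseaseModule = diseaseModule,
                      mpLeaves = mp$leaves, hpLeaves = hp$leaves,
                      bridged = bridged))
}

#' Random single-rooted DAG ontology
#'
#' Substrate for semantic-similarity oracle tests: term 1 is the root;
#' every later term subsumes under 1-2 uniformly chosen earlier terms, so
#' the result is acyclic, single-rooted and fully connected to the root.
#'
#' @param nTerms number of terms (>= 2).
#' @param seed integer seed.
#' @param maxParents maximum parents per term.
#' @return An \linkS4class{Ontology} of SubClassOf axioms.
#' @export
randomDAG <- function(nTerms, seed = 1L, maxParents = 2L) {
  if (nTerms < 2L) .err("need at least 2 terms")
  set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(nTerms))
  subj <- obj <- character()
  for (i in 2:nTerms) {
    np <- sample.int(min(maxParents, i - 1L), 1L)
    parents <- if (i == 2L) 1L else sample.int(i - 1L, np)
    subj <- c(subj, rep(ids[i], length(parents)))
    obj <- c(obj, ids[parents])
  }
  ontology(data.frame(subject = subj, kind = "SubClassOf",
                      relation = NA_character_, object = obj,
                      stringsAsFactors = FALSE))
}

#' Random annotation corpus over a DAG's terms
#'
#' Convenience generator for oracle tests: each entity is annotated with
#' 1-\code{maxTerms} uniformly drawn ontology classes.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param nEntities number of corpus entities.
#' @param maxTerms maximum annotations per entity.
#' @param seed integer seed.
#' @param prefix entity id prefix.
#' @return An \linkS4class{AssociationTable} (\code{has_phenotype}).
#' @export
randomCorpus <- function(ont, nEntities, maxTerms = 3L, seed = 1L,
                         prefix = "G") {
  set.seed(seed)
  cls <- sort(ont@classes)
  prof <- lapply(seq_len(nEntities), function(i)
    sort(unique(sample(cls, sample.int(maxTerms, 1L), replace = TRUE))))
  names(prof) <- sprintf("%s:%04d", prefix, seq_len(nEntities))
  associationTable("has_phenotype", prof)
}
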