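## Ontology construction, association augmentation, graph projection and
## the six graph variants used for embedding training.

#' Construct an Ontology from an axiom data.frame
#'
#' The signature is inferred from the axioms: subjects and objects become
#' classes, restriction relations become roles.  Additional signature
#' elements (isolated classes, individuals) can be supplied explicitly.
#'
#' @param axioms data.frame with columns \code{subject}, \code{kind},
#'   \code{relation}, \code{object}.
#' @param classes,roles,individuals extra signature elements.
#' @return An \linkS4class{Ontology}.
#' @export
ontology <- function(axioms = data.frame(subject = character(),
                                         kind = character(),
                                         relation = character(),
                                         object = character(),
                                         stringsAsFactors = FALSE),
                     classes = character(), roles = character(),
                     individuals = character()) {
  axioms$relation <- as.character(axioms$relation)
  if (nrow(axioms)) axioms$relation[axioms$relation %in% c("-", "")] <- NA
  cls <- sort(unique(c(classes, axioms$subject, axioms$object)))
  rls <- sort(unique(c(roles, axioms$relation[!is.na(axioms$relation)])))
  new("Ontology", classes = cls, roles = rls,
      individuals = sort(unique(individuals)),
      axioms = axioms[, c("subject", "kind", "relation", "object")])
}

#' Parse an ontology from a flat file
#'
#' Two dialects are supported. The axiom TSV dialect has a header
#' \code{subject<TAB>kind<TAB>relation<TAB>object}, with \code{"-"} in the
#' relation column when absent and \code{#}-prefixed comment lines.  The
#' OBO-subset dialect reads \code{[Term]} stanzas with \code{id:},
#' \code{is_a:}, \code{relationship: <rel> <id>} and \code{equivalent_to:}
#' tags only (names, definitions and other decoration are skipped); any
#' other OBO construct carrying logical content is rejected.
#'
#' The reserved relation names (\code{subClassOf}, \code{has_phenotype},
#' \code{has_symptom}, \code{associated_with}) may not appear as ontology
#' roles.
#'
#' @param path file path.
#' @param format \code{"auto"} (sniff by extension/first line),
#'   \code{"tsv"} or \code{"obo"}.
#' @return An \linkS4class{Ontology}.
#' @export
parseOntology <- function(path, format = c("auto", "tsv", "obo")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (format == "auto") {
    format <- if (grepl("\\.obo$", path) ||
                  any(startsWith(lines, "[Term]"))) "obo" else "tsv"
  }
  ont <- if (format == "obo") .parseOBO(lines) else .parseAxiomTSV(lines)
  bad <- intersect(ont@roles, .RESERVED_RELATIONS)
  if (length(bad))
    .err("ontology roles collide with reserved relation name(s): %s",
         paste(bad, collapse = ", "))
  validObject(ont)
  ont
}

.parseAxiomTSV <- function(lines) {
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(ontology())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (!identical(hdr[1:4], c("subject", "kind", "relation", "object")))
    .err("line %d: expected header 'subject\tkind\trelation\tobject'", keep[1])
  fields <- fields[-1]
  rows <- keep[-1]
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    .err("line %d: expected 4 tab-separated fields, found %d",
         rows[bad[1]], lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  kinds <- m[, 2]
  badk <- which(!kinds %in% .AXIOM_KINDS)
  if (length(badk))
    .err("line %d: unknown axiom kind '%s'", rows[badk[1]], kinds[badk[1]])
  needRel <- kinds == "SubClassOfSome"
  badr <- which(needRel & m[, 3] == "-")
  if (length(badr))
    .err("line %d: SubClassOfSome requires a relation", rows[badr[1]])
  badr2 <- which(!needRel & m[, 3] != "-")
  if (length(badr2))
    .err("line %d: relation given for non-restriction axiom", rows[badr2[1]])
  ontology(data.frame(subject = m[, 1], kind = kinds, relation = m[, 3],
                      object = m[, 4], stringsAsFactors = FALSE))
}

.parseOBO <- function(lines) {
  inTerm <- FALSE
  cur <- NULL
  subj <- kind <- rel <- obj <- character()
  classes <- character()
  flushTerm <- function() {}
  skipTags <- c("name", "def", "comment", "namespace", "synonym", "xref",
                "subset", "created_by", "creation_date", "alt_id",
                "property_value", "is_obsolete")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "[")) {
      inTerm <- identical(ln, "[Term]")
      cur <- NULL
      next
    }
    if (!inTerm) next
    if (!grepl(":", ln, fixed = TRUE)) .err("line %d: malformed OBO line", i)
    tag <- sub(":.*$", "", ln)
    val <- trimws(sub("^[^:]+:", "", ln))
    val <- trimws(sub("!.*$", "", val))          # strip trailing comments
    if (tag == "id") {
      cur <- val
      classes <- c(classes, val)
    } else if (tag == "is_a") {
      if (is.null(cur)) .err("line %d: is_a before id", i)
      subj <- c(subj, cur); kind <- c(kind, "SubClassOf")
      rel <- c(rel, NA); obj <- c(obj, val)
    } else if (tag == "relationship") {
      parts <- strsplit(val, "[ \t]+")[[1]]
      if (length(parts) != 2L) .err("line %d: malformed relationship", i)
      subj <- c(subj, cur); kind <- c(kind, "SubClassOfSome")
      rel <- c(rel, parts[1]); obj <- c(obj, parts[2])
    } else if (tag == "equivalent_to") {
      subj <- c(subj, cur); kind <- c(kind, "EquivalentTo")
      rel <- c(rel, NA); obj <- c(obj, val)
    } else if (tag %in% skipTags) {
      next
    } else {
      .err("line %d: unsupported OBO construct '%s'", i, tag)
    }
  }
  ontology(data.frame(subject = subj, kind = kind, relation = rel,
                      object = obj, stringsAsFactors = FALSE),
           classes = classes)
}

#' Write an ontology to the axiom TSV dialect
#'
#' Isolated classes (no axiom) are preserved as degenerate reflexive-free
#' entries only through the signature, so the round trip
#' \code{parseOntology(writeOntologyTSV(x))} reproduces the axiom multiset.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOntologyTSV <- function(ont, path) {
  ax <- ont@axioms
  rel <- ifelse(is.na(ax$relation), "-", ax$relation)
  lines <- c("subject\tkind\trelation\tobject",
             if (nrow(ax)) paste(ax$subject, ax$kind, rel, ax$object,
                                 sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an AssociationTable
#'
#' @param relation one of \code{"has_phenotype"}, \code{"has_symptom"},
#'   \code{"associated_with"}.
#' @param profiles named list mapping entity ids to character vectors of
#'   target term ids.
#' @return An \linkS4class{AssociationTable}.
#' @export
associationTable <- function(relation, profiles = list()) {
  profiles <- lapply(profiles, function(p) sort(unique(as.character(p))))
  if (length(profiles)) profiles <- profiles[order(names(profiles))]
  new("AssociationTable", relation = relation, profiles = profiles)
}

#' Add association axioms to an ontology
#'
#' Each (entity, term) pair becomes an existential-restriction axiom
#' \code{entity SubClassOf <relation> some term}; entities enter the
#' signature as classes.  For the phenotype relations
#' (\code{has_phenotype}, \code{has_symptom}) pairs whose target term is
#' absent from the ontology are dropped with a logged count, mirroring the
#' upstream filtering of annotations against the ontology release.  The
#' input ontology is not modified.
#'
#' @param ont an \linkS4class{Ontology}.
#' @param assoc an \linkS4class{AssociationTable}.
#' @return A new \linkS4class{Ontology} with the added axioms.
#' @export
addAssociationAxioms <- function(ont, assoc) {
  rel <- assoc@relation
  if (rel %in% ont@roles && !rel %in% .RESERVED_RELATIONS)
    .err("relation '%s' collides with an ontology role", rel)
  prof <- assoc@profiles
  if (!length(prof)) return(ont)
  ents <- rep(names(prof), lengths(prof))
  targets <- unlist(prof, use.names = FALSE)
  if (rel %in% c("has_phenotype", "has_symptom")) {
    known <- targets %in% ont@classes
    if (any(!known))
      .logmsg("dropping %d association(s) with term(s) absent from the ontology",
              sum(!known))
    ents <- ents[known]
    targets <- targets[known]
  }
  if (!length(ents)) return(ont)
  ax <- rbind(ont@axioms,
              data.frame(subject = ents, kind = "SubClassOfSome",
                         relation = rel, object = targets,
                         stringsAsFactors = FALSE))
  ontology(ax, classes = ont@classes, roles = ont@roles,
           individuals = ont@individuals)
}

#' Project an ontology to a labeled directed graph
#'
#' Structural projection rules for the supported axiom dialect:
#' \itemize{
#'   \item \code{C SubClassOf D} becomes the edge \code{(C, subClassOf, D)};
#'   \item \code{C SubClassOf R some D} becomes \code{(C, R, D)};
#'   \item \code{C EquivalentTo D} becomes the reciprocal pair
#'     \code{(C, subClassOf, D)} and \code{(D, subClassOf, C)}, so
#'     equivalent (e.g. cross-species bridged) terms are mutual ancestors.
#' }
#' Nodes are the terms appearing in projected edges plus isolated
#' signature classes.  Reflexive subsumptions are dropped.  Projection is
#' deterministic: edges are returned sorted by (relation, head, tail).
#'
#' @param ont an \linkS4class{Ontology}.
#' @param inverse also materialise inverse edges, labeled
#'   \code{<relation>_inv} (off by default, keeping the taxonomy graph
#'   pure).
#' @return A \linkS4class{LabeledGraph}.
#' @export
projectGraph <- function(ont, inverse = FALSE) {
  ax <- ont@axioms
  heads <- character(); rels <- character(); tails <- character()
  if (nrow(ax)) {
    sub <- ax[ax$kind == "SubClassOf" & ax$subject != ax$object, ]
    some <- ax[ax$kind == "SubClassOfSome", ]
    eq <- ax[ax$kind == "EquivalentTo" & ax$subject != ax$object, ]
    heads <- c(sub$subject, some$subject, eq$subject, eq$object)
    rels <- c(rep("subClassOf", nrow(sub)), some$relation,
              rep("subClassOf", 2L * nrow(eq)))
    tails <- c(sub$object, some$object, eq$object, eq$subject)
  }
  edges <- unique(data.frame(head = heads, relation = rels, tail = tails,
                             stringsAsFactors = FALSE))
  if (inverse && nrow(edges)) {
    inv <- data.frame(head = edges$tail,
                      relation = paste0(edges$relation, "_inv"),
                      tail = edges$head, stringsAsFactors = FALSE)
    edges <- unique(rbind(edges, inv))
  }
  nodes <- sort(unique(c(edges$head, edges$tail, ont@classes,
                         ont@individuals)))
  edges <- edges[order(edges$relation, edges$head, edges$tail), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new("LabeledGraph", nodes = nodes, edges = edges)
}

#' Build one of the six graph variants
#'
#' Increasing-information graph variants over a fixed ontology:
#' \describe{
#'   \item{G1}{the projected ontology only (no gene or disease nodes);}
#'   \item{G2}{G1 plus gene-phenotype edges;}
#'   \item{G3}{G2 plus training-disease phenotype edges;}
#'   \item{G4}{G3 plus training gene-disease association edges;}
#'   \item{G3T, G4T}{transductive variants that additionally contain the
#'     test diseases' phenotype edges -- but never their gene-disease
#'     edges.}
#' }
#' For the inductive variants (G1-G4) no test-disease identifier occurs in
#' the graph at all.  As a leakage guard, a gene-disease association
#' involving a test disease in the input is a hard error for every
#' variant.
#'
#' @param ont the phenotype \linkS4class{Ontology}.
#' @param geneAssoc gene-phenotype \linkS4class{AssociationTable}
#'   (\code{has_phenotype}).
#' @param diseaseAssoc disease-phenotype \linkS4class{AssociationTable}
#'   (\code{has_symptom}).
#' @param gdaAssoc disease-gene \linkS4class{AssociationTable}
#'   (\code{associated_with}; entities are diseases, targets genes),
#'   restricted to training diseases.
#' @param variant one of \code{"G1"}, \code{"G2"}, \code{"G3"},
#'   \code{"G4"}, \code{"G3T"}, \code{"G4T"}.
#' @param testDiseases character vector of held-out disease ids.
#' @param inverse passed on to \code{\link{projectGraph}}.
#' @return A \linkS4class{LabeledGraph}.
#' @export
buildGraphVariant <- function(ont, geneAssoc, diseaseAssoc, gdaAssoc,
                              variant = c("G1", "G2", "G3", "G4", "G3T",
                                          "G4T"),
                              testDiseases = character(),
                              inverse = FALSE) {
  variant <- match.arg(variant)
  leak <- intersect(names(gdaAssoc@profiles), testDiseases)
  if (length(leak))
    .err("leakage: gene-disease association(s) present for test disease(s): %s",
         paste(leak, collapse = ", "))
  o <- ont
  if (variant != "G1") o <- addAssociationAxioms(o, geneAssoc)
  if (variant %in% c("G3", "G4", "G3T", "G4T")) {
    dp <- diseaseAssoc@profiles
    if (!variant %in% c("G3T", "G4T"))
      dp <- dp[!names(dp) %in% testDiseases]
    o <- addAssociationAxioms(o, associationTable(diseaseAssoc@relation, dp))
  }
  if (variant %in% c("G4", "G4T"))
    o <- addAssociationAxioms(o, gdaAssoc)
  projectGraph(o, inverse = inverse)
}

#' Write / read a labeled graph as an edge-list TSV
#'
#' @param graph a \linkS4class{LabeledGraph}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{LabeledGraph} (read).
#' @export
writeGraphTSV <- function(graph, path) {
  ed <- graph@edges
  lines <- c("head\trelation\ttail",
             if (nrow(ed)) paste(ed$head, ed$relation, ed$tail, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGraphTSV
#' @export
readGraphTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("head", "relation", "tail") %in% names(tab)))
    .err("graph TSV must have columns head, relation, tail")
  new("LabeledGraph", nodes = sort(unique(c(tab$head, tab$tail))),
      edges = tab[, c("head", "relation", "tail")])
}
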