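## Shared readers and writers for the association-table dialects and for
## ranking output.  All readers tolerate CRLF endings and aggregate pair
## rows into entity profiles.

.readLinesClean <- function(path) {
  sub("\r$", "", readLines(path, warn = FALSE))
}

.pairsToTable <- function(ents, targets, relation, what) {
  if (!length(ents)) {
    warning(sprintf("empty %s table", what), call. = FALSE)
    return(associationTable(relation))
  }
  key <- paste(ents, targets)
  dup <- duplicated(key)
  if (any(dup))
    .logmsg("deduplicated %d repeated %s pair(s)", sum(dup), what)
  ents <- ents[!dup]
  targets <- targets[!dup]
  associationTable(relation, split(targets, ents))
}

#' Read a gene-phenotype association table
#'
#' Tab-separated with a header; requires columns \code{gene_id} and
#' \code{phenotype_id}, any further columns (the gene-phenotype report
#' dialect is column-rich) are ignored.  Duplicate pairs are collapsed
#' with a logged count.  Filtering of phenotypes against the ontology
#' happens downstream in \code{\link{addAssociationAxioms}}.
#'
#' @param path file path.
#' @return An \linkS4class{AssociationTable} (\code{has_phenotype}).
#' @export
readGenePhenotypeTable <- function(path) {
  lines <- .readLinesClean(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty gene-phenotype table", call. = FALSE)
    return(associationTable("has_phenotype"))
  }
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("gene_id", "phenotype_id")
  if (!all(need %in% names(tab)))
    .err("missing required column(s) %s; found: %s",
         paste(setdiff(need, names(tab)), collapse = ", "),
         paste(names(tab), collapse = ", "))
  .pairsToTable(tab$gene_id, tab$phenotype_id, "has_phenotype",
                "gene-phenotype")
}

#' Read a disease-phenotype association table
#'
#' Tab-separated with \code{#}-prefixed comment/header lines skipped;
#' requires columns \code{database_id} and \code{phenotype_id}.  A
#' qualifier column, when present, is ignored with a logged count of
#' qualified rows (negated annotations are not interpreted).
#'
#' @param path file path.
#' @return An \linkS4class{AssociationTable} (\code{has_symptom}).
#' @export
readDiseasePhenotypeTable <- function(path) {
  lines <- .readLinesClean(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty disease-phenotype table", call. = FALSE)
    return(associationTable("has_symptom"))
  }
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("database_id", "phenotype_id")
  if (!all(need %in% names(tab)))
    .err("missing required column(s) %s; found: %s",
         paste(setdiff(need, names(tab)), collapse = ", "),
         paste(names(tab), collapse = ", "))
  qcol <- intersect(c("qualifier", "negated"), names(tab))
  if (length(qcol)) {
    nq <- sum(nzchar(trimws(as.character(tab[[qcol[1]]]))))
    .logmsg("ignoring qualifier column '%s' (%d qualified row(s))",
            qcol[1], nq)
  }
  .pairsToTable(tab$database_id, tab$phenotype_id, "has_symptom",
                "disease-phenotype")
}

#' Read a gene-disease association table
#'
#' Tab-separated with header; requires columns \code{gene_id} and
#' \code{disease_id}.  Profiles are keyed by disease (matching the axiom
#' direction disease SubClassOf associated_with some gene).
#'
#' @param path file path.
#' @return An \linkS4class{AssociationTable} (\code{associated_with}).
#' @export
readGdaTable <- function(path) {
  lines <- .readLinesClean(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty gene-disease table", call. = FALSE)
    return(associationTable("associated_with"))
  }
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("gene_id", "disease_id")
  if (!all(need %in% names(tab)))
    .err("missing required column(s) %s; found: %s",
         paste(setdiff(need, names(tab)), collapse = ", "),
         paste(names(tab), collapse = ", "))
  .pairsToTable(tab$disease_id, tab$gene_id, "associated_with",
                "gene-disease")
}

#' Write an association table in its pair-row dialect
#'
#' Inverse of the three readers; the column pair is chosen by the
#' table's relation.
#'
#' @param assoc an \linkS4class{AssociationTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssociationTable <- function(assoc, path) {
  cols <- switch(assoc@relation,
                 has_phenotype = c("gene_id", "phenotype_id"),
                 has_symptom = c("database_id", "phenotype_id"),
                 associated_with = c("disease_id", "gene_id"),
                 .err("unknown association relation '%s'", assoc@relation))
  ents <- rep(names(assoc@profiles), lengths(assoc@profiles))
  targets <- unlist(assoc@profiles, use.names = FALSE)
  if (assoc@relation == "associated_with") {
    ## stored disease -> genes; file dialect is gene_id, disease_id
    lines <- c(paste("gene_id", "disease_id", sep = "\t"),
               if (length(ents)) paste(targets, ents, sep = "\t"))
  } else {
    lines <- c(paste(cols, collapse = "\t"),
               if (length(ents)) paste(ents, targets, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read ranked gene lists as TSV
#'
#' Columns \code{disease}, \code{gene}, \code{score}, \code{position};
#' scores are printed with 15 significant digits so a read-back
#' reproduces them to full printed precision.
#'
#' @param ranked a \linkS4class{RankedList} or list of them.
#' @param path file path.
#' @param top write only the top N entries per disease (default all).
#' @return \code{path} (write) or a list of \linkS4class{RankedList}
#'   objects (read).
#' @export
writeRankings <- function(ranked, path, top = Inf) {
  if (is(ranked, "RankedList")) ranked <- list(ranked)
  lines <- "disease\tgene\tscore\tposition"
  for (rl in ranked) {
    en <- utils::head(rl@entries, top)
    if (nrow(en))
      lines <- c(lines, paste(rl@disease, en$gene,
                              formatC(en$score, digits = 15, format = "g"),
                              seq_len(nrow(en)), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRankings
#' @export
readRankings <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$disease), function(d) {
    d <- d[order(d$position), ]
    new("RankedList", disease = d$disease[1],
        entries = data.frame(gene = d$gene, score = d$score,
                             stringsAsFactors = FALSE))
  })
}
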