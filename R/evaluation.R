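## Disease-split cross-validation, duplicate-profile filtering, ranking
## metrics (MR, MRR, Hits@k, AUC) and paired method comparison.

#' Partition diseases into cross-validation folds
#'
#' Uniform random partition of the disease set into \code{k} near-equal
#' test subsets (sizes differ by at most one); each fold trains on the
#' complement.  Deterministic under the seed.
#'
#' @param diseases character vector of disease ids.
#' @param k number of folds (> 1).
#' @param seed integer seed.
#' @return List of folds, each a list with \code{index}, \code{train},
#'   \code{test}.
#' @export
diseaseFolds <- function(diseases, k = 10L, seed = 1L) {
  if (k <= 1L) .err("k must be at least 2")
  diseases <- sort(unique(diseases))
  if (length(diseases) < k) .err("fewer diseases than folds")
  set.seed(seed)
  shuffled <- sample(diseases)
  assign <- rep(seq_len(k), length.out = length(shuffled))
  ## rep() cycles 1..k so fold sizes differ by at most one
  lapply(seq_len(k), function(i) {
    test <- sort(shuffled[assign == i])
    list(index = i - 1L, train = setdiff(diseases, test), test = test)
  })
}

#' Remove test diseases duplicating a training disease
#'
#' A test disease is removed when some training disease has exactly the
#' same phenotype profile \emph{and} exactly the same associated-gene set;
#' such duplicates would let the evaluation score a disease the model has
#' effectively seen.  Diseases matching on only one of the two are kept.
#'
#' @param test,train character vectors of disease ids.
#' @param diseaseProfiles \linkS4class{AssociationTable} (or named list)
#'   of disease phenotype profiles.
#' @param gda \linkS4class{AssociationTable} of disease-gene associations
#'   (diseases without an entry have the empty gene set).
#' @return The surviving subset of \code{test}; removals are logged.
#' @export
filterDuplicateTestDiseases <- function(test, train, diseaseProfiles, gda) {
  prof <- if (is(diseaseProfiles, "AssociationTable"))
    diseaseProfiles@profiles else diseaseProfiles
  gprof <- if (is(gda, "AssociationTable")) gda@profiles else gda
  key <- function(d) {
    p <- sort(unique(prof[[d]]))
    g <- sort(unique(gprof[[d]]))
    paste(paste(p, collapse = ","), paste(g, collapse = ","), sep = "|")
  }
  trainKeys <- vapply(train, key, character(1))
  testKeys <- vapply(test, key, character(1))
  dup <- testKeys %in% trainKeys
  if (any(dup))
    .logmsg("removed %d duplicate test disease(s): %s", sum(dup),
            paste(test[dup], collapse = ", "))
  test[!dup]
}

#' Tie-averaged rank records from a score vector
#'
#' Computes one record per true gene: its fractional (tie-averaged) rank
#' among the candidate genes, and the candidate count.  In filtered mode
#' the other true genes of the same disease are removed from the
#' candidate list before ranking, so known associations never push a true
#' gene down.
#'
#' @param scores named numeric vector of candidate gene scores (higher is
#'   better).
#' @param trueGenes character vector of true causative genes (must be
#'   candidates).
#' @param disease disease id recorded with each record.
#' @param filtered remove co-true genes from the candidate list.
#' @return data.frame with columns \code{disease}, \code{gene},
#'   \code{rank}, \code{n_candidates}.
#' @export
rankRecords <- function(scores, trueGenes, disease = "query",
                        filtered = FALSE) {
  trueGenes <- intersect(trueGenes, names(scores))
  if (!length(trueGenes)) .err("no true gene among the candidates")
  if (!filtered) {
    rk <- rank(-scores, ties.method = "average")
    out <- data.frame(disease = disease, gene = trueGenes,
                      rank = unname(rk[trueGenes]),
                      n_candidates = length(scores),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(trueGenes, function(g) {
      sub <- scores[!names(scores) %in% setdiff(trueGenes, g)]
      rk <- rank(-sub, ties.method = "average")
      data.frame(disease = disease, gene = g, rank = unname(rk[g]),
                 n_candidates = length(sub), stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Ranked-retrieval metrics from rank records
#'
#' MR is the mean rank; MRR the mean reciprocal rank; Hits@k the fraction
#' of records with rank at most k; AUC the mean normalised rank
#' \code{(n_candidates - rank) / (n_candidates - 1)} -- the probability
#' that a true association outranks a random non-association under
#' tie-averaged ranks (1 when there is a single candidate).
#'
#' @param records data.frame with columns \code{rank},
#'   \code{n_candidates} (as from \code{\link{rankRecords}}).
#' @param ks integer cutoffs for Hits@k.
#' @return A \linkS4class{MetricsReport}.
#' @export
rankingMetrics <- function(records, ks = c(1L, 10L, 100L)) {
  if (!NROW(records)) .err("no rank records")
  r <- records$rank
  n <- records$n_candidates
  if (any(r < 1 | r > n)) .err("rank outside [1, n_candidates]")
  ks <- sort(unique(as.integer(ks)))
  hits <- vapply(ks, function(k) mean(r <= k), numeric(1))
  names(hits) <- ks
  auc <- mean(ifelse(n == 1L, 1, (n - r) / (n - 1)))
  new("MetricsReport", mr = mean(r), mrr = mean(1 / r), hits = hits,
      auc = auc, nRecords = nrow(records), perFold = list(),
      foldSD = numeric())
}

## mean +/- sample sd across per-fold reports
.aggregateReports <- function(reports, records = NULL) {
  pull <- function(f) vapply(reports, f, numeric(1))
  mrs <- pull(function(x) x@mr)
  mrrs <- pull(function(x) x@mrr)
  aucs <- pull(function(x) x@auc)
  hitMat <- do.call(rbind, lapply(reports, function(x) x@hits))
  hits <- colMeans(hitMat)
  sds <- c(mr = stats::sd(mrs), mrr = stats::sd(mrrs),
           auc = stats::sd(aucs),
           stats::setNames(apply(hitMat, 2, stats::sd),
                           paste0("hits@", colnames(hitMat))))
  new("MetricsReport", mr = mean(mrs), mrr = mean(mrrs), hits = hits,
      auc = mean(aucs),
      nRecords = sum(vapply(reports, function(x) x@nRecords, integer(1))),
      perFold = reports, foldSD = sds)
}

#' Paired comparison of two methods' rank lists
#'
#' Two-sided Wilcoxon signed-rank test on paired rank values aligned by
#' (disease, gene).  Zero differences are dropped first; if none remain
#' the input is degenerate and an error is raised.  The reported
#' statistic is the signed-rank sum centred at its null expectation
#' (positive when \code{a} tends to have larger values), so swapping the
#' arguments flips its sign but not the p-value.
#'
#' @param ranksA,ranksB equal-length numeric vectors of aligned ranks.
#' @return list with \code{statistic}, \code{p.value} and \code{n} (pairs
#'   used).
#' @export
compareMethods <- function(ranksA, ranksB) {
  if (length(ranksA) != length(ranksB)) .err("rank vectors must be aligned")
  if (length(ranksA) < 5L) .err("need at least 5 pairs")
  keep <- ranksA != ranksB
  if (!any(keep)) .err("degenerate input: all paired ranks are equal")
  a <- ranksA[keep]
  b <- ranksB[keep]
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = "two.sided"))
  n <- length(a)
  list(statistic = unname(wt$statistic) - n * (n + 1) / 4,
       p.value = wt$p.value, n = n)
}

#' Run a disease-split cross-validation experiment
#'
#' The end-to-end protocol: diseases are partitioned into \code{k} folds;
#' per fold, duplicate test diseases are removed, the requested graph
#' variants are built from training information only (with a hard
#' leakage guard), embeddings are trained per (variant, model), and every
#' surviving test disease with at least one known gene association is
#' ranked against the full candidate gene set.  One record per true
#' association is collected (tie-averaged rank) and per-fold metrics are
#' aggregated as mean and sample standard deviation across folds.
#'
#' Method specifications are lists with elements:
#' \itemize{
#'   \item \code{scorer}: \code{"bma_e"}, \code{"bmm_e"},
#'     \code{"entity_sim"}, \code{"triple_score"} or
#'     \code{"semantic_baseline"};
#'   \item \code{variant}, \code{model}: graph variant and embedding model
#'     (embedding scorers only);
#'   \item \code{measure}, \code{aggregation}: semantic-baseline options.
#' }
#'
#' @param ont phenotype \linkS4class{Ontology}.
#' @param geneAssoc,diseaseAssoc,gdaAssoc the three association tables.
#' @param methods named list of method specifications.
#' @param k number of folds.
#' @param seed master seed; fold splits, initialisation and sampling
#'   seeds are derived from it (\code{\link{deriveSeed}}).
#' @param trainArgs named list of \code{\link{trainConfig}} overrides
#'   applied to every trained model.
#' @param ks Hits@k cutoffs.
#' @param filtered use filtered candidate lists (see
#'   \code{\link{rankRecords}}).
#' @return Named list of aggregate \linkS4class{MetricsReport} objects
#'   (one per method), each with per-fold reports in \code{perFold}; the
#'   full record table is attached as attribute \code{"records"}.
#' @export
runExperiment <- function(ont, geneAssoc, diseaseAssoc, gdaAssoc, methods,
                          k = 10L, seed = 1L, trainArgs = list(),
                          ks = c(1L, 10L, 100L), filtered = FALSE) {
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    .err("methods must be a named list")
  diseases <- intersect(names(diseaseAssoc@profiles),
                        names(gdaAssoc@profiles))
  folds <- diseaseFolds(diseases, k = k, seed = deriveSeed(seed, 1L))
  needIC <- any(vapply(methods, function(m)
    m$scorer == "semantic_baseline", logical(1)))
  icTab <- if (needIC) computeIC(ont, geneAssoc) else NULL
  embSpecs <- unique(do.call(rbind, lapply(methods, function(m)
    if (m$scorer != "semantic_baseline")
      data.frame(variant = m$variant, model = m$model,
                 stringsAsFactors = FALSE))))
  perMethodFold <- lapply(methods, function(m) vector("list", k))
  allRecords <- list()

  for (f in seq_len(k)) {
    fold <- folds[[f]]
    surviving <- filterDuplicateTestDiseases(fold$test, fold$train,
                                             diseaseAssoc, gdaAssoc)
    gdaTrain <- associationTable(
      gdaAssoc@relation,
      gdaAssoc@profiles[names(gdaAssoc@profiles) %in% fold$train])
    embs <- list()
    if (!is.null(embSpecs)) {
      for (i in seq_len(nrow(embSpecs))) {
        key <- paste(embSpecs$variant[i], embSpecs$model[i], sep = "/")
        graph <- buildGraphVariant(ont, geneAssoc, diseaseAssoc, gdaTrain,
                                   variant = embSpecs$variant[i],
                                   testDiseases = fold$test)
        cfgArgs <- utils::modifyList(
          list(model = embSpecs$model[i],
               seed = deriveSeed(seed, 1000L * f + i)), trainArgs)
        if (embSpecs$model[i] %in% c("convkb", "convkb_d") &&
            is.null(cfgArgs$initFrom)) {
          base <- if (embSpecs$model[i] == "convkb_d") "transd" else "transe"
          baseArgs <- utils::modifyList(
            cfgArgs[setdiff(names(cfgArgs), "model")], list(model = base))
          embs0 <- trainEmbeddings(graph, do.call(trainConfig, baseArgs))
          cfgArgs$initFrom <- embs0
        }
        embs[[key]] <- trainEmbeddings(graph, do.call(trainConfig, cfgArgs))
      }
    }
    queries <- surviving[surviving %in% names(gdaAssoc@profiles)]
    for (mn in names(methods)) {
      m <- methods[[mn]]
      scorer <- if (m$scorer == "semantic_baseline") {
        gdaScorer("semantic_baseline", ic = icTab, ontology = ont,
                  measure = if (is.null(m$measure)) "resnik" else m$measure,
                  aggregation = if (is.null(m$aggregation)) "bma"
                                else m$aggregation)
      } else {
        gdaScorer(m$scorer,
                  embedding = embs[[paste(m$variant, m$model, sep = "/")]])
      }
      recs <- list()
      for (d in queries) {
        rl <- rankGenes(scorer, geneAssoc,
                        query = diseaseAssoc@profiles[[d]], disease = d)
        scores <- stats::setNames(rl@entries$score, rl@entries$gene)
        recs[[d]] <- rankRecords(scores, gdaAssoc@profiles[[d]],
                                 disease = d, filtered = filtered)
      }
      recTab <- do.call(rbind, recs)
      rownames(recTab) <- NULL
      perMethodFold[[mn]][[f]] <- rankingMetrics(recTab, ks = ks)
      recTab$method <- mn
      recTab$fold <- fold$index
      allRecords[[paste(mn, f)]] <- recTab
    }
  }
  out <- lapply(perMethodFold, .aggregateReports)
  attr(out, "records") <- do.call(rbind, c(allRecords,
                                           make.row.names = FALSE))
  out
}

#' Write / read rank records as TSV
#'
#' @param records data.frame of rank records.
#' @param path file path.
#' @return \code{path} (write) or the records data.frame (read).
#' @export
writeRankRecords <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankRecords
#' @export
readRankRecords <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialise a metrics report (with per-fold blocks) to JSON
#'
#' @param reports named list of \linkS4class{MetricsReport} objects (as
#'   from \code{\link{runExperiment}}) or a single report.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsJSON <- function(reports, path) {
  if (is(reports, "MetricsReport")) reports <- list(report = reports)
  asList <- function(r) {
    out <- list(mr = r@mr, mrr = r@mrr, hits = as.list(r@hits),
                auc = r@auc, n_records = r@nRecords)
    if (length(r@foldSD)) out$sd <- as.list(r@foldSD)
    if (length(r@perFold)) out$per_fold <- lapply(r@perFold, asList)
    out
  }
  jsonlite::write_json(lapply(reports, asList), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
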