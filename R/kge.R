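## Knowledge-graph embedding models over a LabeledGraph: TransE, TransH,
## TransD, ConvKB (and ConvKB initialised from TransD, "convkb_d").
## Scoring functions, uniform negative sampling, and mini-batch training
## with manual gradients and an Adam/SGD optimiser, all in base R --
## deliberately dependency-free and deterministic under a fixed seed.

#' Training configuration constructor
#'
#' Defaults target desk-scale graphs (a few hundred nodes); see
#' \code{\link{kgeGrid}} for the release-scale hyperparameter search grid.
#'
#' @param model one of \code{"transe"}, \code{"transh"}, \code{"transd"},
#'   \code{"convkb"}, \code{"convkb_d"}.
#' @param d embedding dimension.
#' @param k TransD projection dimension (defaults to \code{d}).
#' @param batchSize mini-batch size.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param margin margin of the ranking loss (translational models).
#' @param nNeg negatives per positive.
#' @param normOrder TransE norm order (1 or 2).
#' @param nFilters ConvKB filter count tau.
#' @param seed integer seed for initialisation and sampling.
#' @param initFrom pretrained \linkS4class{EmbeddingSet} for ConvKB
#'   initialisation (TransE for \code{convkb}, TransD for
#'   \code{convkb_d}).
#' @param optimizer \code{"adam"} (default) or \code{"sgd"}.
#' @param normalizeEntities clamp entity norms to at most 1 after each
#'   epoch (translational models).
#' @param lambda L2 penalty on the ConvKB weight vector.
#' @param allowRandomConvInit allow ConvKB training without a pretrained
#'   initialisation.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(model, d = 32L, k = d, batchSize = 256L, lr = 0.01,
                        epochs = 200L, margin = 1, nNeg = 2L,
                        normOrder = 2L, nFilters = 8L, seed = 1L,
                        initFrom = NULL, optimizer = c("adam", "sgd"),
                        normalizeEntities = TRUE, lambda = 1e-4,
                        allowRandomConvInit = FALSE) {
  new("TrainConfig", model = model, d = as.integer(d), k = as.integer(k),
      batchSize = as.integer(batchSize), lr = lr,
      epochs = as.integer(epochs), margin = margin, nNeg = as.integer(nNeg),
      normOrder = as.integer(normOrder), nFilters = as.integer(nFilters),
      seed = as.integer(seed), initFrom = initFrom,
      optimizer = match.arg(optimizer),
      normalizeEntities = normalizeEntities, lambda = lambda,
      allowRandomConvInit = allowRandomConvInit)
}

#' Release-scale hyperparameter search grid
#'
#' The default grid enumerated by a full-scale hyperparameter search:
#' embedding dimension, batch size, learning rate and (ConvKB only)
#' filter count.  Desk-scale work uses \code{\link{trainConfig}} defaults
#' instead.
#'
#' @return A data.frame enumerating the grid.
#' @export
kgeGrid <- function() {
  expand.grid(d = c(100L, 200L, 300L, 400L),
              batchSize = c(1024L, 2048L, 4096L, 8192L),
              lr = c(1e-4, 1e-3, 1e-2),
              nFilters = c(100L, 200L))
}

## pad or truncate columns of M to width k (the rectangular identity I^{k x d})
.padTrunc <- function(M, k) {
  d <- ncol(M)
  if (k == d) M
  else if (k < d) M[, seq_len(k), drop = FALSE]
  else cbind(M, matrix(0, nrow(M), k - d))
}

.xavier <- function(nr, nc) {
  lim <- sqrt(6 / (2 * nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.rowNormalize <- function(M) {
  nr <- sqrt(rowSums(M^2))
  nr[nr == 0] <- 1
  M / nr
}

## -- scoring -----------------------------------------------------------------

## core scorer on integer index vectors; par is the internal parameter list
.scoreIdx <- function(par, model, hi, ri, ti, normOrder = 2L) {
  H <- par$ent[hi, , drop = FALSE]
  T <- par$ent[ti, , drop = FALSE]
  R <- par$rel[ri, , drop = FALSE]
  if (model == "transe") {
    U <- H + R - T
    if (normOrder == 1L) return(-rowSums(abs(U)))
    return(-sqrt(rowSums(U^2)))
  }
  if (model == "transh") {
    W <- par$wr[ri, , drop = FALSE]
    Hp <- H - rowSums(W * H) * W
    Tp <- T - rowSums(W * T) * W
    U <- Hp + R - Tp
    return(-rowSums(U^2))
  }
  if (model == "transd") {
    k <- ncol(par$rel)
    Wr <- par$wr[ri, , drop = FALSE]
    a <- rowSums(par$proj[hi, , drop = FALSE] * H)
    b <- rowSums(par$proj[ti, , drop = FALSE] * T)
    U <- (a - b) * Wr + .padTrunc(H, k) - .padTrunc(T, k) + R
    return(-rowSums(U^2))
  }
  ## convkb / convkb_d
  tau <- nrow(par$filt)
  d <- ncol(par$ent)
  f <- numeric(length(hi))
  for (i in seq_len(tau)) {
    Z <- par$filt[i, 1] * H + par$filt[i, 2] * R + par$filt[i, 3] * T +
      par$b
    V <- pmax(Z, 0)
    f <- f + as.vector(V %*% par$w[((i - 1L) * d + 1L):(i * d)])
  }
  f
}

.parFromEmbedding <- function(emb) {
  list(ent = emb@entities, rel = emb@relations, wr = emb@relationNormals,
       proj = emb@entityProjections, filt = emb@convFilters,
       w = emb@convWeight, b = emb@convBias)
}

#' Score triples under an embedding model
#'
#' Evaluates the model's plausibility score \code{f(h, r, t)}; higher is
#' more plausible.  TransE scores are negative translation distances
#' (norm order from \code{normOrder}); TransH and TransD use squared L2
#' distances after their relation-specific entity projections; ConvKB
#' applies its convolution filters to the stacked \code{[h, r, t]} matrix
#' followed by a ReLU and a linear readout.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param triples data.frame with columns \code{head}, \code{relation},
#'   \code{tail}.
#' @param normOrder TransE norm order.
#' @return Numeric vector of scores.
#' @export
scoreTriples <- function(emb, triples, normOrder = 2L) {
  ents <- rownames(emb@entities)
  rels <- rownames(emb@relations)
  hi <- match(triples$head, ents)
  ti <- match(triples$tail, ents)
  ri <- match(triples$relation, rels)
  if (anyNA(hi) || anyNA(ti))
    .err("unknown entity: %s",
         paste(utils::head(unique(c(triples$head[is.na(hi)],
                                    triples$tail[is.na(ti)])), 3),
               collapse = ", "))
  if (anyNA(ri))
    .err("unknown relation: %s",
         paste(utils::head(unique(triples$relation[is.na(ri)]), 3),
               collapse = ", "))
  unname(.scoreIdx(.parFromEmbedding(emb), emb@model, hi, ri, ti,
                   normOrder))
}

#' @rdname scoreTriples
#' @param head,relation,tail single identifiers.
#' @export
scoreTriple <- function(emb, head, relation, tail, normOrder = 2L) {
  scoreTriples(emb, data.frame(head = head, relation = relation,
                               tail = tail, stringsAsFactors = FALSE),
               normOrder = normOrder)
}

## -- negative sampling -------------------------------------------------------

## corrupt head or tail (probability 1/2 each) with a uniform entity;
## operates on integer indices under the current RNG stream
.corruptIdx <- function(hi, ri, ti, nEnt, nNeg) {
  nb <- length(hi)
  hiN <- rep(hi, nNeg)
  riN <- rep(ri, nNeg)
  tiN <- rep(ti, nNeg)
  corruptHead <- stats::runif(nb * nNeg) < 0.5
  repl <- sample.int(nEnt, nb * nNeg, replace = TRUE)
  hiN[corruptHead] <- repl[corruptHead]
  tiN[!corruptHead] <- repl[!corruptHead]
  list(hi = hiN, ri = riN, ti = tiN)
}

#' Sample corrupted (negative) triples
#'
#' Each positive yields \code{nNeg} corruptions in which either the head
#' or the tail (probability 1/2 each) is replaced by an entity drawn
#' uniformly from the graph's node set.  Corruptions are unfiltered:
#' a corruption that happens to be a true edge is kept (standard practice;
#' filtering is available in training via \code{filtered = TRUE}).
#'
#' @param graph a \linkS4class{LabeledGraph}.
#' @param batch data.frame of positive triples (\code{head},
#'   \code{relation}, \code{tail}).
#' @param nNeg corruptions per positive.
#' @param seed integer seed.
#' @return data.frame of corrupted triples.
#' @export
sampleNegatives <- function(graph, batch, nNeg, seed = 1L) {
  ents <- sort(graph@nodes)
  if (length(ents) < 2L) .err("need at least 2 entities to corrupt triples")
  if (nNeg == 0L)
    return(data.frame(head = character(), relation = character(),
                      tail = character(), stringsAsFactors = FALSE))
  hi <- match(batch$head, ents)
  ti <- match(batch$tail, ents)
  set.seed(seed)
  idx <- .corruptIdx(hi, seq_len(nrow(batch)), ti, length(ents), nNeg)
  data.frame(head = ents[idx$hi], relation = rep(batch$relation, nNeg),
             tail = ents[idx$ti], stringsAsFactors = FALSE)
}

## -- gradients ---------------------------------------------------------------

## accumulate per-row gradient contributions G (length(idx) x ncol) into a
## dense matrix of shape like M
.scatterRows <- function(M, idx, G) {
  agg <- rowsum(G, idx)
  out <- matrix(0, nrow(M), ncol(M))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

## gradient of sum(ds * f) w.r.t. all parameters, for index batch (hi,ri,ti)
.gradBatch <- function(par, model, hi, ri, ti, ds, normOrder = 2L) {
  H <- par$ent[hi, , drop = FALSE]
  T <- par$ent[ti, , drop = FALSE]
  R <- par$rel[ri, , drop = FALSE]
  g <- list()
  if (model == "transe") {
    U <- H + R - T
    if (normOrder == 1L) {
      Dh <- -sign(U) * ds
    } else {
      nr <- sqrt(rowSums(U^2))
      nr[nr == 0] <- Inf
      Dh <- -(U / nr) * ds
    }
    g$ent <- .scatterRows(par$ent, c(hi, ti), rbind(Dh, -Dh))
    g$rel <- .scatterRows(par$rel, ri, Dh)
  } else if (model == "transh") {
    W <- par$wr[ri, , drop = FALSE]
    S <- H - T
    alpha <- rowSums(W * S)
    U <- (H + R - T) - alpha * W
    D <- -2 * U * ds
    proj <- D - rowSums(W * D) * W
    g$ent <- .scatterRows(par$ent, c(hi, ti), rbind(proj, -proj))
    g$rel <- .scatterRows(par$rel, ri, D)
    gW <- -(S * rowSums(W * D) + alpha * D)
    g$wr <- .scatterRows(par$wr, ri, gW)
  } else if (model == "transd") {
    k <- ncol(par$rel)
    Wr <- par$wr[ri, , drop = FALSE]
    Wh <- par$proj[hi, , drop = FALSE]
    Wt <- par$proj[ti, , drop = FALSE]
    a <- rowSums(Wh * H)
    b <- rowSums(Wt * T)
    U <- (a - b) * Wr + .padTrunc(H, k) - .padTrunc(T, k) + R
    D <- -2 * U * ds                      # n x k
    c1 <- rowSums(Wr * D)                 # n
    Dback <- .padTrunc(D, ncol(par$ent))  # n x d
    gH <- c1 * Wh + Dback
    gT <- -(c1 * Wt + Dback)
    g$ent <- .scatterRows(par$ent, c(hi, ti), rbind(gH, gT))
    g$rel <- .scatterRows(par$rel, ri, D)
    g$wr <- .scatterRows(par$wr, ri, (a - b) * D)
    g$proj <- .scatterRows(par$proj, c(hi, ti), rbind(c1 * H, -c1 * T))
  } else {                                # convkb
    tau <- nrow(par$filt)
    d <- ncol(par$ent)
    gH <- matrix(0, length(hi), d); gR <- gH; gT <- gH
    gF <- matrix(0, tau, 3)
    gw <- numeric(tau * d)
    gb <- 0
    for (i in seq_len(tau)) {
      wi <- par$w[((i - 1L) * d + 1L):(i * d)]
      Z <- par$filt[i, 1] * H + par$filt[i, 2] * R + par$filt[i, 3] * T +
        par$b
      act <- Z > 0
      V <- Z * act
      gw[((i - 1L) * d + 1L):(i * d)] <- colSums(V * ds)
      delta <- (act * ds) * rep(wi, each = nrow(Z))
      gb <- gb + sum(delta)
      gH <- gH + par$filt[i, 1] * delta
      gR <- gR + par$filt[i, 2] * delta
      gT <- gT + par$filt[i, 3] * delta
      gF[i, 1] <- sum(delta * H)
      gF[i, 2] <- sum(delta * R)
      gF[i, 3] <- sum(delta * T)
    }
    g$ent <- .scatterRows(par$ent, c(hi, ti), rbind(gH, gT))
    g$rel <- .scatterRows(par$rel, ri, gR)
    g$filt <- gF
    g$w <- gw
    g$b <- gb
  }
  g
}

## -- optimiser ---------------------------------------------------------------

.adamInit <- function(par) {
  lapply(par, function(p) if (is.null(p)) NULL else
    list(m = p * 0, v = p * 0))
}

.adamStep <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^t)
    vh <- st$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  list(par = par, state = state)
}

.sgdStep <- function(par, grads, lr) {
  for (nm in names(grads))
    if (!is.null(grads[[nm]])) par[[nm]] <- par[[nm]] - lr * grads[[nm]]
  par
}

## -- training ----------------------------------------------------------------

#' Train knowledge-graph embeddings
#'
#' Mini-batch training on the graph's edge multiset.  Translational
#' models (TransE/TransH/TransD) minimise the margin ranking loss
#' \code{max(0, margin - f(pos) + f(neg))} over uniformly corrupted
#' negatives; ConvKB minimises the soft-margin logistic loss
#' \code{log(1 + exp(-l f))} with labels +1/-1 and an L2 penalty on its
#' weight vector.  ConvKB entity and relation tables are initialised from
#' a pretrained TransE (\code{convkb}) or TransD (\code{convkb_d})
#' embedding set.  TransH relation normals are renormalised to unit
#' length after every update; entity norms are clamped to 1 after each
#' epoch when \code{normalizeEntities} is set.  Training is single
#' threaded and fully reproducible under the config seed.
#'
#' @param graph a \linkS4class{LabeledGraph}.
#' @param config a \linkS4class{TrainConfig}.
#' @param filtered drop corruptions that collide with true edges.
#' @return An \linkS4class{EmbeddingSet}; the per-epoch mean loss is
#'   attached as attribute \code{"history"}.
#' @export
trainEmbeddings <- function(graph, config, filtered = FALSE) {
  if (!nrow(graph@edges)) .err("cannot train on an empty graph")
  ents <- sort(graph@nodes)
  rels <- sort(unique(graph@edges$relation))
  nEnt <- length(ents)
  if (nEnt < 2L) .err("need at least 2 entities to corrupt triples")
  model <- config@model
  d <- config@d
  k <- if (model == "transd") config@k else config@d
  set.seed(config@seed)

  par <- list(ent = .xavier(nEnt, d), rel = .xavier(length(rels), k))
  if (model == "transh") {
    par$rel <- .xavier(length(rels), d)
    par$wr <- .rowNormalize(.xavier(length(rels), d))
  } else if (model == "transd") {
    par$wr <- .xavier(length(rels), k)
    par$proj <- .xavier(nEnt, d)
  } else if (model %in% c("convkb", "convkb_d")) {
    par$rel <- .xavier(length(rels), d)
    init <- config@initFrom
    if (!is.null(init)) {
      want <- if (model == "convkb_d") "transd" else "transe"
      if (init@model != want)
        .err("%s must be initialised from a pretrained %s embedding set",
             model, want)
      if (init@d != d || ncol(init@relations) != d)
        .err("initFrom dimension mismatch: pretrained d=%d/k=%d vs config d=%d",
             init@d, init@k, d)
      eIdx <- match(ents, rownames(init@entities))
      rIdx <- match(rels, rownames(init@relations))
      if (anyNA(eIdx) || anyNA(rIdx))
        .err("initFrom vocabulary does not cover the training graph")
      par$ent <- init@entities[eIdx, , drop = FALSE]
      par$rel <- init@relations[rIdx, , drop = FALSE]
    }
    par$filt <- .xavier(config@nFilters, 3L)
    par$w <- as.vector(.xavier(1L, config@nFilters * d))
    par$b <- 0
  }
  dimnames(par$ent) <- NULL
  dimnames(par$rel) <- NULL

  hiAll <- match(graph@edges$head, ents)
  riAll <- match(graph@edges$relation, rels)
  tiAll <- match(graph@edges$tail, ents)
  nPos <- length(hiAll)
  posKey <- if (filtered)
    paste(hiAll, riAll, tiAll) else NULL
  translational <- model %in% c("transe", "transh", "transd")
  state <- if (config@optimizer == "adam") .adamInit(par) else NULL
  stepT <- 0L
  history <- numeric(config@epochs)

  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(nPos)
    lossSum <- 0
    lossN <- 0
    for (start in seq(1L, nPos, by = config@batchSize)) {
      sel <- ord[start:min(start + config@batchSize - 1L, nPos)]
      hi <- hiAll[sel]; ri <- riAll[sel]; ti <- tiAll[sel]
      neg <- .corruptIdx(hi, ri, ti, nEnt, config@nNeg)
      if (filtered) {
        clash <- paste(neg$hi, neg$ri, neg$ti) %in% posKey
        if (any(clash)) {
          ## re-corrupt colliding triples once; residual collisions kept
          redo <- .corruptIdx(neg$hi[clash], neg$ri[clash], neg$ti[clash],
                              nEnt, 1L)
          neg$hi[clash] <- redo$hi
          neg$ti[clash] <- redo$ti
        }
      }
      if (translational) {
        fPos <- .scoreIdx(par, model, hi, ri, ti, config@normOrder)
        fNeg <- .scoreIdx(par, model, neg$hi, neg$ri, neg$ti,
                          config@normOrder)
        viol <- config@margin - rep(fPos, config@nNeg) + fNeg
        act <- viol > 0
        nPair <- length(fNeg)
        loss <- sum(pmax(viol, 0)) / nPair
        dsPos <- -as.numeric(act) / nPair   # per (pos, neg) pair
        dsNeg <- as.numeric(act) / nPair
        ds <- c(dsPos, dsNeg)
        grads <- .gradBatch(par, model,
                            c(rep(hi, config@nNeg), neg$hi),
                            c(rep(ri, config@nNeg), neg$ri),
                            c(rep(ti, config@nNeg), neg$ti),
                            ds, config@normOrder)
      } else {
        allHi <- c(hi, neg$hi); allRi <- c(ri, neg$ri); allTi <- c(ti, neg$ti)
        lab <- c(rep(1, length(hi)), rep(-1, length(neg$hi)))
        f <- .scoreIdx(par, model, allHi, allRi, allTi)
        n <- length(f)
        loss <- sum(log1p(exp(-pmin(lab * f, 30)))) / n +
          config@lambda / 2 * sum(par$w^2)
        ds <- (-lab * stats::plogis(-lab * f)) / n
        grads <- .gradBatch(par, model, allHi, allRi, allTi, ds)
        grads$w <- grads$w + config@lambda * par$w
      }
      if (!is.finite(loss))
        .err("non-finite loss at epoch %d (model %s, lr %g); reduce the learning rate",
             ep, model, config@lr)
      lossSum <- lossSum + loss * length(sel)
      lossN <- lossN + length(sel)
      stepT <- stepT + 1L
      if (config@optimizer == "adam") {
        upd <- .adamStep(par, grads, state, config@lr, stepT)
        par <- upd$par
        state <- upd$state
      } else {
        par <- .sgdStep(par, grads, config@lr)
      }
      if (model == "transh") par$wr <- .rowNormalize(par$wr)
    }
    if (translational && config@normalizeEntities) {
      nr <- sqrt(rowSums(par$ent^2))
      over <- nr > 1
      if (any(over)) par$ent[over, ] <- par$ent[over, ] / nr[over]
    }
    history[ep] <- lossSum / lossN
  }

  rownames(par$ent) <- ents
  rownames(par$rel) <- rels
  if (!is.null(par[["wr"]])) rownames(par$wr) <- rels
  if (!is.null(par[["proj"]])) rownames(par$proj) <- ents
  emb <- new("EmbeddingSet", model = model, entities = par[["ent"]],
             relations = par[["rel"]], relationNormals = par[["wr"]],
             entityProjections = par[["proj"]], convFilters = par[["filt"]],
             convWeight = par[["w"]], convBias = par[["b"]],
             d = d, k = as.integer(k))
  attr(emb, "history") <- history
  emb
}

#' Construct an EmbeddingSet from raw tables
#'
#' Mostly useful for tests and for loading externally produced embeddings.
#'
#' @param model model name.
#' @param entities entity matrix with rownames.
#' @param relations relation matrix with rownames.
#' @param relationNormals,entityProjections,convFilters,convWeight,convBias
#'   model-specific parameter blocks (see \linkS4class{EmbeddingSet}).
#' @param k TransD projection dimension.
#' @return An \linkS4class{EmbeddingSet}.
#' @export
embeddingSet <- function(model, entities, relations,
                         relationNormals = NULL, entityProjections = NULL,
                         convFilters = NULL, convWeight = NULL,
                         convBias = NULL, k = ncol(relations)) {
  new("EmbeddingSet", model = model, entities = entities,
      relations = relations, relationNormals = relationNormals,
      entityProjections = entityProjections, convFilters = convFilters,
      convWeight = convWeight, convBias = convBias,
      d = ncol(entities), k = as.integer(k))
}

#' Export / import an embedding set as TSV tables plus a JSON manifest
#'
#' Writes one TSV per parameter table (\code{entities.tsv},
#' \code{relations.tsv}, and the model-specific blocks) and a
#' \code{manifest.json} recording model, dimensions and scalars.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param dir output directory (created if needed).
#' @return \code{dir} (write) or an \linkS4class{EmbeddingSet} (read).
#' @export
writeEmbeddings <- function(emb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wTab <- function(M, f) {
    df <- data.frame(id = rownames(M),
                     format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  wTab(emb@entities, "entities.tsv")
  wTab(emb@relations, "relations.tsv")
  if (!is.null(emb@relationNormals)) wTab(emb@relationNormals,
                                          "relation_normals.tsv")
  if (!is.null(emb@entityProjections)) wTab(emb@entityProjections,
                                            "entity_projections.tsv")
  if (!is.null(emb@convFilters)) {
    M <- emb@convFilters
    rownames(M) <- paste0("filter", seq_len(nrow(M)))
    wTab(M, "conv_filters.tsv")
  }
  manifest <- list(model = emb@model, d = emb@d, k = emb@k,
                   tau = if (is.null(emb@convFilters)) NULL
                         else nrow(emb@convFilters),
                   convBias = emb@convBias,
                   convWeight = emb@convWeight)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rTab <- function(f) {
    if (!file.exists(file.path(dir, f))) return(NULL)
    tab <- utils::read.table(file.path(dir, f), sep = "\t",
                             stringsAsFactors = FALSE)
    M <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(M) <- list(tab[, 1], NULL)
    M
  }
  embeddingSet(man$model, rTab("entities.tsv"), rTab("relations.tsv"),
               relationNormals = rTab("relation_normals.tsv"),
               entityProjections = rTab("entity_projections.tsv"),
               convFilters = unname(rTab("conv_filters.tsv")),
               convWeight = if (is.null(man$convWeight)) NULL
                            else as.numeric(man$convWeight),
               convBias = man$convBias, k = man$k)
}
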