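## Brute-force reference implementations used as independent oracles.
## They work directly off the axiom data.frame by explicit set
## enumeration, deliberately sharing no code with the package internals.

oracleAncestors <- function(ax, term) {
  res <- term
  repeat {
    up <- c(ax$object[ax$kind == "SubClassOf" & ax$subject %in% res],
            ax$object[ax$kind == "EquivalentTo" & ax$subject %in% res],
            ax$subject[ax$kind == "EquivalentTo" & ax$object %in% res])
    new <- setdiff(unique(up), res)
    if (!length(new)) return(sort(res))
    res <- c(res, new)
  }
}

## IC by direct counting: an entity counts for a term when the term lies in
## the ancestor closure of any of its annotations
oracleIC <- function(ont, corpus) {
  ax <- axioms(ont)
  prof <- profiles(corpus)
  n <- length(prof)
  closures <- lapply(prof, function(p)
    unique(unlist(lapply(p, oracleAncestors, ax = ax))))
  vapply(sort(ontologyClasses(ont)), function(term) {
    cnt <- sum(vapply(closures, function(cl) term %in% cl, logical(1)))
    if (cnt == 0) log(n) else -log(cnt / n)
  }, numeric(1))
}

oracleResnik <- function(ont, icv, p1, p2) {
  ax <- axioms(ont)
  common <- intersect(oracleAncestors(ax, p1), oracleAncestors(ax, p2))
  if (!length(common)) 0 else max(icv[common])
}

oracleLin <- function(ont, icv, p1, p2) {
  denom <- icv[[p1]] + icv[[p2]]
  if (denom == 0) 0 else 2 * oracleResnik(ont, icv, p1, p2) / denom
}

oraclePairMatrix <- function(ont, icv, pg, pd, measure) {
  f <- if (measure == "resnik") oracleResnik else oracleLin
  outer(seq_along(pg), seq_along(pd),
        Vectorize(function(i, j) f(ont, icv, pg[i], pd[j])))
}

oracleBMA <- function(M) {
  (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
}

oracleBMM <- function(M) {
  max(mean(apply(M, 1, max)), mean(apply(M, 2, max)))
}

oracleSimGIC <- function(ont, icv, pg, pd) {
  ax <- axioms(ont)
  cg <- unique(unlist(lapply(pg, oracleAncestors, ax = ax)))
  cd <- unique(unlist(lapply(pd, oracleAncestors, ax = ax)))
  denom <- sum(icv[union(cg, cd)])
  if (denom == 0) 0 else sum(icv[intersect(cg, cd)]) / denom
}

## AUC by explicit concordant-pair counting: for one record with rank r
## among n candidates, count non-positive candidates ranked below (ties
## half) -- equivalently (n - r) / (n - 1) under tie-averaged ranks
oracleAUCFromScores <- function(scores, trueGene) {
  others <- scores[names(scores) != trueGene]
  s <- scores[[trueGene]]
  (sum(s > others) + 0.5 * sum(s == others)) / length(others)
}
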