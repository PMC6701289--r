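## RIPPER-style sequential-covering rule induction.
##
## Classes are processed from least to most frequent; per class, rules are
## grown condition-by-condition maximizing FOIL gain on a grow split and
## pruned on a prune split maximizing (p - n)/(p + n); rule addition stops
## when the description length of the set exceeds the best seen plus a slack,
## when a pruned rule's error exceeds 50%, or when no positives remain.  The
## most frequent class becomes the default rule.  Conditions are of the form
## gene >= c or gene <= c with c a midpoint of observed values.

ruleCovers <- function(conds, X) {
  keep <- rep(TRUE, nrow(X))
  for (k in seq_len(nrow(conds))) {
    v <- X[, conds$gene[k]]
    keep <- keep & if (conds$op[k] == ">=") v >= conds$threshold[k]
                   else v <= conds$threshold[k]
  }
  keep
}

## Best single condition by FOIL gain over covered grow samples.
## isPos: logical over rows of X; cov: logical, currently covered.
bestCondition <- function(X, isPos, cov) {
  p0 <- sum(isPos & cov); n0 <- sum(!isPos & cov)
  if (p0 == 0) return(NULL)
  base <- log2(p0 / (p0 + n0))
  best <- NULL; bestGain <- 0
  for (j in seq_len(ncol(X))) {
    v <- X[cov, j]
    yp <- isPos[cov]
    ord <- order(v)
    v <- v[ord]; yp <- yp[ord]
    dup <- which(diff(v) > 0)
    if (!length(dup)) next
    cp <- cumsum(yp); cn <- cumsum(!yp)
    thr <- (v[dup] + v[dup + 1]) / 2
    ## gene <= thr keeps the left side; gene >= thr the right side
    pL <- cp[dup]; nL <- cn[dup]
    pR <- p0 - pL; nR <- n0 - nL
    gL <- ifelse(pL > 0, pL * (log2(pL / (pL + nL)) - base), -Inf)
    gR <- ifelse(pR > 0, pR * (log2(pR / (pR + nR)) - base), -Inf)
    for (side in 1:2) {
      g <- if (side == 1) gR else gL   # '>=' inspected first
      i <- which.max(g)
      if (length(i) && g[i] > bestGain + 1e-9) {
        bestGain <- g[i]
        best <- data.frame(gene = colnames(X)[j],
                           op = if (side == 1) ">=" else "<=",
                           threshold = thr[i])
      }
    }
  }
  best
}

growRule <- function(X, isPos) {
  conds <- data.frame(gene = character(), op = character(),
                      threshold = numeric())
  cov <- rep(TRUE, nrow(X))
  repeat {
    if (!sum(!isPos & cov)) break       # no negatives left
    cnd <- bestCondition(X, isPos, cov)
    if (is.null(cnd)) break
    conds <- rbind(conds, cnd)
    v <- X[, cnd$gene]
    cov <- cov & if (cnd$op == ">=") v >= cnd$threshold else v <= cnd$threshold
    if (nrow(conds) >= 20) break        # guard against degenerate growth
  }
  conds
}

## Delete a final sequence of conditions maximizing (p - n)/(p + n) on the
## prune split; ties prefer the shorter rule.  Returns NULL when full
## pruning (empty rule) wins, signalling the end of rule learning.
pruneRule <- function(conds, X, isPos) {
  k <- nrow(conds)
  if (!nrow(X)) return(conds)           # empty prune split: keep as grown
  vals <- numeric(k + 1)
  cov <- rep(TRUE, nrow(X))
  for (len in 0:k) {
    if (len > 0) {
      v <- X[, conds$gene[len]]
      cov <- cov & if (conds$op[len] == ">=") v >= conds$threshold[len]
                   else v <= conds$threshold[len]
    }
    p <- sum(isPos & cov); n <- sum(!isPos & cov)
    vals[len + 1] <- if (p + n == 0) 0 else (p - n) / (p + n)
  }
  bestLen <- which.max(vals) - 1L       # first max: shortest rule on ties
  if (bestLen == 0) return(NULL)
  conds[seq_len(bestLen), , drop = FALSE]
}

log2Choose <- function(n, k) lchoose(n, k) / log(2)

ruleDL <- function(nConds, nCandidates)
  log2(nConds + 1) + log2Choose(nCandidates, nConds)

exceptionDL <- function(covered, uncovered, fp, fn)
  log2(covered + 1) + log2Choose(covered, fp) +
  log2(uncovered + 1) + log2Choose(uncovered, fn)

classRulesDL <- function(ruleList, X, isPos, nCandidates) {
  cov <- rep(FALSE, nrow(X))
  dl <- 0
  for (conds in ruleList) {
    dl <- dl + ruleDL(nrow(conds), nCandidates)
    cov <- cov | ruleCovers(conds, X)
  }
  dl + exceptionDL(sum(cov), sum(!cov), sum(cov & !isPos), sum(!cov & isPos))
}

## Learn the ordered rule list for one class (pos) against the rest (neg).
learnClassRules <- function(X, isPos, growFraction, mdlSlack) {
  ruleList <- list()
  activePos <- isPos
  nCand <- 2 * ncol(X)
  bestDL <- classRulesDL(ruleList, X, isPos, nCand)
  repeat {
    act <- activePos | !isPos
    if (!sum(activePos)) break
    rows <- which(act)
    ## stratified grow/prune split over the still-active samples
    gp <- logical(length(rows))
    for (cl in c(TRUE, FALSE)) {
      w <- which(isPos[rows] == cl)
      if (!length(w)) next
      k <- ceiling(growFraction * length(w))
      gp[w[sample.int(length(w), k)]] <- TRUE
    }
    growRows <- rows[gp]; pruneRows <- rows[!gp]
    if (!sum(isPos[growRows])) break
    conds <- growRule(X[growRows, , drop = FALSE], isPos[growRows])
    if (!nrow(conds)) break
    conds <- pruneRule(conds, X[pruneRows, , drop = FALSE], isPos[pruneRows])
    if (is.null(conds)) break
    ## reject when the pruned rule misclassifies most covered prune samples
    pcov <- ruleCovers(conds, X[pruneRows, , drop = FALSE])
    p <- sum(pcov & isPos[pruneRows]); n <- sum(pcov & !isPos[pruneRows])
    if (p + n > 0 && n / (p + n) >= 0.5) break
    covAll <- ruleCovers(conds, X)
    if (!sum(covAll & activePos)) break
    candidate <- c(ruleList, list(conds))
    dl <- classRulesDL(candidate, X, isPos, nCand)
    if (dl > bestDL + mdlSlack) break
    bestDL <- min(bestDL, dl)
    ruleList <- candidate
    activePos <- activePos & !covAll
  }
  ruleList
}

optimizeClassRules <- function(ruleList, X, isPos, growFraction, passes) {
  nCand <- 2 * ncol(X)
  for (pass in seq_len(passes)) {
    for (i in seq_along(ruleList)) {
      otherCov <- rep(FALSE, nrow(X))
      for (j in seq_along(ruleList)) if (j != i)
        otherCov <- otherCov | ruleCovers(ruleList[[j]], X)
      rows <- which(!otherCov)
      if (!sum(isPos[rows])) next
      gp <- logical(length(rows))
      for (cl in c(TRUE, FALSE)) {
        w <- which(isPos[rows] == cl)
        if (!length(w)) next
        gp[w[sample.int(length(w), ceiling(growFraction * length(w)))]] <- TRUE
      }
      growRows <- rows[gp]; pruneRows <- rows[!gp]
      if (!sum(isPos[growRows])) next
      repl <- growRule(X[growRows, , drop = FALSE], isPos[growRows])
      if (!nrow(repl)) next
      repl <- pruneRule(repl, X[pruneRows, , drop = FALSE], isPos[pruneRows])
      if (is.null(repl)) next
      trial <- ruleList; trial[[i]] <- repl
      if (classRulesDL(trial, X, isPos, nCand) <
          classRulesDL(ruleList, X, isPos, nCand))
        ruleList <- trial
    }
  }
  ruleList
}

#' Induce an ordered threshold rule set (RIPPER-style)
#'
#' @param ds a [LabeledDataset-class] with at least 2 classes (a
#'   single-class input yields just the default rule).
#' @param genes candidate genes (identifiers or indices); typically the
#'   Johnson-reducer output over the informative features.
#' @param growFraction fraction of samples in the grow split (default 2/3;
#'   the rest prunes).
#' @param mdlSlack description-length slack in bits before rule addition
#'   stops (default 64).
#' @param optimizePasses rule-replacement optimization passes (default 2).
#' @param seed integer seed for the grow/prune split draws.
#' @return a [RuleSet-class]; the most frequent class is the default rule.
#' @export
ripperInduce <- function(ds, genes = rownames(ds), growFraction = 2 / 3,
                         mdlSlack = 64, optimizePasses = 2L, seed = 1L) {
  idx <- resolveFeatures(ds, genes)
  X <- t(exprsMatrix(ds))[, idx, drop = FALSE]
  colnames(X) <- rownames(ds)[idx]
  y <- droplevels(classLabels(ds))
  tab <- table(y)
  classOrder <- names(tab)[order(tab, seq_along(tab))]  # least frequent first
  defaultCls <- classOrder[length(classOrder)]
  if (nlevels(y) < 2) return(ruleSet(list(rule(NULL, defaultCls))))

  rules <- list()
  remaining <- rep(TRUE, nrow(X))
  withSeed(deriveSeed(seed, "ripper"), {
    for (cls in classOrder[-length(classOrder)]) {
      rows <- which(remaining)
      if (!length(rows)) break
      isPos <- y[rows] == cls
      if (!sum(isPos)) next
      Xc <- X[rows, , drop = FALSE]
      rl <- learnClassRules(Xc, isPos, growFraction, mdlSlack)
      if (optimizePasses > 0 && length(rl))
        rl <- optimizeClassRules(rl, Xc, isPos, growFraction, optimizePasses)
      for (conds in rl)
        rules[[length(rules) + 1L]] <- rule(conds, cls)
      if (length(rl)) {
        cov <- rep(FALSE, length(rows))
        for (conds in rl) cov <- cov | ruleCovers(conds, Xc)
        remaining[rows[cov]] <- FALSE
      }
    }
  })
  ruleSet(c(rules, list(rule(NULL, defaultCls))))
}
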