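#' Monte Carlo feature selection parameters
#'
#' @param m genes per random projection; `NA` (default) resolves to
#'   `max(ceiling(0.05 * N), 2)` against the dataset.
#' @param t number of random feature subsets (default 100).
#' @param p trees per subset (default 5); `p * t` trees in total.
#' @param u,v exponents on the tree weighted accuracy and on the node sample
#'   fraction in the relative-importance sum (defaults 1, the method's
#'   standard setting).
#' @param trainFraction fraction of samples in each tree's training split
#'   (default 0.66).
#' @param resample `"split"` (stratified subsample; complement held out) or
#'   `"bootstrap"` (within-class bootstrap; out-of-bag held out).
#' @param seed integer master seed.
#' @return an [MCFSParams-class].
#' @export
mcfsParams <- function(m = NA, t = 100L, p = 5L, u = 1, v = 1,
                       trainFraction = 0.66, resample = "split", seed = 1L) {
  methods::new("MCFSParams", m = as.integer(m), t = as.integer(t),
               p = as.integer(p), u = as.numeric(u), v = as.numeric(v),
               trainFraction = as.numeric(trainFraction),
               resample = resample, seed = as.integer(seed))
}

#' Class-balanced weighted accuracy of a confusion matrix
#'
#' The unweighted mean of per-class recalls; classes absent from the
#' held-out set (zero row sum) are excluded from the average.  This is the
#' class-balanced accuracy weighting the trees in the relative-importance
#' sum, robust to the cohort's roughly three-fold class-size imbalance.
#'
#' @param confusion C x C count matrix, rows true classes.
#' @return a number in `[0, 1]`.
#' @examples
#' weightedAccuracy(matrix(c(5, 3, 0, 0), 2))  # 0.5
#' @export
weightedAccuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stopf("confusion matrix must be square")
  rs <- rowSums(confusion)
  if (all(rs == 0)) stopf("weighted accuracy undefined for an all-zero confusion matrix")
  keep <- rs > 0
  mean(diag(confusion)[keep] / rs[keep])
}

resolveM <- function(params, N) {
  m <- if (is.na(params@m)) max(ceiling(0.05 * N), 2L) else params@m
  if (m > N) stopf("m (%d) exceeds the number of genes (%d)", m, N)
  as.integer(m)
}

## Draw one train/test split per the params' resampling mode.  Stratified by
## class so every class is present in training; retries (bounded) if the
## held-out complement comes up empty.
drawSplit <- function(y, params) {
  n <- length(y)
  for (attempt in 1:10) {
    train <- integer(0)
    if (params@resample == "split") {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        k <- max(1L, min(length(idx), ceiling(params@trainFraction * length(idx))))
        train <- c(train, idx[sample.int(length(idx), k)])
      }
      test <- setdiff(seq_len(n), train)
    } else {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        train <- c(train, idx[sample.int(length(idx), length(idx),
                                         replace = TRUE)])
      }
      test <- setdiff(seq_len(n), unique(train))
    }
    if (length(test) > 0 && all(levels(y) %in% y[train]))
      return(list(train = sort(train), test = test))
  }
  stopf("could not draw a training split containing every class")
}

#' Grow the MCFS projection-tree ensemble
#'
#' For each of `t` feature subsets (m genes sampled uniformly without
#' replacement), `p` classification trees are grown, each on an independent
#' stratified training split, with the tree's class-balanced weighted
#' accuracy computed on the held-out complement.  Trees split on Shannon
#' information gain with minimum leaf size 2 and no pruning.
#'
#' @param ds a [LabeledDataset-class].
#' @param params an [MCFSParams-class].
#' @return a [TreeEnsemble-class] of `p * t` trees.
#' @export
growProjectionTrees <- function(ds, params = mcfsParams()) {
  stopifnot(is(ds, "LabeledDataset"), is(params, "MCFSParams"))
  methods::validObject(params)
  N <- nrow(ds)
  m <- resolveM(params, N)
  X <- t(exprsMatrix(ds))
  y <- classLabels(ds)
  yi <- as.integer(y) - 1L
  nc <- nlevels(y)

  subsets <- withSeed(deriveSeed(params@seed, "subsets"),
                      lapply(seq_len(params@t),
                             function(i) sort(sample.int(N, m))))
  trees <- withSeed(deriveSeed(params@seed, "splits"), {
    out <- vector("list", params@t * params@p)
    k <- 0L
    for (i in seq_len(params@t)) {
      cols <- subsets[[i]]
      Xi <- X[, cols, drop = FALSE]
      for (j in seq_len(params@p)) {
        sp <- drawSplit(y, params)
        tr <- .grow_tree_cpp(Xi[sp$train, , drop = FALSE], yi[sp$train],
                             nc, 2L)
        pred <- .predict_tree_cpp(tr, Xi[sp$test, , drop = FALSE])
        conf <- table(factor(y[sp$test], levels = levels(y)),
                      factor(levels(y)[pred + 1L], levels = levels(y)))
        tr$feature <- cols[tr$feature]   # local -> global gene indices
        tr$wAcc <- weightedAccuracy(conf)
        tr$rootN <- length(sp$train)
        k <- k + 1L
        out[[k]] <- tr
      }
    }
    out
  })
  methods::new("TreeEnsemble", trees = trees, params = params,
               genes = rownames(ds))
}

#' Relative importance of every gene from a tree ensemble
#'
#' For gene g, sums over every node (in every tree) splitting on g the
#' product `wAcc^u * IG(node) * (node samples / root samples)^v`, with
#' exponents u, v from the ensemble's parameters.  Genes that split no node
#' score exactly 0.
#'
#' @param ens a [TreeEnsemble-class].
#' @return named numeric vector of RI scores, one per gene.
#' @export
computeRelativeImportance <- function(ens) {
  stopifnot(is(ens, "TreeEnsemble"))
  if (!length(ens@trees)) stopf("empty ensemble")
  u <- ens@params@u
  v <- ens@params@v
  ri <- numeric(length(ens@genes))
  for (tr in ens@trees) {
    internal <- which(!is.na(tr$feature))
    if (!length(internal)) next
    contrib <- tr$wAcc^u * tr$ig[internal] *
      (tr$n_node[internal] / tr$rootN)^v
    g <- tr$feature[internal]
    agg <- rowsum(contrib, g)
    idx <- as.integer(rownames(agg))
    ri[idx] <- ri[idx] + agg[, 1]
  }
  stats::setNames(ri, ens@genes)
}

#' Rank genes by relative importance
#'
#' Stable descending sort; ties broken by ascending gene index for
#' determinism.
#'
#' @param ri named numeric RI vector (one score per gene, in matrix order).
#' @return a [FeatureRanking-class].
#' @export
rankFeatures <- function(ri) {
  if (is.null(names(ri))) names(ri) <- sprintf("g%d", seq_along(ri))
  ord <- order(-ri, seq_along(ri))
  methods::new("FeatureRanking", ranking = as.integer(ord),
               genes = names(ri), ri = as.numeric(stats::setNames(ri, NULL)))
}

#' @rdname pdxsite-generics
#' @export
setMethod("rankedGenes", "FeatureRanking", function(x, ...)
  x@genes[x@ranking])

#' @rdname pdxsite-generics
#' @export
setMethod("riScores", "FeatureRanking", function(x, ...)
  stats::setNames(x@ri, x@genes))

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking of", length(object@genes), "genes; top 5:",
      paste(head(rankedGenes(object), 5), collapse = ", "), "\n")
})

#' Convenience: full MCFS ranking of a dataset
#'
#' @inheritParams growProjectionTrees
#' @return list with `ensemble`, `ri` and `ranking`.
#' @export
mcfsRank <- function(ds, params = mcfsParams()) {
  ens <- growProjectionTrees(ds, params)
  ri <- computeRelativeImportance(ens)
  list(ensemble = ens, ri = ri, ranking = rankFeatures(ri))
}

#' Permutation test for the informative-feature threshold
#'
#' Reruns the full MCFS relative-importance computation on label-permuted
#' copies of the dataset, records each run's maximal RI, and sets the
#' threshold as the one-sided upper (1 - alpha) Student-t prediction bound on
#' a new maximal-RI draw: `mean + t_{1-alpha, n-1} * sd * sqrt(1 + 1/n)`.
#' Genes whose observed RI exceeds the threshold are flagged informative.
#'
#' @param ds a [LabeledDataset-class].
#' @param params an [MCFSParams-class]; the observed RI run is seeded from
#'   `params@seed`, permuted runs from derived sub-seeds.
#' @param nPermutations number of label permutations (default 20).
#' @param alpha one-sided significance level (default 0.05).
#' @param ri optional precomputed observed RI vector (skips the observed run).
#' @return list with `threshold` ([RIThreshold-class]), `informative`
#'   (character vector of genes), and `ri` (observed scores).
#' @export
permutationThreshold <- function(ds, params = mcfsParams(),
                                 nPermutations = 20L, alpha = 0.05,
                                 ri = NULL) {
  if (nPermutations < 3) stopf("need at least 3 permutations")
  if (is.null(ri)) ri <- computeRelativeImportance(growProjectionTrees(ds, params))
  y <- classLabels(ds)
  maxris <- vapply(seq_len(nPermutations), function(k) {
    yp <- withSeed(deriveSeed(params@seed, paste0("permlabels", k)),
                   sample(y))
    dsp <- labeledDataset(exprsMatrix(ds),
                          stats::setNames(as.character(yp), colnames(ds)))
    pp <- params
    pp@seed <- deriveSeed(params@seed, paste0("permrun", k))
    max(computeRelativeImportance(growProjectionTrees(dsp, pp)))
  }, numeric(1))
  s <- sd(maxris)
  if (s == 0) {
    warnf("zero variance across permutation maxima; falling back to their maximum")
    thr <- max(maxris)
  } else {
    thr <- mean(maxris) +
      qt(1 - alpha, nPermutations - 1) * s * sqrt(1 + 1 / nPermutations)
  }
  list(threshold = methods::new("RIThreshold", threshold = thr,
                                alpha = alpha, permutationMaxRIs = maxris,
                                nPermutations = as.integer(nPermutations)),
       informative = names(ri)[ri > thr],
       ri = ri)
}

setMethod("show", "RIThreshold", function(object) {
  cat(sprintf("RIThreshold: %.4g (alpha = %.3g, %d permutations)\n",
              object@threshold, object@alpha, object@nPermutations))
})

setMethod("show", "TreeEnsemble", function(object) {
  cat("TreeEnsemble:", length(object@trees), "trees over",
      length(object@genes), "genes\n")
})
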