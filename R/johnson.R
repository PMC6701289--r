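#' Johnson reducer: greedy discernibility set cover
#'
#' Rough-set feature reduction over MDL-discretized genes.  A gene discerns
#' a pair of differently labeled samples when the two samples fall in
#' different discretization bins of that gene.  The reducer repeatedly
#' picks the gene discerning the most not-yet-covered pairs until every
#' discernible pair is covered.  Ties are broken by the highest
#' relative-importance score when one is supplied, then by ascending gene
#' index.  Indiscernible pairs (identical bins on every candidate gene) are
#' reported via an attribute, not an error.
#'
#' @param ds a [LabeledDataset-class].
#' @param candidateGenes gene identifiers or indices (non-empty).
#' @param ri optional named RI vector used for tie-breaking.
#' @param maxSamples above this many samples, a seeded stratified subsample
#'   of this size is used for exact pair coverage (default 2000).
#' @param seed seed for the subsample draw.
#' @return character vector of selected genes, in coverage order, with
#'   attribute `indiscerniblePairs`.
#' @export
johnsonReducer <- function(ds, candidateGenes, ri = NULL, maxSamples = 2000L,
                           seed = 1L) {
  if (!length(candidateGenes)) stopf("candidateGenes must be non-empty")
  idx <- resolveFeatures(ds, candidateGenes)
  y <- classLabels(ds)
  if (length(y) > maxSamples) {
    keep <- withSeed(deriveSeed(seed, "johnson"), {
      prop <- maxSamples / length(y)
      unlist(lapply(levels(y), function(cl) {
        w <- which(y == cl)
        w[sample.int(length(w), max(2L, floor(prop * length(w))))]
      }))
    })
    ds <- ds[, sort(keep)]
    y <- classLabels(ds)
  }
  cuts <- discretizeMDL(ds, idx)
  m <- exprsMatrix(ds)
  bins <- vapply(seq_along(idx),
                 function(k) findInterval(m[idx[k], ], cuts[[k]]),
                 integer(ncol(ds)))           # samples x candidates
  ## between-class sample pairs
  pairs <- which(outer(as.integer(y), as.integer(y), "!=") &
                 upper.tri(matrix(TRUE, length(y), length(y))), arr.ind = TRUE)
  nPairs <- nrow(pairs)
  ## discernibility: pair x candidate logical
  disc <- bins[pairs[, 1], , drop = FALSE] != bins[pairs[, 2], , drop = FALSE]
  covered <- rep(FALSE, nPairs)
  coverable <- rowSums(disc) > 0
  tie <- if (!is.null(ri)) -ri[rownames(ds)[idx]] else rep(0, length(idx))
  chosen <- integer(0)
  while (any(!covered & coverable)) {
    gain <- colSums(disc & !covered)
    best <- order(-gain, tie, seq_along(idx))[1]
    if (gain[best] == 0) break
    chosen <- c(chosen, best)
    covered <- covered | disc[, best]
  }
  res <- rownames(ds)[idx[chosen]]
  attr(res, "indiscerniblePairs") <- sum(!coverable)
  res
}
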