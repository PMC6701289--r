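## Entropy/MDL (Fayyad-Irani) recursive discretization, the preprocessing
## step for the rough-set reducer.

entropyBits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

## Recursive MDL cut search on (values, integer labels).  Returns accepted
## cut points (midpoints between adjacent distinct values).
mdlCuts <- function(x, y, nClasses) {
  n <- length(x)
  if (n < 4) return(numeric(0))
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  total <- tabulate(y, nClasses)
  ent <- entropyBits(total)
  if (ent == 0) return(numeric(0))

  ## candidate boundaries: between adjacent distinct values
  distinct <- which(diff(x) > 0)
  if (!length(distinct)) return(numeric(0))
  bestGain <- -Inf; bestI <- NA; bestStats <- NULL
  left <- integer(nClasses)
  li <- 0L
  for (i in distinct) {
    while (li < i) { li <- li + 1L; left[y[li]] <- left[y[li]] + 1L }
    right <- total - left
    e1 <- entropyBits(left); e2 <- entropyBits(right)
    gain <- ent - (i / n) * e1 - ((n - i) / n) * e2
    if (gain > bestGain + 1e-12) {
      bestGain <- gain; bestI <- i
      bestStats <- list(e1 = e1, e2 = e2,
                        k1 = sum(left > 0), k2 = sum(right > 0))
    }
  }
  if (!is.finite(bestGain)) return(numeric(0))
  k <- sum(total > 0)
  delta <- log2(3^k - 2) -
    (k * ent - bestStats$k1 * bestStats$e1 - bestStats$k2 * bestStats$e2)
  if (bestGain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (x[bestI] + x[bestI + 1]) / 2
  sort(c(mdlCuts(x[seq_len(bestI)], y[seq_len(bestI)], nClasses),
         cut,
         mdlCuts(x[(bestI + 1):n], y[(bestI + 1):n], nClasses)))
}

#' MDL-based cut points per gene
#'
#' Fayyad-Irani recursive entropy/MDL discretization of each gene's values
#' against the class labels.  Genes for which the MDL criterion accepts no
#' cut (including constant genes) fall back to a single median cut, flagged
#' via the `fallback` attribute.
#'
#' @param ds a [LabeledDataset-class] with at least 2 classes.
#' @param genes gene identifiers or indices to discretize (default: all).
#' @return named list of numeric cut-point vectors; each element carries a
#'   logical attribute `fallback`.
#' @export
discretizeMDL <- function(ds, genes = rownames(ds)) {
  if (nlevels(classLabels(ds)) < 2) stopf("need at least 2 classes")
  idx <- resolveFeatures(ds, genes)
  m <- exprsMatrix(ds)
  y <- as.integer(classLabels(ds))
  nc <- nlevels(classLabels(ds))
  out <- lapply(idx, function(i) {
    cuts <- mdlCuts(m[i, ], y, nc)
    if (!length(cuts)) {
      cuts <- median(m[i, ])
      attr(cuts, "fallback") <- TRUE
    } else attr(cuts, "fallback") <- FALSE
    cuts
  })
  names(out) <- rownames(ds)[idx]
  out
}
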