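#' Multi-class Matthews correlation coefficient (Gorodkin form)
#'
#' Computes `cov(X, Y) / sqrt(cov(X, X) * cov(Y, Y))` from n x C binary
#' indicator matrices of predictions (X) and truth (Y), where covariances
#' are summed over all columns about their column means.  For C = 2 this is
#' exactly the classical binary Matthews correlation.  When either variance
#' term is zero (a constant prediction or a single-class truth) the
#' coefficient is 0 by convention.
#'
#' @param X n x C binary prediction indicator matrix (one 1 per row).
#' @param Y n x C binary truth indicator matrix (one 1 per row).
#' @return a number in `[-1, 1]`.
#' @export
multiclassMCC <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stopf("X and Y must have identical dimensions")
  if (any(rowSums(X) != 1) || any(rowSums(Y) != 1))
    stopf("each row of X and Y must contain exactly one 1")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- sum(Xc * Yc)
  den <- sqrt(sum(Xc * Xc) * sum(Yc * Yc))
  if (den == 0) return(0)
  num / den
}

## Expand a confusion matrix (rows truth, cols predicted) into the indicator
## matrices the MCC definition works on.
confusionToIndicators <- function(confusion) {
  C <- nrow(confusion)
  n <- sum(confusion)
  X <- matrix(0L, n, C)
  Y <- matrix(0L, n, C)
  r <- 1L
  for (i in seq_len(C)) for (j in seq_len(C)) {
    k <- confusion[i, j]
    if (k > 0) {
      rows <- r:(r + k - 1L)
      Y[rows, i] <- 1L
      X[rows, j] <- 1L
      r <- r + as.integer(k)
    }
  }
  list(X = X, Y = Y)
}

#' Per-class and overall accuracy of a confusion matrix
#'
#' The individual accuracy of class i is its diagonal count over its row sum
#' (its recall); the overall accuracy is the total diagonal over the total
#' count.
#'
#' @param confusion C x C count matrix, rows true classes.
#' @return list with `perClass` (numeric) and `overall` (number).
#' @examples
#' accuracyMetrics(matrix(c(3, 2, 1, 4), 2))  # perClass 0.75, 2/3; overall 0.7
#' @export
accuracyMetrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stopf("confusion matrix must be square")
  rs <- rowSums(confusion)
  if (any(rs < 1)) stopf("every class row must contain at least one sample")
  list(perClass = stats::setNames(diag(confusion) / rs, rownames(confusion)),
       overall = sum(diag(confusion)) / sum(confusion))
}

#' Build a PerformanceReport from a confusion matrix
#'
#' @param confusion C x C count matrix, rows true classes, columns predicted.
#' @return a [PerformanceReport-class] with per-class accuracies, overall
#'   accuracy and multi-class MCC.
#' @export
performanceReport <- function(confusion) {
  confusion <- as.matrix(confusion)
  acc <- accuracyMetrics(confusion)
  ind <- confusionToIndicators(confusion)
  methods::new("PerformanceReport", confusion = confusion,
               perClassAccuracy = acc$perClass,
               overallAccuracy = acc$overall,
               mcc = multiclassMCC(ind$X, ind$Y))
}

#' @rdname pdxsite-generics
#' @export
setMethod("confusionMatrix", "PerformanceReport", function(x, ...) x@confusion)

#' @rdname pdxsite-generics
#' @export
setMethod("mcc", "PerformanceReport", function(x, ...) x@mcc)

#' @rdname pdxsite-generics
#' @export
setMethod("overallAccuracy", "PerformanceReport", function(x, ...)
  x@overallAccuracy)

#' @rdname pdxsite-generics
#' @export
setMethod("perClassAccuracy", "PerformanceReport", function(x, ...)
  x@perClassAccuracy)

setMethod("show", "PerformanceReport", function(object) {
  cat(sprintf("PerformanceReport: ACC = %.3f, MCC = %.3f over %d samples\n",
              object@overallAccuracy, object@mcc, sum(object@confusion)))
})

## data.frame row used by the IFS curve writers: size, per-class ACC, ACC, MCC
reportRow <- function(report) {
  pc <- as.list(report@perClassAccuracy)
  names(pc) <- paste0("ACC_", names(pc))
  c(pc, list(ACC = report@overallAccuracy, MCC = report@mcc))
}
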