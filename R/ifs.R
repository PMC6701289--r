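## Two-stage incremental feature selection around the one-vs-rest SVM.

#' Evaluate growing prefixes of a ranked feature list
#'
#' Evaluates the prefixes of sizes `start, start + step, ..., <= stop` of
#' the ranking by cross-validated one-vs-rest SVM and returns the curve.
#' Kernel matrices are updated incrementally across prefixes, so a
#' fine-step curve costs little more than its last point.
#'
#' @param ds a [LabeledDataset-class].
#' @param ranking a [FeatureRanking-class] covering `ds`.
#' @param start,stop,step prefix-size grid (1 <= start <= stop <= N).
#' @param clf a [ClassifierConfig-class].
#' @param cv a [CVConfig-class].
#' @return an [IFSCurve-class].
#' @export
ifsStage <- function(ds, ranking, start, stop, step = 1L,
                     clf = classifierConfig(), cv = cvConfig()) {
  stopifnot(is(ranking, "FeatureRanking"))
  N <- nrow(ds)
  if (length(ranking@ranking) != N)
    stopf("ranking does not cover the dataset")
  if (start < 1 || stop > N || start > stop || step < 1)
    stopf("need 1 <= start <= stop <= N and step >= 1")
  sizes <- seq.int(start, stop, by = step)
  ord <- ranking@ranking
  blocks <- vector("list", length(sizes))
  prev <- 0L
  for (i in seq_along(sizes)) {
    blocks[[i]] <- ord[seq.int(prev + 1L, sizes[i])]
    prev <- sizes[i]
  }
  reports <- cvEngine(t(exprsMatrix(ds)), classLabels(ds), clf, cv, blocks)
  methods::new("IFSCurve", sizes = as.integer(sizes), reports = reports)
}

#' @describeIn ifsStage flatten an IFS curve to a data.frame with one row
#'   per evaluated prefix (`n_features`, per-class accuracies, `ACC`, `MCC`).
#' @param x an [IFSCurve-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "IFSCurve", function(x, ...) {
  rows <- lapply(seq_along(x@sizes), function(i)
    as.data.frame(c(list(n_features = x@sizes[i]), reportRow(x@reports[[i]]))))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
})

setMethod("show", "IFSCurve", function(object) {
  mccs <- vapply(object@reports, mcc, numeric(1))
  cat(sprintf("IFSCurve: %d prefixes in [%d, %d], best MCC %.3f at %d features\n",
              length(object@sizes), min(object@sizes), max(object@sizes),
              max(mccs), object@sizes[which.max(mccs)]))
})

bestPoint <- function(curve) {
  mccs <- vapply(curve@reports, mcc, numeric(1))
  i <- which.max(mccs)   # first maximum = smallest size on ties
  list(size = curve@sizes[i], report = curve@reports[[i]], mcc = mccs[i])
}

#' Two-stage incremental feature selection
#'
#' Stage 1 scans prefixes of the ranking with a coarse step over the whole
#' list; stage 2 rescans with step 1 inside a symmetric interval around the
#' coarse optimum (`+/- intervalHalfwidthSteps * coarseStep`, clipped to
#' `[1, N]`).  The optimal feature set is the stage-2 prefix with the
#' highest MCC, smallest size on ties.
#'
#' @param ds a [LabeledDataset-class].
#' @param ranking a [FeatureRanking-class].
#' @param coarseStep stage-1 step (default 10).
#' @param intervalHalfwidthSteps half-width of the stage-2 interval in units
#'   of `coarseStep` (default 10).
#' @param clf,cv classifier and CV configuration.
#' @return list with `optimal` ([OptimalFeatureSet-class]), `stage1` and
#'   `stage2` ([IFSCurve-class]).
#' @export
twoStageIFS <- function(ds, ranking, coarseStep = 10L,
                        intervalHalfwidthSteps = 10L,
                        clf = classifierConfig(), cv = cvConfig()) {
  N <- nrow(ds)
  coarseStep <- as.integer(coarseStep)
  stage1 <- if (N < coarseStep)
    ifsStage(ds, ranking, N, N, 1L, clf, cv)
  else
    ifsStage(ds, ranking, coarseStep, N, coarseStep, clf, cv)
  b <- bestPoint(stage1)
  hw <- as.integer(intervalHalfwidthSteps) * coarseStep
  lo <- max(1L, b$size - hw)
  hi <- min(N, b$size + hw)
  stage2 <- ifsStage(ds, ranking, lo, hi, 1L, clf, cv)
  b2 <- bestPoint(stage2)
  idx <- ranking@ranking[seq_len(b2$size)]
  optimal <- methods::new("OptimalFeatureSet",
                          genes = ranking@genes[idx],
                          indices = as.integer(idx),
                          size = as.integer(b2$size), report = b2$report)
  list(optimal = optimal, stage1 = stage1, stage2 = stage2)
}

setMethod("show", "OptimalFeatureSet", function(object) {
  cat(sprintf("OptimalFeatureSet: %d genes, MCC %.3f\n", object@size,
              mcc(object@report)))
})

#' Significance of an observed MCC against random feature subsets
#'
#' Draws uniform random gene subsets of the given size, evaluates each with
#' the cross-validated one-vs-rest SVM, and locates the observed MCC in the
#' resulting null distribution.  The empirical p-value uses the add-one
#' estimator `(1 + #(random >= observed)) / (n + 1)`; the reported
#' significance line is the 95th percentile of the random MCCs.
#'
#' @param ds a [LabeledDataset-class].
#' @param subsetSize number of genes per random subset.
#' @param nSubsets number of random subsets (published protocol: 1000).
#' @param clf,cv classifier and CV configuration.
#' @param observedMcc the MCC to be tested.
#' @param seed integer seed for the subset draws.
#' @return list with `p`, `mccs` and `alphaThreshold`.
#' @export
randomSubsetSignificance <- function(ds, subsetSize, nSubsets = 1000L,
                                     clf = classifierConfig(),
                                     cv = cvConfig(), observedMcc,
                                     seed = 1L) {
  N <- nrow(ds)
  if (subsetSize > N) stopf("subsetSize exceeds the number of genes")
  subsets <- withSeed(deriveSeed(seed, "subsets"),
                      lapply(seq_len(nSubsets),
                             function(i) sample.int(N, subsetSize)))
  X <- t(exprsMatrix(ds))
  y <- classLabels(ds)
  mccs <- vapply(subsets, function(s)
    mcc(cvEngine(X, y, clf, cv, list(s))[[1]]), numeric(1))
  list(p = (1 + sum(mccs >= observedMcc)) / (nSubsets + 1),
       mccs = mccs,
       alphaThreshold = unname(quantile(mccs, 0.95)))
}
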