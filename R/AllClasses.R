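## S4 classes for the tissue-of-origin pipeline.

#' LabeledDataset: expression matrix with per-sample tissue labels
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples matrix of continuous log-scale expression values in the
#' `"exprs"` assay and one tissue-class label per sample in
#' `colData(x)$class`.  Gene order defines feature indices `1..N` for the
#' feature-selection stages.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("LabeledDataset", contains = "SummarizedExperiment")

setValidity("LabeledDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msg <- c(msg, "'exprs' must be numeric")
    else if (any(!is.finite(m)))
      msg <- c(msg, "'exprs' must be finite (missing values are rejected, not imputed)")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)) ||
      any(!nzchar(rownames(object))))
    msg <- c(msg, "gene identifiers must be non-empty and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"class" %in% colnames(cd))
    msg <- c(msg, "colData column 'class' (tissue label) is required")
  else {
    cl <- cd$class
    if (!is.factor(cl)) msg <- c(msg, "'class' must be a factor")
    else if (any(table(cl) < 1) || nlevels(cl) < 1)
      msg <- c(msg, "every class level must have at least one sample")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of Monte Carlo feature selection
#'
#' @slot m integer, genes per random projection; `NA` means the default
#'   `max(ceiling(0.05 * N), 2)` resolved against the dataset.
#' @slot t integer, number of random feature subsets.
#' @slot p integer, trees grown per subset (`p * t` trees in total).
#' @slot u,v numeric exponents on the tree's weighted accuracy and on the
#'   node sample fraction in the relative-importance sum (defaults 1).
#' @slot trainFraction fraction of samples in each tree's training split.
#' @slot resample `"split"` (stratified subsample, held-out complement) or
#'   `"bootstrap"` (within-class bootstrap, out-of-bag complement).
#' @slot seed integer master seed for subset and split draws.
#' @export
setClass("MCFSParams", representation(
  m = "integer", t = "integer", p = "integer",
  u = "numeric", v = "numeric", trainFraction = "numeric",
  resample = "character", seed = "integer"))

setValidity("MCFSParams", function(object) {
  msg <- character()
  if (!is.na(object@m) && object@m < 1) msg <- c(msg, "m must be >= 1")
  if (object@t < 1 || object@p < 1) msg <- c(msg, "t and p must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (!object@resample %in% c("split", "bootstrap"))
    msg <- c(msg, "resample must be 'split' or 'bootstrap'")
  if (length(msg)) msg else TRUE
})

#' Ensemble of MCFS projection trees
#'
#' Each element of `trees` is a list with per-node vectors `feature` (global
#' gene index, `NA` at leaves), `threshold`, `ig` (Shannon information gain,
#' bits), `n_node` (training samples reaching the node), `left`, `right`,
#' `pred`, plus the tree's held-out weighted accuracy `wAcc` and its root
#' training-set size `rootN`.
#'
#' @slot trees list of trees.
#' @slot params the [MCFSParams-class] used.
#' @slot genes character vector of gene identifiers (defines indices).
#' @export
setClass("TreeEnsemble", representation(
  trees = "list", params = "MCFSParams", genes = "character"))

setValidity("TreeEnsemble", function(object) {
  for (tr in object@trees) {
    if (!all(c("feature", "ig", "n_node", "wAcc", "rootN") %in% names(tr)))
      return("malformed tree record")
    if (any(tr$ig < 0)) return("information gain must be non-negative")
    if (!is.na(tr$wAcc) && (tr$wAcc < 0 || tr$wAcc > 1))
      return("wAcc must lie in [0, 1]")
  }
  TRUE
})

#' Genes ranked by relative importance
#'
#' @slot ranking integer permutation of `1..N` (descending RI, ties broken
#'   by ascending gene index).
#' @slot genes gene identifiers in original matrix order.
#' @slot ri numeric RI score per gene (original order).
#' @export
setClass("FeatureRanking", representation(
  ranking = "integer", genes = "character", ri = "numeric"))

setValidity("FeatureRanking", function(object) {
  n <- length(object@genes)
  if (length(object@ranking) != n || length(object@ri) != n)
    return("ranking, genes and ri must have equal length")
  if (!identical(sort(object@ranking), seq_len(n)))
    return("ranking must be a permutation of 1..N")
  TRUE
})

#' Permutation-derived informative-feature threshold
#'
#' @slot threshold numeric RI cutoff.
#' @slot alpha one-sided significance level of the Student-t prediction bound.
#' @slot permutationMaxRIs maximal RI observed in each label-permuted run.
#' @slot nPermutations number of permuted runs.
#' @export
setClass("RIThreshold", representation(
  threshold = "numeric", alpha = "numeric",
  permutationMaxRIs = "numeric", nPermutations = "integer"))

setValidity("RIThreshold", function(object) {
  if (length(object@permutationMaxRIs) != object@nPermutations)
    return("one max-RI value per permutation is required")
  if (!is.finite(object@threshold) || object@threshold <= 0)
    return("threshold must be a positive number")
  TRUE
})

#' One-vs-rest SVM configuration
#'
#' @slot kernel `"rbf"` or `"linear"`.
#' @slot cost soft-margin cost C (> 0).
#' @slot gamma RBF width; `NA` means "auto": `1 / (d * mean feature variance)`
#'   computed on the standardized training fold.
#' @slot probabilityMethod label of the score-to-probability mapping
#'   (`"platt"`: sigmoid fit on training decision values).
#' @export
setClass("ClassifierConfig", representation(
  kernel = "character", cost = "numeric", gamma = "numeric",
  probabilityMethod = "character"))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (!object@kernel %in% c("rbf", "linear"))
    msg <- c(msg, "kernel must be 'rbf' or 'linear'")
  if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
  if (!is.na(object@gamma) && object@gamma <= 0)
    msg <- c(msg, "gamma must be > 0 or NA ('auto')")
  if (length(msg)) msg else TRUE
})

#' Cross-validation configuration
#'
#' @slot folds number of folds (default 10; reduced with a warning when a
#'   class has fewer samples than folds).
#' @slot repeats number of repetitions; confusion counts are summed over
#'   repeats.
#' @slot stratified logical; stratified fold assignment.
#' @slot seed integer seed for fold draws.
#' @export
setClass("CVConfig", representation(
  folds = "integer", repeats = "integer", stratified = "logical",
  seed = "integer"))

setValidity("CVConfig", function(object) {
  if (object@folds < 2) return("folds must be >= 2")
  if (object@repeats < 1) return("repeats must be >= 1")
  TRUE
})

#' Multi-class performance report
#'
#' Confusion matrix (rows: truth, columns: predicted) with the per-class
#' accuracies, the overall accuracy and the Gorodkin multi-class Matthews
#' correlation coefficient derived from it.
#'
#' @slot confusion C x C count matrix.
#' @slot perClassAccuracy numeric per-class recall.
#' @slot overallAccuracy numeric.
#' @slot mcc numeric in `[-1, 1]`.
#' @export
setClass("PerformanceReport", representation(
  confusion = "matrix", perClassAccuracy = "numeric",
  overallAccuracy = "numeric", mcc = "numeric"))

setValidity("PerformanceReport", function(object) {
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
  if (any(cm < 0)) return("confusion counts must be non-negative")
  if (abs(object@overallAccuracy - sum(diag(cm)) / sum(cm)) > 1e-8)
    return("overall accuracy inconsistent with confusion matrix")
  if (object@mcc < -1 - 1e-12 || object@mcc > 1 + 1e-12)
    return("mcc must lie in [-1, 1]")
  TRUE
})

#' Incremental-feature-selection curve
#'
#' @slot sizes strictly increasing feature-prefix sizes.
#' @slot reports list of [PerformanceReport-class], one per size.
#' @export
setClass("IFSCurve", representation(sizes = "integer", reports = "list"))

setValidity("IFSCurve", function(object) {
  if (length(object@sizes) != length(object@reports))
    return("one report per evaluated size is required")
  if (is.unsorted(object@sizes, strictly = TRUE))
    return("sizes must be strictly increasing")
  TRUE
})

#' Optimal feature set chosen by incremental feature selection
#'
#' @slot genes gene identifiers of the optimal prefix.
#' @slot indices their indices in the original matrix.
#' @slot size prefix length.
#' @slot report the [PerformanceReport-class] at the optimum.
#' @export
setClass("OptimalFeatureSet", representation(
  genes = "character", indices = "integer", size = "integer",
  report = "PerformanceReport"))

#' A single IF-THEN threshold rule
#'
#' @slot conditions data.frame with columns `gene`, `op` (`">="` or `"<="`),
#'   `threshold`; zero rows for the default rule.
#' @slot consequent predicted class label.
#' @export
setClass("Rule", representation(conditions = "data.frame",
                                consequent = "character"))

setValidity("Rule", function(object) {
  cd <- object@conditions
  if (!all(c("gene", "op", "threshold") %in% colnames(cd)))
    return("conditions need columns gene, op, threshold")
  if (nrow(cd) && !all(cd$op %in% c(">=", "<=")))
    return("condition operators must be '>=' or '<='")
  if (nrow(cd) && any(!is.finite(cd$threshold)))
    return("thresholds must be finite")
  if (length(object@consequent) != 1 || !nzchar(object@consequent))
    return("consequent must be a single non-empty class label")
  TRUE
})

#' Ordered rule set with a default class
#'
#' @slot rules ordered list of [Rule-class]; exactly one rule with an empty
#'   condition list (the default), in last position.
#' @export
setClass("RuleSet", representation(rules = "list"))

setValidity("RuleSet", function(object) {
  if (!length(object@rules)) return("a rule set needs at least the default rule")
  nc <- vapply(object@rules, function(r) nrow(r@conditions), integer(1))
  if (sum(nc == 0) != 1 || nc[length(nc)] != 0)
    return("exactly one empty-condition (default) rule is allowed, last")
  TRUE
})

#' Synthetic cohort configuration
#'
#' @slot seed integer generator seed.
#' @slot classSizes named integer vector of per-class sample counts.
#' @slot nGenes total number of genes N.
#' @slot markersPerClass planted marker genes per class.
#' @slot effectSize log-units up-shift of a marker in its own class.
#' @slot baselineMean,noiseSd Gaussian background mean / sd (log scale).
#' @slot markerOverlap if `TRUE`, each class additionally shares one marker
#'   with the next class, exercising multi-condition rules.
#' @export
setClass("SyntheticConfig", representation(
  seed = "integer", classSizes = "integer", nGenes = "integer",
  markersPerClass = "integer", effectSize = "numeric",
  baselineMean = "numeric", noiseSd = "numeric", markerOverlap = "logical"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (any(object@classSizes < 1)) msg <- c(msg, "class sizes must be >= 1")
  if (is.null(names(object@classSizes)) || any(!nzchar(names(object@classSizes))))
    msg <- c(msg, "classSizes must be named by class")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@markersPerClass < 0) msg <- c(msg, "markersPerClass must be >= 0")
  if (!object@markerOverlap &&
      object@markersPerClass * length(object@classSizes) > object@nGenes)
    msg <- c(msg, "markersPerClass * classes must be <= nGenes for disjoint markers")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot markerMap named list, class -> character vector of planted marker
#'   gene ids.
#' @slot config the [SyntheticConfig-class] used.
#' @export
setClass("GroundTruth", representation(markerMap = "list",
                                       config = "SyntheticConfig"))
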