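## Synthetic multi-class expression cohorts with planted marker genes.
##
## The generator emulates the 8-tissue PDX cohort shape: unbalanced classes,
## log-scale Gaussian expression, a small set of class-specific markers
## shifted up by a fixed effect against a large uninformative background.

PDX_CLASS_SIZES <- c(
  breast = 79L, kidney = 41L, `large intestine` = 121L, lung = 99L,
  ovary = 52L, pancreas = 94L, skin = 46L, `soft tissue` = 62L)
PDX_N_GENES <- 20502L

#' Synthetic cohort configuration
#'
#' @param classSizes named integer vector of per-class sample counts.
#' @param nGenes total gene count N.
#' @param markersPerClass planted markers per class (default 5).
#' @param effectSize log-units shift of a marker within its class (default 3).
#' @param baselineMean,noiseSd background Gaussian mean / sd (defaults 4, 1;
#'   the resulting marker cutoffs resemble published log2-scale rule
#'   thresholds).
#' @param markerOverlap if `TRUE`, each class additionally shares one marker
#'   with the next class.
#' @param seed integer generator seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(classSizes, nGenes, markersPerClass = 5L,
                            effectSize = 3, baselineMean = 4, noiseSd = 1,
                            markerOverlap = FALSE, seed = 1L) {
  methods::new("SyntheticConfig", seed = as.integer(seed),
               classSizes = stats::setNames(as.integer(classSizes),
                                            names(classSizes)),
               nGenes = as.integer(nGenes),
               markersPerClass = as.integer(markersPerClass),
               effectSize = as.numeric(effectSize),
               baselineMean = as.numeric(baselineMean),
               noiseSd = as.numeric(noiseSd),
               markerOverlap = isTRUE(markerOverlap))
}

#' Default PDX-cohort configuration at a given scale
#'
#' At `scale = 1` the configuration reproduces the published cohort shape:
#' eight tissues with 79/41/121/99/52/94/46/62 samples (594 in total) and
#' 20,502 genes.  Smaller scales shrink class sizes proportionally (rounded,
#' minimum 5 per class) and the gene count proportionally (minimum 200).
#'
#' @param scale real in (0, 1].
#' @param ... further arguments passed to [syntheticConfig()].
#' @return a [SyntheticConfig-class].
#' @examples
#' defaultPdxConfig(0.1)@classSizes   # c(8, 5, 12, 10, 5, 9, 5, 6)
#' @export
defaultPdxConfig <- function(scale = 1, ...) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1)
    stopf("scale must be a single number in (0, 1]")
  sizes <- pmax(5L, as.integer(round(scale * PDX_CLASS_SIZES)))
  names(sizes) <- names(PDX_CLASS_SIZES)
  nGenes <- max(200L, as.integer(round(scale * PDX_N_GENES)))
  syntheticConfig(classSizes = sizes, nGenes = nGenes, ...)
}

#' @rdname pdxsite-generics
#' @export
setMethod("markerMap", "GroundTruth", function(x, ...) x@markerMap)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@markerMap), "classes,",
      length(unique(unlist(object@markerMap))), "distinct marker genes\n")
})

#' Generate a labeled synthetic dataset with known marker genes
#'
#' Background values are drawn i.i.d. Normal(`baselineMean`, `noiseSd`); a
#' marker gene of class c is shifted up by `effectSize` in samples of class c
#' only.  Marker genes are placed at seeded random positions among the N
#' genes so that ranking stages cannot exploit gene order.  Fully
#' reproducible from the config seed.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return a list with elements `dataset` ([LabeledDataset-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
generateDataset <- function(cfg) {
  stopifnot(is(cfg, "SyntheticConfig"))
  methods::validObject(cfg)
  classes <- names(cfg@classSizes)
  n <- sum(cfg@classSizes)
  N <- cfg@nGenes
  genes <- sprintf("G%05d", seq_len(N))
  samples <- sprintf("S%04d", seq_len(n))
  labels <- factor(rep(classes, cfg@classSizes), levels = classes)

  nMark <- cfg@markersPerClass * length(classes)
  markerIdx <- withSeed(deriveSeed(cfg@seed, "markers"),
                        sample.int(N, min(nMark, N)))
  markerMap <- split(genes[markerIdx],
                     rep(classes, each = cfg@markersPerClass)[seq_along(markerIdx)])
  markerMap <- markerMap[classes[classes %in% names(markerMap)]]
  if (cfg@markerOverlap && length(classes) > 1) {
    for (i in seq_along(classes)) {
      nxt <- classes[i %% length(classes) + 1]
      markerMap[[classes[i]]] <- union(markerMap[[classes[i]]],
                                       markerMap[[nxt]][1])
    }
  }

  vals <- withSeed(deriveSeed(cfg@seed, "background"),
                   matrix(rnorm(N * n, cfg@baselineMean, cfg@noiseSd), N, n,
                          dimnames = list(genes, samples)))
  for (cl in names(markerMap)) {
    rows <- match(markerMap[[cl]], genes)
    cols <- which(labels == cl)
    vals[rows, cols] <- vals[rows, cols] + cfg@effectSize
  }
  ds <- labeledDataset(vals, stats::setNames(as.character(labels), samples))
  list(dataset = ds,
       truth = methods::new("GroundTruth", markerMap = markerMap,
                            config = cfg))
}
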