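## Shared fixtures, built in code.

## tiny two-class dataset where gene "sep" perfectly separates the classes
makeSeparableDs <- function(n1 = 10, n2 = 10, nNoise = 4, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  m <- matrix(rnorm(nNoise * n, 4, 1), nNoise, n)
  sep <- c(rnorm(n1, 2, 0.3), rnorm(n2, 8, 0.3))
  m <- rbind(sep = sep, m)
  rownames(m) <- c("sep", paste0("noise", seq_len(nNoise)))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  labeledDataset(m, rep(c("A", "B"), c(n1, n2)))
}

## small multi-class synthetic dataset with planted markers
makePlantedDs <- function(seed = 1, classes = 3, perClass = 15,
                          nGenes = 120, markers = 4, delta = 3) {
  sizes <- stats::setNames(rep(perClass, classes), LETTERS[seq_len(classes)])
  cfg <- syntheticConfig(classSizes = sizes, nGenes = nGenes,
                         markersPerClass = markers, effectSize = delta,
                         seed = seed)
  generateDataset(cfg)
}

## hand-built ensemble wrapper: trees given as lists of node vectors
handEnsemble <- function(trees, genes, u = 1, v = 1) {
  params <- mcfsParams(m = length(genes), t = length(trees), p = 1L,
                       u = u, v = v)
  methods::new("TreeEnsemble", trees = trees, params = params, genes = genes)
}

## one hand-built tree record
handTree <- function(feature, ig, n_node, wAcc, rootN) {
  list(feature = feature, threshold = rep(NA_real_, length(feature)),
       ig = ig, n_node = n_node,
       left = rep(NA_integer_, length(feature)),
       right = rep(NA_integer_, length(feature)),
       pred = rep(0L, length(feature)), wAcc = wAcc, rootN = rootN)
}

## independent brute-force RI oracle: walk every node of every tree
riOracle <- function(ens) {
  ri <- stats::setNames(numeric(length(ens@genes)), ens@genes)
  for (tr in ens@trees) {
    for (k in seq_along(tr$feature)) {
      g <- tr$feature[k]
      if (is.na(g)) next
      ri[g] <- ri[g] + tr$wAcc^ens@params@u * tr$ig[k] *
        (tr$n_node[k] / tr$rootN)^ens@params@v
    }
  }
  ri
}

## independent first-match rule application oracle
applyRulesOracle <- function(rs, values) {
  for (r in rs@rules) {
    fired <- TRUE
    cd <- r@conditions
    for (k in seq_len(nrow(cd))) {
      v <- values[[cd$gene[k]]]
      ok <- if (cd$op[k] == ">=") v >= cd$threshold[k] else v <= cd$threshold[k]
      if (!ok) { fired <- FALSE; break }
    }
    if (fired) return(r@consequent)
  }
  stop("no rule fired")
}

## baseline sample values that fail every condition rule of the published
## set: genes used with '>=' sit far below their cutoffs, '<=' far above
table2Baseline <- function(rs) {
  vals <- numeric(0)
  for (r in rs@rules) {
    cd <- r@conditions
    for (k in seq_len(nrow(cd))) {
      vals[cd$gene[k]] <-
        if (cd$op[k] == ">=") cd$threshold[k] - 5 else cd$threshold[k] + 5
    }
  }
  vals
}

## classical binary MCC from a 2x2 confusion (rows truth, cols predicted)
binaryMCC <- function(cm) {
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
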