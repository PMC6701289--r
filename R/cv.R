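#' One-vs-rest SVM configuration
#'
#' @param kernel `"rbf"` (Gaussian, the default) or `"linear"`.
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF width; `"auto"` (default) uses
#'   `1 / (d * mean feature variance)` computed on the standardized training
#'   fold, or supply a positive number.
#' @param probabilityMethod `"platt"`: a sigmoid fit on training decision
#'   values maps scores to probabilities; the class with the highest
#'   probability wins, ties broken by class order.
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(kernel = "rbf", cost = 1, gamma = "auto",
                             probabilityMethod = "platt") {
  g <- if (identical(gamma, "auto")) NA_real_ else as.numeric(gamma)
  methods::new("ClassifierConfig", kernel = kernel, cost = as.numeric(cost),
               gamma = g, probabilityMethod = probabilityMethod)
}

#' Cross-validation configuration
#'
#' @param folds number of folds (default 10).
#' @param repeats repetitions; pooled by summing confusion matrices.
#' @param stratified stratified fold assignment (default TRUE; the cohort's
#'   class imbalance makes unstratified folds unstable).
#' @param seed integer seed for fold draws.
#' @return a [CVConfig-class].
#' @export
cvConfig <- function(folds = 10L, repeats = 1L, stratified = TRUE,
                     seed = 1L) {
  methods::new("CVConfig", folds = as.integer(folds),
               repeats = as.integer(repeats), stratified = stratified,
               seed = as.integer(seed))
}

## Platt sigmoid fit (Newton with backtracking, regularized targets) mapping
## decision values f to P(y = +1) = 1 / (1 + exp(A f + B)).
plattFit <- function(f, pos) {
  prior1 <- sum(pos); prior0 <- length(pos) - prior1
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  tt <- ifelse(pos, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, tt * z + log1p(exp(-z)), (tt - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    d1 <- tt - p
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nA <- A + step * dA; nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) { A <- nA; B <- nB; fv <- nf; break }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

## One-vs-rest prediction for one fold, given the full-kernel matrix.
ovrPredictFold <- function(K, train, test, y, clf) {
  classes <- levels(y)
  probs <- matrix(0, length(test), length(classes))
  Ktr <- K[train, train, drop = FALSE]
  Kte <- K[test, train, drop = FALSE]
  for (ci in seq_along(classes)) {
    yb <- ifelse(y[train] == classes[ci], 1L, -1L)
    if (all(yb == yb[1])) { probs[, ci] <- (yb[1] + 1) / 2; next }
    fit <- .smo_train_cpp(Ktr, yb, clf@cost, 1e-3, 100000L)
    ftr <- drop(Ktr %*% fit$coef) - fit$rho
    fte <- drop(Kte %*% fit$coef) - fit$rho
    ab <- plattFit(ftr, yb == 1L)
    probs[, ci] <- 1 / (1 + exp(ab[["A"]] * fte + ab[["B"]]))
  }
  factor(classes[max.col(probs, ties.method = "first")], levels = classes)
}

## Cross-validated one-vs-rest SVM over cumulative feature blocks.
##
## `blocks` is a list of column-index vectors; after each block is appended,
## the cumulative feature set is evaluated, so an IFS curve reuses the
## standardized squared-distance (or inner-product) matrices incrementally
## instead of recomputing kernels per prefix.  Returns one PerformanceReport
## per block.
cvEngine <- function(X, y, clf, cv, blocks) {
  n <- nrow(X)
  classes <- levels(y)
  minClass <- min(table(y))
  if (minClass < 2) stopf("every class needs at least 2 samples")
  k <- cv@folds
  if (minClass < k) {
    k <- as.integer(max(2L, minClass))
    warnf("reducing folds from %d to %d (smallest class has %d samples)",
          cv@folds, k, minClass)
  }
  states <- list()
  for (r in seq_len(cv@repeats)) {
    fold <- withSeed(deriveSeed(cv@seed, paste0("rep", r)),
                     if (cv@stratified) stratifiedFoldIds(y, k)
                     else sample(rep_len(seq_len(k), n)))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      states[[length(states) + 1L]] <- new.env(parent = emptyenv())
      st <- states[[length(states)]]
      st$train <- train; st$test <- test
      st$B <- matrix(0, n, n)
      st$nzv <- 0L; st$d <- 0L
    }
  }
  reports <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    cols <- blocks[[b]]
    conf <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
    for (st in states) {
      if (length(cols)) {
        Xb <- X[, cols, drop = FALSE]
        Xtr <- Xb[st$train, , drop = FALSE]
        mu <- colMeans(Xtr)
        s <- sqrt(colSums(sweep(Xtr, 2, mu)^2) / max(1L, nrow(Xtr) - 1L))
        nz <- s > 0
        s[!nz] <- 1
        Zb <- sweep(sweep(Xb, 2, mu), 2, s, "/")
        st$B <- st$B + (if (clf@kernel == "rbf") as.matrix(dist(Zb))^2
                        else tcrossprod(Zb))
        st$nzv <- st$nzv + sum(nz)
        st$d <- st$d + length(cols)
      }
    }
    for (st in states) {
      K <- if (clf@kernel == "rbf") {
        g <- if (!is.na(clf@gamma)) clf@gamma
             else if (st$nzv > 0) 1 / st$nzv else 1 / max(1L, st$d)
        exp(-g * st$B)
      } else st$B
      pred <- ovrPredictFold(K, st$train, st$test, y, clf)
      conf <- conf + unclass(table(y[st$test], pred))
    }
    reports[[b]] <- performanceReport(conf)
  }
  reports
}

#' Cross-validated evaluation of a feature subset with a one-vs-rest SVM
#'
#' Stratified fold assignment is seeded from the CV config; per fold, one
#' binary SVM per class is trained on the standardized training-fold
#' features (z-scores fit on the training fold only) and applied to the
#' held-out fold; the class with the highest Platt probability wins.
#' Out-of-fold predictions over all folds and repeats are pooled into one
#' confusion matrix from which all metrics derive.
#'
#' @param ds a [LabeledDataset-class].
#' @param featureSubset gene identifiers or row indices (non-empty).
#' @param clf a [ClassifierConfig-class].
#' @param cv a [CVConfig-class].
#' @return a [PerformanceReport-class].
#' @export
cvEvaluate <- function(ds, featureSubset, clf = classifierConfig(),
                       cv = cvConfig()) {
  idx <- resolveFeatures(ds, featureSubset)
  X <- t(exprsMatrix(ds))
  cvEngine(X, classLabels(ds), clf, cv, list(idx))[[1]]
}

resolveFeatures <- function(ds, featureSubset) {
  if (!length(featureSubset)) stopf("feature subset must be non-empty")
  if (is.character(featureSubset)) {
    idx <- match(featureSubset, rownames(ds))
    if (anyNA(idx))
      stopf("unknown genes: %s",
            paste(featureSubset[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(featureSubset)
    if (any(idx < 1 | idx > nrow(ds))) stopf("feature index out of range")
    idx
  }
}
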