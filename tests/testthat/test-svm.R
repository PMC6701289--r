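test_that("the SMO dual solver reproduces libsvm decision values", {
  library(e1071)
  set.seed(41)
  for (rep in 1:10) {
    n <- 25 + 2 * rep; d <- 4
    X <- matrix(rnorm(n * d), n, d)
    y <- ifelse(X[, 1] + rnorm(n, 0, 0.8) > 0, 1L, -1L)
    if (length(unique(y)) < 2) next
    g <- 1 / d
    K <- exp(-g * as.matrix(dist(X))^2)
    fit <- pdxsite:::.smo_train_cpp(K, y, 1.0, 1e-4, 100000L)
    f1 <- drop(K %*% fit$coef) - fit$rho
    em <- svm(x = X, y = factor(y, levels = c(1, -1)), kernel = "radial",
              gamma = g, cost = 1, scale = FALSE)
    dv <- attr(predict(em, X, decision.values = TRUE), "decision.values")
    f2 <- drop(dv)
    if (colnames(dv)[1] == "-1/1") f2 <- -f2
    expect_gt(cor(f1, f2), 0.9999)
    expect_lt(max(abs(f1 - f2)), 0.05)
    expect_equal(sign(f1), sign(f2))
  }
})

test_that("cross-validated evaluation is bit-reproducible given its seed", {
  gen <- makePlantedDs(seed = 8)
  mk <- unlist(markerMap(gen$truth))
  r1 <- cvEvaluate(gen$dataset, mk, cv = cvConfig(folds = 5L, seed = 9))
  r2 <- cvEvaluate(gen$dataset, mk, cv = cvConfig(folds = 5L, seed = 9))
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  ## different seeds assign different folds
  y <- classLabels(gen$dataset)
  f1 <- pdxsite:::withSeed(deriveSeed(9L, "rep1"),
                           pdxsite:::stratifiedFoldIds(y, 5L))
  f2 <- pdxsite:::withSeed(deriveSeed(10L, "rep1"),
                           pdxsite:::stratifiedFoldIds(y, 5L))
  expect_false(identical(f1, f2))
  expect_true(all(table(f1, y) <= ceiling(table(y)[1] / 5)))
})

test_that("planted markers classify nearly perfectly; noise does not", {
  gen <- makePlantedDs(seed = 12, classes = 3, perClass = 30, nGenes = 150,
                       markers = 4, delta = 4)
  mk <- unlist(markerMap(gen$truth))
  rep <- cvEvaluate(gen$dataset, mk, cv = cvConfig(seed = 1))
  expect_gte(mcc(rep), 0.95)
  noise <- setdiff(rownames(gen$dataset), mk)[1:10]
  nulls <- vapply(1:8, function(s)
    mcc(cvEvaluate(gen$dataset, noise, cv = cvConfig(seed = s))), numeric(1))
  expect_lt(mean(abs(nulls)), 0.15)
})

test_that("repeats sum confusion counts to repeats * n", {
  gen <- makePlantedDs(seed = 13, classes = 3, perClass = 10, nGenes = 60)
  mk <- unlist(markerMap(gen$truth))
  rep3 <- cvEvaluate(gen$dataset, mk,
                     cv = cvConfig(folds = 5L, repeats = 3L, seed = 2))
  expect_equal(sum(confusionMatrix(rep3)), 3L * ncol(gen$dataset))
})

test_that("folds are reduced with a warning when a class is small", {
  gen <- makePlantedDs(seed = 14, classes = 3, perClass = 4, nGenes = 40)
  mk <- unlist(markerMap(gen$truth))
  expect_warning(cvEvaluate(gen$dataset, mk, cv = cvConfig(folds = 10L)),
                 "reducing folds")
})

test_that("a duplicated collinear feature neither errors nor shifts MCC much", {
  gen <- makePlantedDs(seed = 15, classes = 3, perClass = 20, nGenes = 80)
  mk <- unlist(markerMap(gen$truth))
  base <- mcc(cvEvaluate(gen$dataset, mk, cv = cvConfig(seed = 3)))
  dup <- mcc(cvEvaluate(gen$dataset, c(mk, mk[1]), cv = cvConfig(seed = 3)))
  expect_lt(abs(base - dup), 0.1)
})

test_that("empty subsets and unknown genes are rejected", {
  gen <- makePlantedDs(seed = 16)
  expect_error(cvEvaluate(gen$dataset, character(0)), "non-empty")
  expect_error(cvEvaluate(gen$dataset, "NOPE"), "NOPE")
})
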