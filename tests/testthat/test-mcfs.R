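test_that("weighted accuracy is the mean of per-class recalls", {
  expect_equal(weightedAccuracy(diag(c(5, 3))), 1.0)
  expect_equal(weightedAccuracy(matrix(c(5, 3, 0, 0), 2)), 0.5)
  cm <- matrix(c(8, 1, 0, 2, 9, 0, 0, 0, 5), 3)   # recalls .8, .9, 1
  expect_equal(weightedAccuracy(cm), 0.9)
  ## absent class (zero row) is excluded from the average
  cm0 <- rbind(cm, c(0, 0, 0)); cm0 <- cbind(cm0, c(0, 0, 0, 0))
  expect_equal(weightedAccuracy(cm0), 0.9)
  expect_error(weightedAccuracy(matrix(0, 2, 2)), "all-zero")
})

test_that("the ensemble holds exactly p * t trees restricted to m genes", {
  gen <- makePlantedDs(seed = 2)
  ens1 <- growProjectionTrees(gen$dataset,
                              mcfsParams(m = 10L, t = 1L, p = 1L, seed = 1))
  expect_length(ens1@trees, 1L)
  ens <- growProjectionTrees(gen$dataset,
                             mcfsParams(m = 10L, t = 3L, p = 5L, seed = 1))
  expect_length(ens@trees, 15L)
  for (tr in ens@trees) {
    used <- tr$feature[!is.na(tr$feature)]
    expect_lte(length(unique(used)), 10L)
    expect_true(all(tr$ig[!is.na(tr$feature)] >= 0))
    expect_gte(tr$wAcc, 0); expect_lte(tr$wAcc, 1)
  }
})

test_that("a perfectly separating gene takes the root and yields wAcc 1", {
  ds <- makeSeparableDs()
  ens <- growProjectionTrees(ds, mcfsParams(m = 5L, t = 1L, p = 1L,
                                            seed = 4))
  tr <- ens@trees[[1]]
  expect_equal(rownames(ds)[tr$feature[1]], "sep")
  expect_equal(tr$wAcc, 1.0)
})

test_that("relative importance follows the per-node sum exactly", {
  ## single tree, wAcc 1, one root split with IG 1 and fraction 1
  t1 <- handTree(feature = c(1L, NA, NA), ig = c(1, 0, 0),
                 n_node = c(10L, 5L, 5L), wAcc = 1, rootN = 10L)
  ens <- handEnsemble(list(t1), genes = c("g1", "g2"))
  ri <- computeRelativeImportance(ens)
  expect_equal(unname(ri["g1"]), 1.0)
  expect_equal(unname(ri["g2"]), 0)   # never a splitter

  ## two-tree worked case: 0.8*0.9*1 + 0.8*0.5*0.4 + 0.5*1.0*1 = 1.38
  tA <- handTree(feature = c(1L, 1L, NA, NA), ig = c(0.9, 0.5, 0, 0),
                 n_node = c(10L, 4L, 2L, 2L), wAcc = 0.8, rootN = 10L)
  tB <- handTree(feature = c(1L, NA, NA), ig = c(1.0, 0, 0),
                 n_node = c(8L, 4L, 4L), wAcc = 0.5, rootN = 8L)
  ens2 <- handEnsemble(list(tA, tB), genes = c("g1", "g2"))
  expect_equal(unname(computeRelativeImportance(ens2)["g1"]), 1.38)
})

test_that("RI matches a brute-force node-traversal oracle on hand ensembles", {
  set.seed(31)
  for (rep in 1:10) {
    nGenes <- 6
    trees <- lapply(seq_len(sample(2:5, 1)), function(i) {
      k <- sample(2:6, 1)
      rootN <- sample(8:20, 1)
      handTree(feature = sample(c(seq_len(nGenes), NA), k, replace = TRUE),
               ig = round(runif(k), 3),
               n_node = sample.int(rootN, k, replace = TRUE),
               wAcc = round(runif(1), 2), rootN = rootN)
    })
    ens <- handEnsemble(trees, genes = paste0("g", seq_len(nGenes)),
                        u = sample(c(0.5, 1, 2), 1),
                        v = sample(c(0.5, 1, 2), 1))
    expect_equal(computeRelativeImportance(ens), riOracle(ens),
                 tolerance = 1e-14)
  }
})

test_that("permuting gene order permutes RI scores identically", {
  t1 <- handTree(feature = c(2L, 3L, NA), ig = c(0.7, 0.2, 0),
                 n_node = c(12L, 6L, 6L), wAcc = 0.9, rootN = 12L)
  genes <- c("g1", "g2", "g3")
  ens <- handEnsemble(list(t1), genes)
  perm <- c(3L, 1L, 2L)          # position i holds old gene perm[i]
  t1p <- t1; t1p$feature <- match(t1$feature, perm)
  ensP <- handEnsemble(list(t1p), genes[perm])
  expect_equal(unname(computeRelativeImportance(ensP)),
               unname(computeRelativeImportance(ens)[perm]))
})

test_that("scaling u or v rescales RI but never changes which genes are 0", {
  set.seed(32)
  gen <- makePlantedDs(seed = 7, nGenes = 60)
  ens <- growProjectionTrees(gen$dataset,
                             mcfsParams(m = 15L, t = 10L, p = 2L, seed = 7))
  ri1 <- computeRelativeImportance(ens)
  ens@params@u <- 2; ens@params@v <- 0.5
  ri2 <- computeRelativeImportance(ens)
  expect_identical(ri1 == 0, ri2 == 0)
  expect_true(all(ri1 >= 0) && all(ri2 >= 0))
})

test_that("ranking sorts descending with ties broken by gene index", {
  r <- rankFeatures(c(g1 = 0.5, g2 = 0.9, g3 = 0.5))
  expect_equal(rankedGenes(r), c("g2", "g1", "g3"))
  r0 <- rankFeatures(c(a = 0, b = 0, c = 0))
  expect_equal(rankedGenes(r0), c("a", "b", "c"))
  set.seed(33)
  x <- stats::setNames(round(runif(50), 2), paste0("g", 1:50))
  r2 <- rankFeatures(x)
  oracle <- names(x)[order(-x, seq_along(x))]
  expect_equal(rankedGenes(r2), oracle)
  expect_identical(sort(r2@ranking), seq_len(50L))
})

test_that("ensembles and rankings are reproducible from their seed", {
  gen <- makePlantedDs(seed = 3, nGenes = 80)
  p <- mcfsParams(m = 20L, t = 8L, p = 2L, seed = 42)
  r1 <- mcfsRank(gen$dataset, p)
  r2 <- mcfsRank(gen$dataset, p)
  expect_identical(r1$ri, r2$ri)
  p2 <- p; p2@seed <- 43L
  expect_false(identical(mcfsRank(gen$dataset, p2)$ri, r1$ri))
})

test_that("the permutation threshold shrinks the informative set as alpha falls", {
  gen <- makePlantedDs(seed = 5, classes = 3, perClass = 10, nGenes = 60,
                       markers = 3)
  p <- mcfsParams(m = 15L, t = 15L, p = 2L, seed = 5)
  ri <- computeRelativeImportance(growProjectionTrees(gen$dataset, p))
  th10 <- permutationThreshold(gen$dataset, p, 5L, alpha = 0.10, ri = ri)
  th01 <- permutationThreshold(gen$dataset, p, 5L, alpha = 0.01, ri = ri)
  expect_gt(th01$threshold@threshold, th10$threshold@threshold)
  expect_lte(length(th01$informative), length(th10$informative))
  expect_length(th10$threshold@permutationMaxRIs, 5L)
  expect_error(permutationThreshold(gen$dataset, p, 2L), "3 permutations")
})
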