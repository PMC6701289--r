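test_that("a stage evaluates the expected prefix grid", {
  gen <- makePlantedDs(seed = 18, nGenes = 60)
  rk <- mcfsRank(gen$dataset, mcfsParams(m = 15L, t = 10L, p = 2L, seed = 1))
  cv <- cvConfig(folds = 5L, seed = 2)
  curve <- ifsStage(gen$dataset, rk$ranking, 10, 50, 10, cv = cv)
  expect_s4_class(curve, "IFSCurve")
  expect_equal(curve@sizes, seq(10L, 50L, 10L))
  df <- as.data.frame(curve)
  expect_equal(nrow(df), 5L)
  expect_true(all(c("n_features", "ACC", "MCC") %in% colnames(df)))
})

test_that("a single-point stage equals a direct evaluation of the prefix", {
  gen <- makePlantedDs(seed = 19, nGenes = 50)
  rk <- mcfsRank(gen$dataset, mcfsParams(m = 12L, t = 8L, p = 2L, seed = 1))
  cv <- cvConfig(folds = 5L, seed = 7)
  k <- 12L
  single <- ifsStage(gen$dataset, rk$ranking, k, k, 1L, cv = cv)
  direct <- cvEvaluate(gen$dataset, rankedGenes(rk$ranking)[1:k], cv = cv)
  expect_identical(confusionMatrix(single@reports[[1]]),
                   confusionMatrix(direct))
})

test_that("stage-2 never falls below stage-1 and clips to the gene count", {
  gen <- makePlantedDs(seed = 20, nGenes = 60)
  rk <- mcfsRank(gen$dataset, mcfsParams(m = 15L, t = 10L, p = 2L, seed = 1))
  cv <- cvConfig(folds = 5L, seed = 3)
  res <- twoStageIFS(gen$dataset, rk$ranking, coarseStep = 10L,
                     intervalHalfwidthSteps = 2L, cv = cv)
  best1 <- max(vapply(res$stage1@reports, mcc, numeric(1)))
  expect_gte(mcc(res$optimal@report), best1)
  expect_lte(res$optimal@size, nrow(gen$dataset))
  expect_equal(res$optimal@genes,
               rankedGenes(rk$ranking)[seq_len(res$optimal@size)])
})

test_that("a dataset smaller than one coarse step degenerates gracefully", {
  set.seed(44)
  m <- matrix(rnorm(8 * 20, 4, 1), 8, 20,
              dimnames = list(paste0("G", 1:8), paste0("s", 1:20)))
  m[1, 1:10] <- m[1, 1:10] + 4
  ds <- labeledDataset(m, rep(c("A", "B"), each = 10))
  rk <- rankFeatures(stats::setNames(8:1, rownames(m)))
  res <- twoStageIFS(ds, rk, coarseStep = 10L,
                     cv = cvConfig(folds = 5L, seed = 1))
  expect_equal(res$stage1@sizes, 8L)            # single full set
  expect_equal(res$stage2@sizes, 1:8)           # scan of [1, N]
})

test_that("MCC rises with markers then plateaus on planted data", {
  gen <- makePlantedDs(seed = 21, classes = 3, perClass = 20, nGenes = 100,
                       markers = 5)
  mk <- unlist(markerMap(gen$truth))
  ## construct an oracle ranking: markers first, then noise
  ri <- stats::setNames(rep(0, 100), rownames(gen$dataset))
  ri[mk] <- seq(2, 1, length.out = length(mk))
  rk <- rankFeatures(ri)
  curve <- ifsStage(gen$dataset, rk, 5, 30, 5,
                    cv = cvConfig(folds = 5L, seed = 5))
  mccs <- vapply(curve@reports, mcc, numeric(1))
  expect_gte(mccs[3] + 0.05, mccs[1])           # rising portion
  expect_gte(min(mccs[4:6]), max(mccs) - 0.05)  # plateau after all markers
})

test_that("extreme observed MCCs map to the boundary p-values", {
  gen <- makePlantedDs(seed = 22, classes = 3, perClass = 8, nGenes = 40,
                       delta = 0)
  rc <- randomSubsetSignificance(gen$dataset, 5, nSubsets = 12L,
                                 cv = cvConfig(folds = 4L, seed = 1),
                                 observedMcc = 1.0, seed = 2)
  expect_equal(rc$p, 1 / 13)
  rc2 <- randomSubsetSignificance(gen$dataset, 5, nSubsets = 12L,
                                  cv = cvConfig(folds = 4L, seed = 1),
                                  observedMcc = -2, seed = 2)
  expect_equal(rc2$p, 1.0)
  expect_length(rc$mccs, 12L)
  expect_identical(rc$mccs, rc2$mccs)
})
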