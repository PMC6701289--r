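test_that("default PDX config reproduces the cohort shape at scale 1", {
  cfg <- defaultPdxConfig(1)
  expect_equal(sum(cfg@classSizes), 594L)
  expect_equal(cfg@nGenes, 20502L)
  expect_equal(length(cfg@classSizes), 8L)
  expect_equal(unname(cfg@classSizes[c("breast", "kidney")]), c(79L, 41L))
})

test_that("scaling rounds proportionally with a floor of 5 per class", {
  cfg <- defaultPdxConfig(0.1)
  expect_equal(unname(cfg@classSizes), c(8L, 5L, 12L, 10L, 5L, 9L, 5L, 6L))
  expect_equal(cfg@nGenes, 2050L)
  tiny <- defaultPdxConfig(0.01)
  expect_true(all(tiny@classSizes == 5L))
  expect_equal(sum(tiny@classSizes), 40L)
  expect_equal(tiny@nGenes, 205L)
  expect_error(defaultPdxConfig(0), "scale")
  expect_error(defaultPdxConfig(1.5), "scale")
})

test_that("generation is reproducible from the seed and seeds differ", {
  cfg <- syntheticConfig(c(A = 6, B = 6), nGenes = 50, seed = 3)
  g1 <- generateDataset(cfg)
  g2 <- generateDataset(cfg)
  expect_identical(exprsMatrix(g1$dataset), exprsMatrix(g2$dataset))
  expect_identical(markerMap(g1$truth), markerMap(g2$truth))
  cfg2 <- cfg; cfg2@seed <- 4L
  g3 <- generateDataset(cfg2)
  expect_false(identical(exprsMatrix(g1$dataset), exprsMatrix(g3$dataset)))
})

test_that("marker genes shift by the effect size in their own class", {
  sizes <- stats::setNames(rep(50L, 3), c("A", "B", "C"))
  gen <- generateDataset(syntheticConfig(sizes, nGenes = 200,
                                         markersPerClass = 5L,
                                         effectSize = 3, seed = 5))
  ds <- gen$dataset; y <- classLabels(ds)
  for (cl in names(markerMap(gen$truth))) {
    for (g in markerMap(gen$truth)[[cl]]) {
      v <- exprsMatrix(ds)[g, ]
      shift <- mean(v[y == cl]) - mean(v[y != cl])
      expect_gt(shift, 2.5); expect_lt(shift, 3.5)
    }
  }
})

test_that("with zero effect no gene carries class signal beyond chance", {
  sizes <- stats::setNames(rep(25L, 2), c("A", "B"))
  gen <- generateDataset(syntheticConfig(sizes, nGenes = 400,
                                         markersPerClass = 5L,
                                         effectSize = 0, seed = 6))
  ds <- gen$dataset; y <- classLabels(ds)
  pvals <- apply(exprsMatrix(ds), 1, function(v)
    stats::t.test(v[y == "A"], v[y == "B"])$p.value)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.12)   # nominal 5% rejection
})

test_that("planted cohort with published class sizes totals 594 samples", {
  cfg <- syntheticConfig(defaultPdxConfig(1)@classSizes, nGenes = 250,
                         seed = 2)
  gen <- generateDataset(cfg)
  expect_equal(ncol(gen$dataset), 594L)
  expect_equal(nlevels(classLabels(gen$dataset)), 8L)
  expect_true(all(unlist(markerMap(gen$truth)) %in% rownames(gen$dataset)))
})

test_that("markers are disjoint across classes by default, shared on demand", {
  sizes <- stats::setNames(rep(6L, 3), c("A", "B", "C"))
  g1 <- generateDataset(syntheticConfig(sizes, 100, markersPerClass = 4L,
                                        seed = 9))
  mm <- markerMap(g1$truth)
  expect_equal(anyDuplicated(unlist(mm)), 0L)
  g2 <- generateDataset(syntheticConfig(sizes, 100, markersPerClass = 4L,
                                        markerOverlap = TRUE, seed = 9))
  mm2 <- markerMap(g2$truth)
  expect_gt(length(unlist(mm2)), length(unique(unlist(mm2))))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(c(A = 3, B = 3), nGenes = 5,
                               markersPerClass = 4L), "disjoint")
  expect_error(syntheticConfig(c(A = 0, B = 3), nGenes = 50), ">= 1")
  expect_error(syntheticConfig(c(A = 3, B = 3), nGenes = 50, noiseSd = 0),
               "noiseSd")
})
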