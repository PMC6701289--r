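test_that("the published 16-rule set loads exactly as printed", {
  rs <- loadTable2Rules()
  expect_s4_class(rs, "RuleSet")
  expect_length(rs, 16L)
  r1 <- rs@rules[[1]]
  expect_equal(r1@conditions$gene, c("ANGPTL4", "BHMT2"))
  expect_equal(r1@conditions$op, c(">=", ">="))
  expect_equal(r1@conditions$threshold, c(6.409, 4.826))
  expect_equal(r1@consequent, "Kidney")
  r14 <- rs@rules[[14]]
  expect_equal(nrow(r14@conditions), 3L)
  expect_equal(r14@conditions$gene, c("MSN", "PDGFC", "BCL2L15"))
  expect_equal(r14@conditions$threshold, c(5.037, 1.903, 5.317))
  expect_equal(r14@conditions$op, c(">=", ">=", "<="))
  expect_equal(r14@consequent, "Lung")
  expect_equal(nrow(rs@rules[[16]]@conditions), 0L)
  expect_equal(defaultClass(rs), "Large intestine")
  expect_length(ruleGenes(rs), 27L)
  expect_true(all(c("LOC102724689", "TP73-AS1") %in% ruleGenes(rs)))
})

test_that("application fires the first matching rule, inclusively", {
  rs <- loadTable2Rules()
  base <- table2Baseline(rs)
  s1 <- base; s1["ANGPTL4"] <- 6.5; s1["BHMT2"] <- 4.9
  expect_equal(applyRules(rs, s1), "Kidney")
  s2 <- base; s2["UPK1A"] <- 6.474          # boundary is inclusive
  expect_equal(applyRules(rs, s2), "Kidney")
  expect_equal(applyRules(rs, base), "Large intestine")
  ## order sensitivity: satisfy rule 1 (Kidney) and rule 11 (Pancreas)
  s3 <- base
  s3["ANGPTL4"] <- 7; s3["BHMT2"] <- 5
  s3["ADAM28"] <- 4; s3["BTBD6"] <- 7
  expect_equal(applyRules(rs, s3), "Kidney")
})

test_that("a sample missing a referenced gene is an error naming it", {
  rs <- loadTable2Rules()
  base <- table2Baseline(rs)
  expect_error(applyRules(rs, base[setdiff(names(base), "MIA")]), "MIA")
})

test_that("application matches a brute-force first-match oracle", {
  set.seed(61)
  genes <- paste0("g", 1:6)
  for (rep in 1:200) {
    nRules <- sample(1:5, 1)
    rules <- lapply(seq_len(nRules), function(i) {
      k <- sample(1:3, 1)
      rule(data.frame(gene = sample(genes, k),
                      op = sample(c(">=", "<="), k, replace = TRUE),
                      threshold = round(rnorm(k, 5, 2), 2)),
           sample(LETTERS[1:4], 1))
    })
    rs <- ruleSet(c(rules, list(rule(NULL, "Z"))))
    for (j in 1:5) {
      smp <- stats::setNames(rnorm(length(genes), 5, 2), genes)
      expect_identical(applyRules(rs, smp), applyRulesOracle(rs, smp))
    }
  }
})

test_that("serialization round-trips and enforces the default-rule position", {
  rs <- loadTable2Rules()
  txt <- serializeRules(rs)
  expect_identical(serializeRules(parseRules(txt)), txt)
  expect_error(parseRules(c("IF THEN X", "IF g >= 1 THEN Y")),
               "last line")
  uni <- parseRules(c("IF g ≥ 1.5 AND h ≤ 2 THEN A", "IF THEN B"))
  expect_equal(uni@rules[[1]]@conditions$op, c(">=", "<="))
  expect_match(serializeRules(uni), ">=", fixed = TRUE)
  expect_error(parseRules("IF g == 1 THEN A"), "condition")
  ## file round trip
  path <- withr::local_tempfile()
  writeRules(rs, path)
  expect_identical(serializeRules(readRules(path)), txt)
})

test_that("rule sets reject malformed structure", {
  r1 <- rule(data.frame(gene = "g", op = ">=", threshold = 1), "A")
  expect_error(ruleSet(list(r1)), "default")
  expect_error(ruleSet(list(rule(NULL, "A"), r1)), "default")
  expect_error(rule(data.frame(gene = "g", op = ">", threshold = 1), "A"),
               "operators")
})

test_that("self-consistency on samples built to fire each rule is perfect", {
  rs <- loadTable2Rules()
  base <- table2Baseline(rs)
  cols <- list()
  for (i in c(1, 3, 5, 8, 9, 11, 14, 16)) {  # one rule per tissue
    r <- rs@rules[[i]]
    v <- base
    cd <- r@conditions
    for (k in seq_len(nrow(cd)))
      v[cd$gene[k]] <- if (cd$op[k] == ">=") cd$threshold[k] + 1
                       else cd$threshold[k] - 1
    cols[[r@consequent]] <- v
  }
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("s%d", seq_along(cols))
  ds <- labeledDataset(m, stats::setNames(names(cols), colnames(m)))
  rep <- evaluateRuleSet(rs, ds, "self_consistency")
  expect_equal(overallAccuracy(rep), 1)
  expect_equal(mcc(rep), 1)
})

test_that("cross-validated rule evaluation pools repeats * n predictions", {
  gen <- makePlantedDs(seed = 62, classes = 3, perClass = 10, nGenes = 50,
                       markers = 3, delta = 4)
  mk <- unlist(markerMap(gen$truth))
  rs <- ripperInduce(gen$dataset, mk, seed = 1)
  cvRep <- suppressWarnings(
    evaluateRuleSet(rs, gen$dataset, "cv",
                    cv = cvConfig(folds = 5L, repeats = 3L, seed = 2),
                    candidateGenes = mk))
  expect_equal(sum(confusionMatrix(cvRep)), 3L * ncol(gen$dataset))
  fixed <- suppressWarnings(
    evaluateRuleSet(rs, gen$dataset, "cv",
                    cv = cvConfig(folds = 5L, repeats = 1L, seed = 2),
                    reinduce = FALSE))
  expect_equal(sum(confusionMatrix(fixed)), ncol(gen$dataset))
})
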