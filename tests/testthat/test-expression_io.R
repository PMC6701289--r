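test_that("a small TSV matrix with labels parses into a valid dataset", {
  mpath <- withr::local_tempfile(fileext = ".tsv")
  lpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3",
               "G1\t1.5\t2.5\t3.5",
               "G2\t0.1\t0.2\t0.3"), mpath)
  writeLines(c("s1\tA", "s2\tA", "s3\tB"), lpath)
  ds <- readLabeledDataset(mpath, lpath)
  expect_s4_class(ds, "LabeledDataset")
  expect_equal(dim(ds), c(2L, 3L))
  expect_equal(nlevels(classLabels(ds)), 2L)
  expect_equal(exprsMatrix(ds)["G2", "s2"], 0.2)
  expect_equal(as.character(classLabels(ds)), c("A", "A", "B"))
})

test_that("labels are realigned to matrix column order", {
  mpath <- withr::local_tempfile(); lpath <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2", "G1\t1\t2"), mpath)
  writeLines(c("s2\tB", "s1\tA"), lpath)   # reversed order
  ds <- readLabeledDataset(mpath, lpath)
  expect_equal(as.character(classLabels(ds)), c("A", "B"))
})

test_that("write -> read round trip preserves the dataset to 1e-9", {
  set.seed(11)
  m <- matrix(rnorm(30, 4, 2), 5, 6,
              dimnames = list(paste0("G", 1:5), paste0("s", 1:6)))
  ds <- labeledDataset(m, rep(c("kidney", "lung", "skin"), each = 2))
  mpath <- withr::local_tempfile(); lpath <- withr::local_tempfile()
  writeLabeledDataset(ds, mpath, lpath)
  ds2 <- readLabeledDataset(mpath, lpath)
  expect_equal(rownames(ds2), rownames(ds))
  expect_equal(colnames(ds2), colnames(ds))
  expect_lt(max(abs(exprsMatrix(ds2) - exprsMatrix(ds))), 1e-9)
  expect_equal(as.character(classLabels(ds2)), as.character(classLabels(ds)))
})

test_that("sample/label mismatches are reported by name", {
  mpath <- withr::local_tempfile(); lpath <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts4", "G1\t1\t2"), mpath)
  writeLines(c("s1\tA"), lpath)
  expect_error(readLabeledDataset(mpath, lpath), "s4")
  writeLines(c("s1\tA", "s4\tA", "s9\tB"), lpath)
  expect_error(readLabeledDataset(mpath, lpath), "s9")
})

test_that("ragged rows and non-numeric cells are format errors", {
  mpath <- withr::local_tempfile(); lpath <- withr::local_tempfile()
  writeLines(c("s1\tA", "s2\tA"), lpath)
  writeLines(c("gene\ts1\ts2", "G1\t1"), mpath)
  expect_error(readLabeledDataset(mpath, lpath), "ragged")
  writeLines(c("gene\ts1\ts2", "G1\t1\tfoo"), mpath)
  expect_error(readLabeledDataset(mpath, lpath), "G1.*s2")
})

test_that("degenerate datasets are refused on write; 1x1 writes 2 lines", {
  m <- matrix(1.25, 1, 1, dimnames = list("G1", "s1"))
  ds <- labeledDataset(m, "A")
  mpath <- withr::local_tempfile(); lpath <- withr::local_tempfile()
  writeLabeledDataset(ds, mpath, lpath)
  expect_length(readLines(mpath), 2L)
  expect_error(labeledDataset(m[, 0, drop = FALSE], character(0)))
})

test_that("comma delimiter is auto-detected and GEO metadata lines skipped", {
  mpath <- withr::local_tempfile(); lpath <- withr::local_tempfile()
  writeLines(c("!Series_title,x", "gene,s1,s2", "!weird,1,2",
               "G1,1.5,2.5"), mpath)
  writeLines(c("s1\tA", "s2\tB"), lpath)
  ds <- readLabeledDataset(mpath, lpath, geoSeriesMatrix = TRUE)
  expect_equal(unname(exprsMatrix(ds)[1, ]), c(1.5, 2.5))
})

test_that("missing values are rejected, not imputed", {
  m <- matrix(c(1, NA), 1, 2, dimnames = list("G1", c("s1", "s2")))
  expect_error(labeledDataset(m, c("A", "B")), "finite")
})
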