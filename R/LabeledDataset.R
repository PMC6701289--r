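#' Construct a LabeledDataset
#'
#' @param exprs numeric genes x samples matrix with unique non-empty rownames
#'   (gene symbols) and colnames (sample ids); values are continuous
#'   log-scale expression intensities.
#' @param labels character or factor of tissue labels, one per sample, in
#'   matrix column order (or named by sample id, in which case they are
#'   realigned).
#' @return a [LabeledDataset-class].
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' labeledDataset(m, c("kidney", "kidney", "lung"))
#' @export
labeledDataset <- function(exprs, labels) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stopf("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stopf("'exprs' must have gene rownames and sample colnames")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(exprs), names(labels))
    if (length(missing))
      stopf("samples missing from labels: %s", paste(missing, collapse = ", "))
    labels <- labels[colnames(exprs)]
  }
  if (length(labels) != ncol(exprs))
    stopf("need one label per sample (%d labels for %d samples)",
          length(labels), ncol(exprs))
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(as.character(labels)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(class = labels,
                                   row.names = colnames(exprs)))
  methods::new("LabeledDataset", se)
}

#' @rdname pdxsite-generics
#' @export
setMethod("classLabels", "LabeledDataset", function(x, ...)
  SummarizedExperiment::colData(x)$class)

#' @rdname pdxsite-generics
#' @export
setMethod("classLevels", "LabeledDataset", function(x, ...)
  levels(classLabels(x)))

#' @rdname pdxsite-generics
#' @export
setMethod("exprsMatrix", "LabeledDataset", function(x, ...)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname pdxsite-generics
#' @export
setMethod("geneIds", "LabeledDataset", function(x, ...) rownames(x))

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset:", nrow(object), "genes x", ncol(object), "samples\n")
  tab <- table(classLabels(object))
  cat(" classes (", length(tab), "): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
})

## ---- delimited-text I/O ----------------------------------------------------

detectDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a labeled expression dataset from delimited text
#'
#' The matrix file is genes-in-rows, samples-in-columns, with a header row of
#' sample ids and gene symbols in the first column (the GEO series-matrix
#' orientation).  The labels file has two columns, sample id and class, with
#' or without a header.
#'
#' @param matrixPath path to the expression matrix file.
#' @param labelsPath path to the sample-to-class label file.
#' @param delim field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @param transpose set `TRUE` when the matrix file is samples-in-rows.
#' @param geoSeriesMatrix set `TRUE` to skip GEO series-matrix metadata lines
#'   (those beginning with `!`) in the matrix file.
#' @return a [LabeledDataset-class]; label order is realigned to the matrix
#'   column order.
#' @seealso [writeLabeledDataset()]
#' @export
readLabeledDataset <- function(matrixPath, labelsPath, delim = NULL,
                               transpose = FALSE, geoSeriesMatrix = FALSE) {
  if (is.null(delim)) delim <- detectDelim(matrixPath)
  lines <- readLines(matrixPath)
  if (geoSeriesMatrix) lines <- lines[!startsWith(lines, "!")]
  if (!length(lines)) stopf("empty matrix file: %s", matrixPath)
  cells <- strsplit(lines, delim, fixed = TRUE)
  width <- lengths(cells)
  if (length(unique(width)) != 1)
    stopf("ragged matrix file %s: rows have %s fields", matrixPath,
          paste(unique(width), collapse = "/"))
  header <- cells[[1]]
  samples <- header[-1]
  body <- cells[-1]
  genes <- vapply(body, `[`, character(1), 1L)
  vals <- matrix(NA_real_, length(body), length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(v))
    if (length(bad))
      stopf("non-numeric value at gene '%s', sample '%s' in %s",
            genes[i], samples[bad[1]], matrixPath)
    vals[i, ] <- v
  }
  if (transpose) vals <- t(vals)

  ldelim <- detectDelim(labelsPath)
  lab <- read.delim(labelsPath, sep = ldelim, header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stopf("labels file must have two columns: %s", labelsPath)
  if (identical(tolower(lab[1, 1]), "sample_id") ||
      identical(tolower(lab[1, 2]), "class")) lab <- lab[-1, , drop = FALSE]
  labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  unlabeled <- setdiff(colnames(vals), names(labels))
  if (length(unlabeled))
    stopf("samples in matrix missing from labels: %s",
          paste(unlabeled, collapse = ", "))
  extra <- setdiff(names(labels), colnames(vals))
  if (length(extra))
    stopf("samples in labels missing from matrix: %s",
          paste(extra, collapse = ", "))
  labeledDataset(vals, labels)
}

#' Write a labeled expression dataset as delimited text
#'
#' Values are written with 15 significant digits so a write/read round trip
#' reproduces the dataset to well below 1e-9.
#'
#' @param ds a [LabeledDataset-class].
#' @param matrixPath,labelsPath output paths.
#' @param delim field delimiter (default tab).
#' @return invisibly, the two paths.
#' @export
writeLabeledDataset <- function(ds, matrixPath, labelsPath, delim = "\t") {
  stopifnot(is(ds, "LabeledDataset"))
  if (ncol(ds) == 0 || nrow(ds) == 0)
    stopf("refusing to write a degenerate dataset (%d genes x %d samples)",
          nrow(ds), ncol(ds))
  m <- exprsMatrix(ds)
  lines <- c(
    paste(c("gene", colnames(m)), collapse = delim),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                     scientific = FALSE)), collapse = delim),
      character(1)))
  tryCatch(writeLines(lines, matrixPath),
           error = function(e) stopf("cannot write %s: %s", matrixPath,
                                     conditionMessage(e)))
  writeLines(paste(colnames(m), as.character(classLabels(ds)), sep = "\t"),
             labelsPath)
  invisible(c(matrixPath, labelsPath))
}
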