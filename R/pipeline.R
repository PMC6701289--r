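## End-to-end orchestration: MCFS ranking -> informative threshold ->
## IFS/SVM branch and Johnson+RIPPER rule branch, with a reproducibility
## manifest.

#' Assemble a pipeline configuration
#'
#' Either a synthetic-data configuration or a pair of input files drives the
#' run; every stage consumes a sub-seed derived from the master seed.
#'
#' @param synthetic a [SyntheticConfig-class], or `NULL` when reading files.
#' @param matrixPath,labelsPath delimited-text inputs (ignored when
#'   `synthetic` is given).
#' @param mcfs an [MCFSParams-class] (its seed is overridden by a derived
#'   sub-seed).
#' @param clf a [ClassifierConfig-class].
#' @param cv a [CVConfig-class].
#' @param nPermutations,alpha informative-threshold settings.
#' @param coarseStep,intervalHalfwidthSteps two-stage IFS settings.
#' @param runIFS,runRules,runRandomCheck stage switches.
#' @param nRandomSubsets random-subset count for the significance check.
#' @param ripperArgs list of extra arguments for [ripperInduce()].
#' @param outDir output directory.
#' @param seed master seed.
#' @return a named list (class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(synthetic = NULL, matrixPath = NULL,
                           labelsPath = NULL, mcfs = mcfsParams(),
                           clf = classifierConfig(), cv = cvConfig(),
                           nPermutations = 20L, alpha = 0.05,
                           coarseStep = 10L, intervalHalfwidthSteps = 10L,
                           runIFS = TRUE, runRules = TRUE,
                           runRandomCheck = FALSE, nRandomSubsets = 100L,
                           ripperArgs = list(), outDir = tempfile("pdxrun"),
                           seed = 1L) {
  structure(list(synthetic = synthetic, matrixPath = matrixPath,
                 labelsPath = labelsPath, mcfs = mcfs, clf = clf, cv = cv,
                 nPermutations = as.integer(nPermutations), alpha = alpha,
                 coarseStep = as.integer(coarseStep),
                 intervalHalfwidthSteps = as.integer(intervalHalfwidthSteps),
                 runIFS = runIFS, runRules = runRules,
                 runRandomCheck = runRandomCheck,
                 nRandomSubsets = as.integer(nRandomSubsets),
                 ripperArgs = ripperArgs, outDir = outDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Collects all diagnostics rather than failing on the first; an empty
#' character vector means the configuration is runnable.
#'
#' @param cfg a `PipelineConfig`.
#' @param ds optionally, the already-loaded dataset to validate against.
#' @return character vector of diagnostics.
#' @export
validatePipelineConfig <- function(cfg, ds = NULL) {
  diag <- character()
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$matrixPath) || is.null(cfg$labelsPath)))
    diag <- c(diag, "either 'synthetic' or both input paths must be set")
  if (!is.null(cfg$synthetic)) {
    v <- methods::validObject(cfg$synthetic, test = TRUE)
    if (!isTRUE(v)) diag <- c(diag, paste("synthetic:", v))
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) diag <- c(diag, "alpha must be in (0, 1)")
  if (cfg$nPermutations < 3) diag <- c(diag, "nPermutations must be >= 3")
  if (cfg$coarseStep < 1) diag <- c(diag, "coarseStep must be >= 1")
  if (is.null(ds) && !is.null(cfg$synthetic)) {
    sizes <- cfg$synthetic@classSizes
    N <- cfg$synthetic@nGenes
  } else if (!is.null(ds)) {
    sizes <- table(classLabels(ds)); N <- nrow(ds)
  } else sizes <- N <- NULL
  if (!is.null(sizes)) {
    small <- names(sizes)[sizes < cfg$cv@folds]
    if (length(small))
      diag <- c(diag, sprintf(
        "folds (%d) exceed the size of class(es) %s; folds will be reduced",
        cfg$cv@folds, paste(small, collapse = ", ")))
    if (!is.na(cfg$mcfs@m) && cfg$mcfs@m > N)
      diag <- c(diag, sprintf("mcfs m (%d) exceeds gene count (%d)",
                              cfg$mcfs@m, N))
  }
  diag
}

writeTSV <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full tissue-of-origin pipeline
#'
#' Stages, in order: data acquisition (synthetic generation or file read),
#' MCFS ranking, permutation threshold for informative genes, the rule
#' branch (Johnson reducer + RIPPER on the informative genes, evaluated by
#' self-consistency and honest cross-validation), the IFS/SVM branch
#' (two-stage scan of the ranking), and optionally the random-subset
#' significance check of the optimal set.  All outputs are plain text under
#' `cfg$outDir`; `manifest.json` records parameters, derived stage seeds and
#' output files, and re-running the same configuration reproduces every
#' file bit-identically (wall-times go to `run.log`, which is excluded from
#' that guarantee).
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  diag <- validatePipelineConfig(cfg)
  fatal <- diag[!grepl("will be reduced", diag)]
  if (length(fatal))
    stopf("invalid pipeline configuration:\n  %s", paste(fatal, collapse = "\n  "))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), logCon)
    if (!quiet) message(msg)
  }
  manifest <- list(package = "pdxsite",
                   version = as.character(utils::packageVersion("pdxsite")),
                   seed = cfg$seed, stages = list(), files = character())
  addFile <- function(f) manifest$files <<- c(manifest$files, basename(f))
  result <- list()

  tryCatch({
    ## ---- stage: data -------------------------------------------------------
    say("stage data: acquiring dataset")
    if (!is.null(cfg$synthetic)) {
      syn <- cfg$synthetic
      syn@seed <- deriveSeed(cfg$seed, "synthetic")
      gen <- generateDataset(syn)
      ds <- gen$dataset
      truth <- gen$truth
      writeLabeledDataset(ds, file.path(cfg$outDir, "matrix.tsv"),
                          file.path(cfg$outDir, "labels.tsv"))
      addFile("matrix.tsv"); addFile("labels.tsv")
      mk <- data.frame(
        class = rep(names(truth@markerMap), lengths(truth@markerMap)),
        gene = unlist(truth@markerMap, use.names = FALSE))
      writeTSV(mk, file.path(cfg$outDir, "ground_truth.tsv"))
      addFile("ground_truth.tsv")
      manifest$stages$data <- list(kind = "synthetic", seed = syn@seed)
      result$truth <- truth
    } else {
      ds <- readLabeledDataset(cfg$matrixPath, cfg$labelsPath)
      manifest$stages$data <- list(kind = "files", matrix = cfg$matrixPath,
                                   labels = cfg$labelsPath)
    }
    result$dataset <- ds

    ## ---- stage: mcfs -------------------------------------------------------
    mp <- cfg$mcfs
    mp@seed <- deriveSeed(cfg$seed, "mcfs")
    say("stage mcfs: growing %d trees over %d genes", mp@t * mp@p, nrow(ds))
    rk <- mcfsRank(ds, mp)
    ranking <- rk$ranking
    rankDf <- data.frame(rank = seq_len(nrow(ds)),
                         gene = rankedGenes(ranking),
                         RI = ranking@ri[ranking@ranking])
    writeTSV(rankDf, file.path(cfg$outDir, "ranking.tsv"))
    addFile("ranking.tsv")
    manifest$stages$mcfs <- list(seed = mp@seed, t = mp@t, p = mp@p,
                                 m = resolveM(mp, nrow(ds)))
    result$ranking <- ranking

    say("stage threshold: %d permutations", cfg$nPermutations)
    th <- permutationThreshold(ds, mp, cfg$nPermutations, cfg$alpha,
                               ri = rk$ri)
    infoDf <- data.frame(gene = rankDf$gene, RI = rankDf$RI,
                         informative = rankDf$gene %in% th$informative)
    writeTSV(infoDf, file.path(cfg$outDir, "informative.tsv"))
    addFile("informative.tsv")
    manifest$stages$threshold <- list(threshold = th$threshold@threshold,
                                      alpha = cfg$alpha,
                                      nInformative = length(th$informative))
    result$threshold <- th

    ## ---- stage: rules ------------------------------------------------------
    if (cfg$runRules) {
      candidates <- th$informative
      if (length(candidates) < 2) {
        say("stage rules: too few informative genes (%d); using top 50 ranked",
            length(candidates))
        candidates <- head(rankedGenes(ranking), 50)
      }
      say("stage rules: Johnson reducer + RIPPER on %d candidate genes",
          length(candidates))
      red <- johnsonReducer(ds, candidates, ri = riScores(ranking),
                            seed = deriveSeed(cfg$seed, "johnson"))
      rs <- do.call(ripperInduce,
                    c(list(ds = ds, genes = red,
                           seed = deriveSeed(cfg$seed, "ripper")),
                      cfg$ripperArgs))
      writeRules(rs, file.path(cfg$outDir, "rules.txt"))
      addFile("rules.txt")
      selfRep <- evaluateRuleSet(rs, ds, "self_consistency")
      cvr <- cfg$cv
      cvr@repeats <- 3L
      cvr@seed <- deriveSeed(cfg$seed, "rulecv")
      cvRep <- suppressWarnings(
        evaluateRuleSet(rs, ds, "cv", cv = cvr, candidateGenes = candidates,
                        ripperArgs = cfg$ripperArgs))
      ruleReport <- list(
        n_rules = length(rs), default_class = defaultClass(rs),
        self_consistency = list(ACC = overallAccuracy(selfRep),
                                MCC = mcc(selfRep)),
        cv = list(ACC = overallAccuracy(cvRep), MCC = mcc(cvRep)))
      jsonlite::write_json(ruleReport,
                           file.path(cfg$outDir, "rule_report.json"),
                           auto_unbox = TRUE, digits = NA)
      addFile("rule_report.json")
      manifest$stages$rules <- list(seed = deriveSeed(cfg$seed, "ripper"),
                                    nReduct = length(red),
                                    nRules = length(rs))
      result$rules <- rs
      result$ruleSelf <- selfRep
      result$ruleCV <- cvRep
    } else manifest$stages$rules <- list(skipped = TRUE)

    ## ---- stage: ifs --------------------------------------------------------
    if (cfg$runIFS) {
      say("stage ifs: two-stage scan (coarse step %d)", cfg$coarseStep)
      cvi <- cfg$cv
      cvi@seed <- deriveSeed(cfg$seed, "ifs")
      ifs <- suppressWarnings(
        twoStageIFS(ds, ranking, cfg$coarseStep, cfg$intervalHalfwidthSteps,
                    cfg$clf, cvi))
      writeTSV(as.data.frame(ifs$stage1),
               file.path(cfg$outDir, "ifs_stage1.tsv"))
      writeTSV(as.data.frame(ifs$stage2),
               file.path(cfg$outDir, "ifs_stage2.tsv"))
      writeLines(ifs$optimal@genes,
                 file.path(cfg$outDir, "optimal_features.txt"))
      addFile("ifs_stage1.tsv"); addFile("ifs_stage2.tsv")
      addFile("optimal_features.txt")
      opt <- ifs$optimal
      jsonlite::write_json(
        list(size = opt@size, ACC = overallAccuracy(opt@report),
             MCC = mcc(opt@report),
             per_class_ACC = as.list(perClassAccuracy(opt@report))),
        file.path(cfg$outDir, "optimal_report.json"),
        auto_unbox = TRUE, digits = NA)
      addFile("optimal_report.json")
      manifest$stages$ifs <- list(seed = cvi@seed, optimalSize = opt@size,
                                  optimalMCC = mcc(opt@report))
      result$ifs <- ifs

      if (cfg$runRandomCheck) {
        say("stage randomcheck: %d random subsets of size %d",
            cfg$nRandomSubsets, opt@size)
        rc <- suppressWarnings(randomSubsetSignificance(
          ds, opt@size, cfg$nRandomSubsets, cfg$clf, cvi,
          observedMcc = mcc(opt@report),
          seed = deriveSeed(cfg$seed, "randomcheck")))
        writeTSV(data.frame(subset = seq_along(rc$mccs), MCC = rc$mccs),
                 file.path(cfg$outDir, "random_mccs.tsv"))
        addFile("random_mccs.tsv")
        manifest$stages$randomcheck <- list(p = rc$p,
                                            threshold95 = rc$alphaThreshold)
        result$randomCheck <- rc
      } else manifest$stages$randomcheck <- list(skipped = TRUE)
    } else {
      manifest$stages$ifs <- list(skipped = TRUE)
      manifest$stages$randomcheck <- list(skipped = TRUE)
    }
  }, error = function(e) {
    manifest$stages$error <<- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stopf("pipeline stage failed: %s", conditionMessage(e))
  })

  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  addFile("manifest.json")
  say("pipeline complete: %s", cfg$outDir)
  result$manifest <- manifest
  invisible(result)
}
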