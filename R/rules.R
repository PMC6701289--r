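#' Construct a rule
#'
#' @param conditions data.frame with columns `gene`, `op` (`">="`/`"<="`),
#'   `threshold`; zero rows make a default rule.
#' @param consequent class label predicted when all conditions hold.
#' @return a [Rule-class].
#' @export
rule <- function(conditions, consequent) {
  if (is.null(conditions) || !nrow(as.data.frame(conditions)))
    conditions <- data.frame(gene = character(), op = character(),
                             threshold = numeric())
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  methods::new("Rule", conditions = conditions,
               consequent = as.character(consequent))
}

#' Construct an ordered rule set
#'
#' @param rules ordered list of [Rule-class]; the single empty-condition
#'   (default) rule must come last.
#' @return a [RuleSet-class].
#' @export
ruleSet <- function(rules) methods::new("RuleSet", rules = rules)

#' @rdname pdxsite-generics
#' @export
setMethod("defaultClass", "RuleSet", function(x, ...)
  x@rules[[length(x@rules)]]@consequent)

#' @rdname pdxsite-generics
#' @export
setMethod("ruleGenes", "RuleSet", function(x, ...)
  unique(unlist(lapply(x@rules, function(r) r@conditions$gene))))

setMethod("length", "RuleSet", function(x) length(x@rules))

setMethod("show", "Rule", function(object) {
  cat(serializeRules(ruleSetUnchecked(list(object))), "\n")
})

ruleSetUnchecked <- function(rules) {
  obj <- methods::new("RuleSet")
  obj@rules <- rules
  obj
}

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet of", length(object@rules), "rules (default:",
      defaultClass(object), ")\n")
  writeLines(strsplit(serializeRules(object), "\n")[[1]])
})

conditionHolds <- function(cond, values) {
  v <- values[cond$gene]
  ifelse(cond$op == ">=", v >= cond$threshold, v <= cond$threshold)
}

#' Apply an ordered rule set to one or more samples
#'
#' The first rule (in order) whose conditions all hold fires; comparisons
#' are inclusive, exactly as the thresholds are printed.  If no condition
#' rule fires, the default class is returned.
#'
#' @param rs a [RuleSet-class].
#' @param sample a named numeric vector of expression values, a genes x
#'   samples matrix, or a [LabeledDataset-class].
#' @return the predicted class label(s).
#' @export
applyRules <- function(rs, sample) {
  stopifnot(is(rs, "RuleSet"))
  if (is(sample, "LabeledDataset")) sample <- exprsMatrix(sample)
  if (is.matrix(sample))
    return(vapply(seq_len(ncol(sample)), function(j) {
      v <- sample[, j]
      names(v) <- rownames(sample)   # 1-gene matrices drop names otherwise
      applyRules(rs, v)
    }, character(1)))
  needed <- ruleGenes(rs)
  missing <- setdiff(needed, names(sample))
  if (length(missing))
    stopf("sample is missing gene(s): %s", paste(missing, collapse = ", "))
  for (r in rs@rules) {
    if (!nrow(r@conditions) || all(conditionHolds(r@conditions, sample)))
      return(r@consequent)
  }
  defaultClass(rs)   # unreachable: the default rule always fires
}

## ---- serialization ---------------------------------------------------------

#' Serialize / parse rule sets as plain text
#'
#' One rule per line, `IF gene >= x AND gene <= y THEN class`; the default
#' rule is written `IF THEN class` and is only legal on the last line.
#' Unicode operators are accepted on input; `>=` / `<=` are canonical on
#' output.
#'
#' @param rs a [RuleSet-class].
#' @return `serializeRules`: a single string; `parseRules`: a
#'   [RuleSet-class].
#' @export
serializeRules <- function(rs) {
  lines <- vapply(rs@rules, function(r) {
    if (!nrow(r@conditions)) return(paste("IF THEN", r@consequent))
    conds <- paste(r@conditions$gene, r@conditions$op,
                   format(r@conditions$threshold, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   collapse = " AND ")
    paste("IF", conds, "THEN", r@consequent)
  }, character(1))
  paste(lines, collapse = "\n")
}

#' @rdname serializeRules
#' @param text character: a single string with newlines, or a vector of
#'   lines.
#' @export
parseRules <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    mt <- regmatches(ln, regexec("^IF\\s*(.*?)\\s*THEN\\s+(.+)$", ln))[[1]]
    if (length(mt) != 3)
      stopf("cannot parse rule on line %d: '%s'", i, ln)
    condStr <- mt[2]; cls <- mt[3]
    if (!nzchar(condStr)) {
      if (i != length(lines))
        stopf("default rule (no conditions) only allowed on the last line, found on line %d", i)
      rules[[i]] <- rule(NULL, cls)
      next
    }
    parts <- strsplit(condStr, "\\s+AND\\s+")[[1]]
    conds <- lapply(seq_along(parts), function(k) {
      cm <- regmatches(parts[k],
                       regexec("^(\\S+)\\s*(>=|<=|≥|≤)\\s*(-?[0-9.eE+-]+)$",
                               parts[k]))[[1]]
      if (length(cm) != 4)
        stopf("cannot parse condition '%s' on line %d", parts[k], i)
      op <- switch(cm[3], "≥" = ">=", "≤" = "<=", cm[3])
      thr <- suppressWarnings(as.numeric(cm[4]))
      if (is.na(thr)) stopf("bad threshold in '%s' on line %d", parts[k], i)
      data.frame(gene = cm[2], op = op, threshold = thr)
    })
    rules[[i]] <- rule(do.call(rbind, conds), cls)
  }
  ruleSet(rules)
}

#' @rdname serializeRules
#' @param path file path.
#' @export
writeRules <- function(rs, path) {
  writeLines(serializeRules(rs), path)
  invisible(path)
}

#' @rdname serializeRules
#' @export
readRules <- function(path) parseRules(readLines(path))

#' Load the published 16-rule tissue classifier
#'
#' Returns the sixteen IF-THEN threshold rules distinguishing the eight PDX
#' tissues, exactly as published: 15 condition rules plus the final default
#' rule assigning Large intestine, in their printed order, thresholds to
#' three decimals.
#'
#' @return a [RuleSet-class] of 16 rules.
#' @examples
#' rs <- loadTable2Rules()
#' length(rs)          # 16
#' defaultClass(rs)    # "Large intestine"
#' @export
loadTable2Rules <- function() {
  path <- system.file("extdata", "table2_rules.txt", package = "pdxsite",
                      mustWork = TRUE)
  readRules(path)
}

## ---- evaluation ------------------------------------------------------------

normalizeLabel <- function(x) tolower(trimws(x))

rulesConfusion <- function(rs, ds) {
  truth <- as.character(classLabels(ds))
  pred <- applyRules(rs, ds)
  lv <- classLevels(ds)
  predNorm <- lv[match(normalizeLabel(pred), normalizeLabel(lv))]
  if (anyNA(predNorm))
    stopf("rule consequent(s) not among dataset classes: %s",
          paste(unique(pred[is.na(predNorm)]), collapse = ", "))
  unclass(table(factor(truth, levels = lv), factor(predNorm, levels = lv)))
}

#' Evaluate a rule set by self-consistency or cross-validation
#'
#' Self-consistency applies the given rules to every sample.
#' Cross-validation, by default, honestly re-induces a rule set on each
#' training fold (MDL discretization, Johnson reducer, RIPPER) and applies
#' it to the held-out fold, pooling confusion counts over folds and repeats;
#' set `reinduce = FALSE` to evaluate the fixed rule set per fold instead.
#'
#' @param rs a [RuleSet-class] (for `mode = "cv"` with `reinduce = TRUE` it
#'   only supplies the candidate gene pool default).
#' @param ds a [LabeledDataset-class].
#' @param mode `"self_consistency"` or `"cv"`.
#' @param cv a [CVConfig-class]; rules are conventionally evaluated with
#'   `repeats = 3`.
#' @param reinduce logical, see above.
#' @param candidateGenes gene pool for per-fold re-induction; defaults to
#'   the genes referenced by `rs`.
#' @param ripperArgs list of arguments passed on to [ripperInduce()].
#' @return a [PerformanceReport-class].
#' @export
evaluateRuleSet <- function(rs, ds, mode = c("self_consistency", "cv"),
                            cv = cvConfig(repeats = 3L), reinduce = TRUE,
                            candidateGenes = NULL, ripperArgs = list()) {
  mode <- match.arg(mode)
  if (mode == "self_consistency")
    return(performanceReport(rulesConfusion(rs, ds)))
  y <- classLabels(ds)
  lv <- classLevels(ds)
  minClass <- min(table(y))
  if (minClass < 2) stopf("every class needs at least 2 samples")
  k <- min(cv@folds, minClass)
  if (k < cv@folds)
    warnf("reducing folds from %d to %d (smallest class has %d samples)",
          cv@folds, k, minClass)
  if (is.null(candidateGenes)) candidateGenes <- ruleGenes(rs)
  conf <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_len(cv@repeats)) {
    fold <- withSeed(deriveSeed(cv@seed, paste0("rulerep", r)),
                     if (cv@stratified) stratifiedFoldIds(y, k)
                     else sample(rep_len(seq_len(k), length(y))))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      dtr <- ds[, -test]
      rsf <- if (reinduce) {
        red <- johnsonReducer(dtr, candidateGenes)
        do.call(ripperInduce,
                c(list(ds = dtr, genes = red,
                       seed = deriveSeed(cv@seed, sprintf("induce%d_%d", r, f))),
                  ripperArgs))
      } else rs
      pred <- applyRules(rsf, exprsMatrix(ds)[, test, drop = FALSE])
      predNorm <- lv[match(normalizeLabel(pred), normalizeLabel(lv))]
      conf <- conf + unclass(table(factor(as.character(y[test]), levels = lv),
                                   factor(predNorm, levels = lv)))
    }
  }
  performanceReport(conf)
}
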