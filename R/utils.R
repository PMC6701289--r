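## Internal helpers: seed derivation and RNG hygiene.

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' One master seed fans out to per-stage seeds so that each pipeline stage
#' (subset draws, split draws, permutations, folds, ...) consumes its own
#' documented stream and can be replayed in isolation.  The derivation is a
#' small multiplicative hash of the label folded into the master seed, kept
#' strictly below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. `"subsets"` or `"perm3"`.
#' @return a single integer seed.
#' @examples
#' deriveSeed(1L, "subsets")
#' @export
deriveSeed <- function(seed, label) {
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 69069 + h) %% 2147483629 + 1)
}

## Evaluate `expr` under a local RNG seeded with `seed`, restoring the
## caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Stratified assignment of samples to k folds; returns an integer vector of
## fold ids.  Within each class, samples are shuffled and dealt round-robin,
## so fold class proportions differ by at most one sample.
stratifiedFoldIds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
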