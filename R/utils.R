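# internal helpers

# run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one seed, all below 2^31
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertScalarCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      x != round(x))
    stop(what, " must be a single positive integer", call. = FALSE)
  as.integer(x)
}

# stratified fold assignment: within each level, samples are shuffled and
# dealt round-robin, so fold class proportions differ by at most one
# sample. When sample ids are supplied, samples are ordered by id before
# the seeded shuffle, making the assignment a function of sample identity
# rather than position (so cross-validation is permutation-equivariant).
.stratifiedFolds <- function(y, folds, seed, ids = NULL) {
  y <- as.factor(y)
  fold <- integer(length(y))
  .withSeed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      if (!is.null(ids)) idx <- idx[order(ids[idx])]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# rank-based one-vs-rest AUROC (Wilcoxon identity, ties averaged)
.aucRank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# argmax over probability rows with ties broken by column (level) order
.argmaxAssign <- function(prob) {
  lev <- colnames(prob)
  factor(lev[apply(prob, 1L, which.max)], levels = lev)
}
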