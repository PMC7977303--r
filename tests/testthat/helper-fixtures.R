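# shared fixtures, built lazily once per test run

.fixture_cache <- new.env(parent = emptyenv())

smallClassSizes <- c(ABMR = 18, AKI = 8, MIXED = 8, TCMR = 12,
                     NOREJECTION = 40, NORMAL = 6)

mediumClassSizes <- c(ABMR = 36, AKI = 14, MIXED = 14, TCMR = 24,
                      NOREJECTION = 96, NORMAL = 12)

smallConfig <- function(seed = 42L, ...) {
  bhotFixtureConfig(n_genes = 120, class_sizes = smallClassSizes,
                    seed = seed, ...)
}

mediumConfig <- function(seed = 101L, ...) {
  bhotFixtureConfig(n_genes = 240, class_sizes = mediumClassSizes,
                    seed = seed, ...)
}

# the full-size default cohort taken through batch correction and low-CV
# filtering, with its PC sets and feature bundles; reused across files
# (classifier tests on it use the cheap models, not the elastic net)
fixturePipeline <- function() {
  if (!is.null(.fixture_cache$medium)) return(.fixture_cache$medium)
  cfg <- bhotFixtureConfig()
  sim <- simulateBhot(cfg)
  ds <- batchNormalize(sim$dataset, detectBatches(sim$dataset, seed = 3L))
  ds <- dropLowCV(ds)
  suppressWarnings({
    pbpc <- derivePBPC(ds)
    cppc <- deriveCPPC(ds, fixtureCatalog(cfg))
    upc <- deriveUPC(ds)
  })
  bundles <- makeBundles(pbpc = pbpc, cppc = cppc, upc = upc)
  .fixture_cache$medium <- list(cfg = cfg, sim = sim, ds = ds,
                                pbpc = pbpc, cppc = cppc, upc = upc,
                                bundles = bundles,
                                dx = diagnosis(ds))
  .fixture_cache$medium
}

# noise-free configuration: deterministic mean structure
noiselessConfig <- function(n_subtypes = NULL,
                            batch_offsets = list(list(offset = 0,
                                                      genes = NULL)),
                            seed = 5L) {
  bhotFixtureConfig(n_genes = 120, class_sizes = smallClassSizes,
                    noise_sd = 0, subtype_shift_sd = 0,
                    module_effect_sd = 0,
                    batch_offsets = batch_offsets, seed = seed,
                    heterogeneity = !is.null(n_subtypes))
}

# sample from a known TAN/naive-Bayes generator over binary features
sampleTAN <- function(n, p_c = 0.5, p1 = c(0.3, 0.7),
                      dep = 0.8, chain = TRUE, seed = 1L) {
  set.seed(seed)
  C <- rbinom(n, 1, p_c)
  X1 <- rbinom(n, 1, p1[C + 1])
  if (chain) {
    X2 <- rbinom(n, 1, ifelse(X1 == 1, dep, 1 - dep))
    X3 <- rbinom(n, 1, ifelse(X2 == 1, dep, 1 - dep))
  } else {
    X2 <- rbinom(n, 1, c(0.4, 0.6)[C + 1])
    X3 <- rbinom(n, 1, c(0.2, 0.8)[C + 1])
  }
  bins <- c("low", "high")
  x <- cbind(X1 = bins[X1 + 1], X2 = bins[X2 + 1], X3 = bins[X3 + 1])
  list(x = x, y = factor(c("c0", "c1")[C + 1]))
}

# two well-separated Gaussian blobs: a perfectly separable 2-class toy
separableToy <- function(n = 100, d = 4, gap = 12, seed = 9L) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- matrix(rnorm(n * d), n, d)
  x[y == "B", 1] <- x[y == "B", 1] + gap
  colnames(x) <- paste0("f", seq_len(d))
  rownames(x) <- paste0("s", seq_len(n))
  list(x = x, y = y)
}

# hand-built PredictionTable from a desired confusion layout
predTableFromConfusion <- function(counts, levels_ = c("A", "B"),
                                   p_assigned = 0.8) {
  truth <- character(); assigned <- character()
  for (i in seq_along(levels_)) for (j in seq_along(levels_)) {
    k <- counts[i, j]
    truth <- c(truth, rep(levels_[i], k))
    assigned <- c(assigned, rep(levels_[j], k))
  }
  n <- length(truth)
  prob <- matrix((1 - p_assigned) / (length(levels_) - 1), n,
                 length(levels_), dimnames = list(NULL, levels_))
  prob[cbind(seq_len(n), match(assigned, levels_))] <- p_assigned
  new("PredictionTable",
      truth = factor(truth, levels = levels_), prob = prob,
      assigned = factor(assigned, levels = levels_),
      meta = list(model = "manual", bundle = "manual"))
}
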