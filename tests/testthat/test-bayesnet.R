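test_that("supervised cuts land on the class boundary", {
  set.seed(2)
  y <- factor(rep(c("A", "B"), each = 40))
  f <- ifelse(y == "B", 1, 0) + rnorm(80, 0, 0.01)
  x <- cbind(ind = f, noise = rnorm(80))
  map <- discretizeFeatures(x, y, seed = 1L)
  expect_gt(map[["ind"]], 0.1)
  expect_lt(map[["ind"]], 0.9)
  bins <- applyDiscretization(map, x)
  expect_identical(unname(bins[, "ind"]),
                   ifelse(y == "B", "high", "low"))
  # determinism and the constant-feature contract
  map2 <- discretizeFeatures(x, y, seed = 1L)
  expect_identical(map, map2)
  expect_error(discretizeFeatures(cbind(flat = rep(1, 80)), y), "flat")
})

test_that("chain structure is recovered and independence is pruned", {
  chain_hits <- 0L; nb_hits <- 0L
  for (s in 1:5) {
    ch <- sampleTAN(2000, chain = TRUE, seed = 40L + s)
    m <- learnTAN(ch$x, ch$y)
    kept <- m@edgeTable[m@edgeTable$kept, c("from", "to")]
    edges <- apply(kept, 1, function(r) paste(sort(r), collapse = "-"))
    chain_hits <- chain_hits +
      setequal(edges, c("X1-X2", "X2-X3"))
    nb <- sampleTAN(2000, chain = FALSE, seed = 60L + s)
    m2 <- learnTAN(nb$x, nb$y)
    nb_hits <- nb_hits + (sum(m2@edgeTable$kept) == 0L)
  }
  expect_gte(chain_hits, 4L)
  expect_gte(nb_hits, 4L)
})

test_that("two features admit at most one edge and MDL decreases", {
  ch <- sampleTAN(500, chain = TRUE, seed = 3L)
  m <- learnTAN(ch$x[, 1:2], ch$y)
  expect_lte(sum(!is.na(m@parent)), 1L)
  m3 <- learnTAN(ch$x, ch$y)
  trace <- attr(m3, "mdl_trace")
  expect_true(all(diff(trace) < 0))
})

test_that("posteriors match brute-force enumeration of the joint", {
  ch <- sampleTAN(300, chain = TRUE, seed = 7L)
  m <- learnTAN(ch$x, ch$y)
  prob <- predictTAN(m, ch$x)
  # oracle: tabulate the full joint P(c, x1, x2, x3) from the CPTs
  bins <- c("low", "high")
  configs <- expand.grid(X1 = bins, X2 = bins, X3 = bins,
                         stringsAsFactors = FALSE)
  joint <- matrix(0, nrow(configs), length(m@classLevels),
                  dimnames = list(NULL, m@classLevels))
  for (r in seq_len(nrow(configs))) for (ci in seq_along(m@classLevels)) {
    p <- m@classPrior[[ci]]
    for (f in m@features) {
      xi <- match(configs[r, f], bins)
      p <- p * if (is.na(m@parent[[f]])) m@cpts[[f]][xi, ci] else
        m@cpts[[f]][xi, ci, match(configs[r, m@parent[[f]]], bins)]
    }
    joint[r, ci] <- p
  }
  key <- apply(configs, 1, paste, collapse = "|")
  obs <- apply(ch$x, 1, paste, collapse = "|")
  oracle <- joint[match(obs, key), , drop = FALSE]
  oracle <- oracle / rowSums(oracle)
  expect_lt(max(abs(prob - oracle)), 1e-10)
})

test_that("uniform CPTs predict the prior with prior-entropy log-loss", {
  ch <- sampleTAN(200, seed = 9L)
  m <- learnTAN(ch$x, ch$y)
  for (f in m@features) m@cpts[[f]][] <- 0.5
  prob <- predictTAN(m, ch$x)
  expect_lt(max(abs(sweep(prob, 2, m@classPrior))), 1e-12)
  pt <- new("PredictionTable", truth = ch$y, prob = prob,
            assigned = bhotmodel:::.argmaxAssign(prob), meta = list())
  prior_for_truth <- m@classPrior[as.character(ch$y)]
  expect_equal(evaluatePredictions(pt)$log_loss,
               -mean(log(prior_for_truth)), tolerance = 1e-9)
})

test_that("the learned model approaches the generator's Bayes error", {
  gen <- sampleTAN(2000, chain = FALSE, seed = 11L)
  m <- learnTAN(gen$x, gen$y)
  ev <- evaluateTAN(m, gen$x, gen$y)
  # Bayes error of the naive generator by enumeration of true posteriors
  p1 <- c(0.3, 0.7); p2 <- c(0.4, 0.6); p3 <- c(0.2, 0.8)
  bins <- c(0, 1)
  err <- 0
  for (a in bins) for (b in bins) for (cc in bins) {
    like <- function(k)
      dbinom(a, 1, p1[k]) * dbinom(b, 1, p2[k]) * dbinom(cc, 1, p3[k])
    post <- c(like(1), like(2)) * 0.5
    err <- err + sum(post) * (min(post) / sum(post))
  }
  expect_lt(abs(ev$report$percent_error - 100 * err), 2)
})

test_that("Bayes factors follow their likelihood-ratio definition", {
  # P(high|c) = 0.9, P(high|not c) = 0.3 -> BF = 3.0 (unsmoothed)
  y <- factor(rep(c("c", "o"), each = 100))
  f1 <- c(rep(c("high", "low"), c(90, 10)), rep(c("high", "low"),
                                                c(30, 70)))
  ind <- rep(c("high", "low"), 100)      # independent of the class
  x <- cbind(f1 = f1, f2 = ind)
  m <- learnTAN(x, y, alpha_smooth = 0)
  bf <- bayesFactors(m, x, y)
  expect_equal(bf$bf[bf$class == "c" & bf$feature == "f1" &
                       bf$bin == "high"], 3.0, tolerance = 1e-9)
  expect_equal(bf$bf[bf$class == "c" & bf$feature == "f2" &
                       bf$bin == "high"], 1.0, tolerance = 1e-9)
  expect_equal(bf$log2_bf[bf$class == "c" & bf$feature == "f2" &
                            bf$bin == "high"], 0, tolerance = 1e-9)
  # smoothed per-class bin probabilities stay normalized
  m2 <- learnTAN(x, y, alpha_smooth = 0.5)
  bf2 <- bayesFactors(m2, x, y)
  sums <- aggregate(p_in ~ class + feature, data = bf2, FUN = sum)
  expect_true(all(abs(sums$p_in - 1) < 1e-9))
})

test_that("fixture Bayes factors separate NORMAL by tubular, not inflammation", {
  med <- fixturePipeline()
  map <- discretizeFeatures(med$bundles$CPPC, med$dx, seed = 4L)
  bin <- applyDiscretization(map, med$bundles$CPPC)
  m <- learnTAN(bin, med$dx)
  bf <- bayesFactors(m, bin, med$dx)
  tub <- grep("tubular", unique(bf$feature), value = TRUE)
  infl <- grep("inflammatory", unique(bf$feature), value = TRUE)
  expect_gt(bf$bf[bf$class == "NORMAL" & bf$feature == tub &
                    bf$bin == "high"], 1)
  expect_lt(bf$bf[bf$class == "NORMAL" & bf$feature == infl &
                    bf$bin == "high"], 1)
})

test_that("TAN models serialize to JSON and DOT", {
  ch <- sampleTAN(300, seed = 15L)
  m <- learnTAN(ch$x, ch$y)
  path <- tempfile(fileext = ".json")
  writeTANJson(m, path)
  obj <- jsonlite::read_json(path)
  expect_identical(unlist(obj$features), m@features)
  dot <- tanToDot(m)
  expect_match(dot, "digraph TAN")
  expect_match(dot, "C -> \"X1\"")
})
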