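# independent first-principal-component oracle: eigen-decomposition of
# the explicit cross-product matrix (a different route than svd())
oracleFirstPC <- function(z) {
  n <- nrow(z)
  cp <- crossprod(z) / (n - 1)
  e <- eigen(cp, symmetric = TRUE)
  v <- e$vectors[, 1]
  list(score = as.numeric(z %*% v), loading = v, eigenvalue = e$values[1])
}

test_that("robust standardization tracks the classical z on clean data", {
  set.seed(4)
  x <- matrix(rnorm(500 * 3, mean = 7, sd = 1.2), nrow = 3)
  rownames(x) <- paste0("g", 1:3)
  z <- robustStandardize(x)
  for (g in 1:3) {
    cz <- (x[g, ] - mean(x[g, ])) / sd(x[g, ])
    expect_gt(cor(z[, g], cz), 0.99)
  }
})

test_that("standardization winsorizes outliers and zeroes dead genes", {
  x <- rbind(out = c(rnorm(50), 50), const = rep(3, 51))
  expect_warning(z <- robustStandardize(x), "zero-variance")
  expect_equal(max(abs(z[, "out"])), 4)
  expect_true(all(z[, "const"] == 0))
})

test_that("gene-set scores match the brute-force decomposition oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(20:60, 1); p <- sample(3:12, 1)
    z <- matrix(rnorm(n * p), n, p)
    sv <- svd(z, nu = 1, nv = 1)
    ours <- as.numeric(sv$u[, 1] * sv$d[1])
    orc <- oracleFirstPC(z)
    expect_lt(min(max(abs(ours - orc$score)), max(abs(ours + orc$score))),
              1e-8)
    expect_equal(sv$d[1]^2 / (n - 1), orc$eigenvalue, tolerance = 1e-8)
  }
})

test_that("a rank-1 submatrix yields score ~ u and full-variance eigenvalue", {
  set.seed(21)
  n <- 40; p <- 6
  u <- rnorm(n); u <- u - mean(u); v <- abs(rnorm(p)) + 0.5
  z <- u %*% t(v)
  # validate the decomposition itself on the rank-1 matrix (robust
  # standardization would reshape the exact rank-1 structure)
  sv <- svd(z, nu = 1, nv = 1)
  score <- sv$u[, 1] * sv$d[1]
  expect_gt(abs(cor(score, u)), 1 - 1e-10)
  expect_equal(sv$d[1]^2 / (n - 1), sum(apply(z, 2, var)),
               tolerance = 1e-8)
})

test_that("single-gene sets pass through as the standardized gene", {
  sim <- simulateBhot(smallConfig())
  ds <- sim$dataset
  g1 <- rownames(ds)[1]
  expect_warning(
    pcs <- deriveCPPC(ds, GeneSetCatalog(list(ONE = g1, NONE = "absent"))),
    "no overlapping")
  z <- robustStandardize(ds)
  zg <- z[, g1] - mean(z[, g1])
  sc <- pcScores(pcs)[, "ONE"]
  expect_lt(min(max(abs(sc - zg)), max(abs(sc + zg))), 1e-8)
})

test_that("eigenvalues conserve the standardized variance and scores are orthogonal", {
  sim <- simulateBhot(smallConfig())
  ds <- sim$dataset[1:40, ]   # fewer genes than samples: full spectrum
  upc <- deriveUPC(ds, min_eigen = 0)
  z <- robustStandardize(ds)
  expect_lt(abs(sum(eigenvalues(upc)) - sum(apply(z, 2, var))), 1e-6)
  sc <- pcScores(upc)
  cc <- abs(cor(sc))
  expect_lt(max(cc[upper.tri(cc)]), 1e-8)
  expect_true(all(diff(eigenvalues(upc)) <= 1e-8))
})

test_that("an i.i.d. Gaussian matrix retains no component at threshold 3", {
  set.seed(31)
  n <- 400; p <- 30   # n >> p: all eigenvalues near 1
  x <- matrix(rnorm(n * p, 8, 1), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  ds <- BhotExperiment(x)
  upc <- deriveUPC(ds, min_eigen = 3)
  expect_identical(ncol(pcScores(upc)), 0L)
})

test_that("supervised contrasts recover a planted single-module signal", {
  # only the inflammatory module separates TCMR from NOREJECTION here
  cfg <- simConfig(
    n_genes = 150, class_sizes = smallClassSizes,
    modules = list(
      inflammatory = list(genes = 1:30, shifts = list(TCMR = 1.6)),
      endothelial = list(genes = 31:55, shifts = list(ABMR = 1.4))),
    noise_sd = 0.6, housekeeping_frac = 0, seed = 13L)
  sim <- simulateBhot(cfg)
  pbpc <- suppressWarnings(derivePBPC(sim$dataset))
  prov <- pcProvenance(pbpc)
  expect_true("TCMR" %in% prov$decomposition)
  tcmr1 <- prov$component[prov$decomposition == "TCMR"][1]
  genes <- sim$truth$genes$gene[which(sim$truth$genes$module ==
                                        "inflammatory")]
  ld <- pcLoadings(pbpc)[, tcmr1]
  top20 <- names(sort(abs(ld), decreasing = TRUE))[1:20]
  expect_gte(mean(top20 %in% genes), 0.8)
})

test_that("the FDR gate uses the stated threshold", {
  expect_equal(-log10(0.005), 2.3, tolerance = 0.01)
  sim <- simulateBhot(smallConfig())
  ct <- contrastGenes(sim$dataset, "TCMR", alpha_fdr = 0.005)
  expect_identical(ct$selected, ct$p_adj < 0.005)
})

test_that("fixture class means reproduce the expected immunopathology", {
  med <- fixturePipeline()
  sc <- pcScores(med$cppc)
  dx <- med$dx
  cm <- apply(sc, 2, function(s) tapply(s, dx, mean))
  expect_true(all(cm[c("TCMR", "MIXED"), "inflammatory"] >
                    max(cm[c("NORMAL", "AKI"), "inflammatory"])))
  expect_true(all(cm[c("ABMR", "MIXED"), "endothelial"] >
                    max(cm[setdiff(diagnosisLevels(), c("ABMR", "MIXED")),
                           "endothelial"])))
  expect_gt(cm["NORMAL", "tubular"],
            max(cm[setdiff(diagnosisLevels(), "NORMAL"), "tubular"]))
  # UPC1 is an inflammatory contrast: top loadings from that module
  infl <- med$sim$truth$genes$gene[
    which(med$sim$truth$genes$module == "inflammatory")]
  ld <- pcLoadings(med$upc)[, "UPC1"]
  top <- names(sort(abs(ld), decreasing = TRUE))[1:20]
  expect_gte(mean(top %in% infl), 0.5)
})

test_that("derivations are invariant to sample order", {
  sim <- simulateBhot(smallConfig())
  ds <- sim$dataset
  perm <- sample(ncol(ds))
  upc1 <- deriveUPC(ds)
  upc2 <- deriveUPC(ds[, perm])
  expect_equal(pcScores(upc2), pcScores(upc1)[perm, , drop = FALSE],
               tolerance = 1e-8)
  cat_ <- fixtureCatalog(smallConfig())
  c1 <- suppressWarnings(deriveCPPC(ds, cat_))
  c2 <- suppressWarnings(deriveCPPC(ds[, perm], cat_))
  expect_equal(pcScores(c2), pcScores(c1)[perm, , drop = FALSE],
               tolerance = 1e-8)
})

test_that("loading reports annotate memberships and enrichment", {
  med <- fixturePipeline()
  rep_ <- loadingReport(med$cppc, fixtureCatalog(med$cfg), top_n = 15)
  tub <- med$sim$truth$genes$gene[
    which(med$sim$truth$genes$module == "tubular")]
  expect_gte(rep_$enrichment["tubular", "tubular"], 0.8)
  expect_true(all(rep_$top$rank <= 15))
  # empty catalog: gene list without memberships
  bare <- loadingReport(med$cppc, NULL, top_n = 5)
  expect_identical(ncol(bare$enrichment), 0L)
  expect_true(all(bare$top$sets == ""))
  # a component loading only on one set has enrichment 1 there
  one <- loadingReport(med$cppc,
                       GeneSetCatalog(list(tubular = tub)), top_n = 10)
  expect_equal(unname(one$enrichment["tubular", "tubular"]), 1)
})
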