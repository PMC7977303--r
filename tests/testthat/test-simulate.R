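test_that("default fixture reproduces the archival cohort dimensions", {
  cfg <- bhotFixtureConfig()
  expect_identical(cfg$n_genes, 667L)
  expect_identical(unname(cfg$class_sizes[c("ABMR", "NOREJECTION",
                                            "NORMAL")]),
                   c(105L, 514L, 22L))
  expect_identical(sum(cfg$class_sizes), 764L)
  sim <- simulateBhot(bhotFixtureConfig(n_genes = 80,
                                        class_sizes = smallClassSizes))
  expect_setequal(as.character(unique(diagnosis(sim$dataset))),
                  diagnosisLevels())
})

test_that("fixture encodes the expected heterogeneity and batch layout", {
  cfg <- bhotFixtureConfig()
  expect_gte(cfg$n_subtypes[["NOREJECTION"]], 3L)
  expect_identical(unname(which.max(cfg$class_sizes)),
                   match("NOREJECTION", names(cfg$class_sizes)))
  expect_true(all(cfg$n_subtypes[c("AKI", "TCMR", "MIXED",
                                   "NOREJECTION")] >= 2L))
  expect_length(cfg$batch_offsets, 3L)
  off <- bhotFixtureConfig(heterogeneity = FALSE)
  expect_true(all(off$n_subtypes == 1L))
  # qualitative class-shift pattern: inflammatory top in TCMR/MIXED,
  # endothelial in ABMR/MIXED, tubular in NORMAL, injury in AKI
  sh <- function(m) unlist(cfg$modules[[m]]$shifts)[diagnosisLevels()]
  expect_setequal(names(sort(sh("inflammatory"), decreasing = TRUE))[1:2],
                  c("TCMR", "MIXED"))
  expect_setequal(names(sort(sh("endothelial"), decreasing = TRUE))[1:2],
                  c("ABMR", "MIXED"))
  expect_identical(names(which.max(sh("tubular"))), "NORMAL")
  expect_identical(names(which.max(sh("injury"))), "AKI")
})

test_that("noise-free generation reproduces the planted template exactly", {
  cfg <- noiselessConfig()
  cfg$hk_noise_sd <- 0
  sim <- simulateBhot(cfg)
  x <- exprs(sim$dataset)
  dx <- diagnosis(sim$dataset)
  for (m in names(cfg$modules)) {
    gi <- sprintf("g%04d", cfg$modules[[m]]$genes)
    for (cl in diagnosisLevels()) {
      planted <- cfg$base_log2 + sim$truth$class_module_means[m, cl]
      expect_lt(max(abs(x[gi, dx == cl] - planted)), 1e-9)
    }
  }
  # non-module, non-housekeeping genes sit at baseline
  bg <- setdiff(rownames(sim$dataset),
                sprintf("g%04d", c(unlist(lapply(cfg$modules, `[[`,
                                                 "genes")), cfg$hk_genes)))
  expect_lt(max(abs(x[bg, ] - cfg$base_log2)), 1e-9)
})

test_that("generation is seed-deterministic", {
  cfg <- smallConfig(seed = 11L)
  a <- simulateBhot(cfg)
  b <- simulateBhot(cfg)
  expect_identical(exprs(a$dataset), exprs(b$dataset))
  expect_identical(a$truth, b$truth)
  cfg2 <- smallConfig(seed = 12L)
  expect_false(identical(exprs(a$dataset),
                         exprs(simulateBhot(cfg2)$dataset)))
})

test_that("annotations stay consistent with matrix dimensions", {
  set.seed(77)
  for (rep in 1:5) {
    ng <- sample(60:150, 1)
    cs <- smallClassSizes + sample(0:5, 6, replace = TRUE)
    cfg <- bhotFixtureConfig(n_genes = ng, class_sizes = cs,
                             seed = sample.int(1e6, 1))
    sim <- simulateBhot(cfg)
    ds <- sim$dataset
    expect_identical(dim(exprs(ds)), as.integer(c(ng, sum(cs))))
    expect_identical(nrow(sim$truth$samples), ncol(ds))
    expect_identical(nrow(sim$truth$genes), nrow(ds))
    expect_identical(as.integer(table(diagnosis(ds))[names(cs)]),
                     unname(as.integer(cs[names(cs)])))
    expect_false(anyNA(exprs(ds)))
    # every sample has exactly one diagnosis, subtype and batch
    expect_false(anyNA(sim$truth$samples$subtype))
    expect_false(anyNA(sim$truth$samples$batch))
    # housekeeping genes belong to no shifted module
    expect_true(all(sim$truth$genes$module[sim$truth$genes$housekeeping]
                    == "housekeeping"))
  }
})

test_that("planted batch offsets are recoverable from low-CV genes", {
  cfg <- noiselessConfig(batch_offsets = list(
    list(offset = 0, genes = NULL), list(offset = 0.8, genes = NULL),
    list(offset = -0.5, genes = NULL)))
  cfg$hk_noise_sd <- 0
  sim <- simulateBhot(cfg)
  hk <- names(which(housekeeping(sim$dataset)))
  x <- exprs(sim$dataset)[hk, ]
  bt <- sim$truth$samples$batch
  means <- tapply(colMeans(x), bt, mean)
  expect_equal(as.numeric(means - means[1]), c(0, 0.8, -0.5),
               tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(bhotFixtureConfig(class_sizes = c(ABMR = 1)), "six diagnoses")
  cs <- smallClassSizes; cs["NORMAL"] <- 0
  expect_error(bhotFixtureConfig(class_sizes = cs), "positive integer")
  expect_error(simConfig(n_genes = 50, class_sizes = smallClassSizes,
                         modules = list(bad = list(
                           genes = c(1, 60), shifts = list(TCMR = 1)))),
               "outside")
  expect_error(simConfig(n_genes = 100, class_sizes = smallClassSizes,
                         housekeeping_frac = 0.1,
                         modules = list(bad = list(
                           genes = 95:100, shifts = list(TCMR = 1)))),
               "housekeeping")
})

test_that("configs round-trip through YAML and cohorts through TSV", {
  cfg <- smallConfig(seed = 3L)
  yml <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, yml)
  cfg2 <- readSimConfig(yml)
  expect_identical(exprs(simulateBhot(cfg)$dataset),
                   exprs(simulateBhot(cfg2)$dataset))
  sim <- simulateBhot(cfg)
  dir <- tempfile(); writeExperimentTSV(sim$dataset, dir)
  m <- readExpressionTSV(file.path(dir, "expression.tsv"))
  expect_equal(m, exprs(sim$dataset), tolerance = 1e-9)
})
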