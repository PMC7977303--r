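test_that("series-matrix fixture parses with annotations", {
  path <- system.file("extdata", "synthetic_series_matrix.txt",
                      package = "bhotmodel")
  sm <- readSeriesMatrix(path)
  expect_identical(dim(sm$expr), c(8L, 6L))
  expect_identical(rownames(sm$expr)[1], "1001_at")
  expect_identical(colnames(sm$expr)[1], "GSM000001")
  expect_identical(nrow(sm$sampleInfo), 6L)
  expect_match(sm$sampleInfo$characteristics_ch1[1], "TCMR")
})

test_that("ingest subsets to the panel, collapses probes and maps labels", {
  path <- system.file("extdata", "synthetic_series_matrix.txt",
                      package = "bhotmodel")
  probe_map <- c("1001_at" = "CCL5", "1002_a_at" = "ACTB",
                 "1003_s_at" = "CXCL9", "1004_x_at" = "GAPDH",
                 "1005_at" = "GZMB", "1006_at" = "HAVCR1",
                 "1007_s_at" = "UMOD", "1008_at" = "XIST",
                 # duplicate probe for CCL5 with lower intensity
                 "1009_at" = "CCL5")
  panel <- c("CCL5", "ACTB", "CXCL9", "GAPDH", "GZMB", "HAVCR1", "UMOD",
             "XIST")
  sm <- readSeriesMatrix(path)
  ann <- data.frame(
    sample = colnames(sm$expr),
    diagnosis = sub("diagnosis: ", "", sm$sampleInfo$characteristics_ch1),
    row.names = colnames(sm$expr))
  mapping <- readDiagnosisMapping(
    system.file("extdata", "diagnosis_mapping.tsv", package = "bhotmodel"))
  ds <- ingestExpression(path, ann, panel = panel, exclude = "XIST",
                         mapping = mapping,
                         housekeeping = c("ACTB", "GAPDH"),
                         probe_map = probe_map, log2_transform = TRUE)
  expect_s4_class(ds, "BhotExperiment")
  expect_identical(nrow(ds), 7L)            # 8 panel genes - 1 excluded
  expect_setequal(names(which(housekeeping(ds))), c("ACTB", "GAPDH"))
  expect_identical(as.character(diagnosis(ds)),
                   c("TCMR", "ABMR", "NOREJECTION", "NOREJECTION", "AKI",
                     "NORMAL"))
  # unmapped labels are reported by name
  ann2 <- ann; ann2$diagnosis[2] <- "mystery label"
  expect_error(
    ingestExpression(path, ann2, panel = panel, mapping = mapping,
                     probe_map = probe_map, log2_transform = TRUE),
    "mystery label")
  expect_error(
    ingestExpression(path, ann, panel = c("NOT1", "NOT2"),
                     probe_map = probe_map),
    "panel error")
})

test_that("duplicate probes collapse to the highest mean intensity", {
  m <- rbind(a1 = c(10, 12, 14), a2 = c(100, 120, 140), b = c(5, 6, 7))
  colnames(m) <- paste0("s", 1:3)
  ds <- ingestExpression(m, panel = c("GENEA", "GENEB"),
                         probe_map = c(a1 = "GENEA", a2 = "GENEA",
                                       b = "GENEB"))
  expect_identical(unname(exprs(ds)["GENEA", ]), c(100, 120, 140))
})

test_that("synthetic pass-through ingest is the identity", {
  sim <- simulateBhot(smallConfig())
  dir <- tempfile(); writeExperimentTSV(sim$dataset, dir)
  ds <- ingestExpression(
    file.path(dir, "expression.tsv"),
    file.path(dir, "sample_annotations.tsv"),
    panel = rownames(sim$dataset),
    housekeeping = names(which(housekeeping(sim$dataset))))
  expect_equal(exprs(ds)[rownames(sim$dataset), colnames(sim$dataset)],
               exprs(sim$dataset), tolerance = 1e-9)
  expect_identical(as.character(diagnosis(ds)),
                   as.character(diagnosis(sim$dataset)))
})

test_that("GMT catalogs load through the GeneSetCatalog surface", {
  cat_ <- readGMT(system.file("extdata", "example_sets.gmt",
                              package = "bhotmodel"))
  expect_s4_class(cat_, "GeneSetCatalog")
  expect_identical(length(geneSets(cat_)), 3L)
  expect_true("UMOD" %in% geneSets(cat_)$TUBULAR)
})

test_that("housekeeping renormalization aligns sample geometric means", {
  prof <- c(7.0, 7.4, 6.8, 9.1, 5.2)
  m <- cbind(s1 = prof, s2 = prof + 1, s3 = prof, s4 = prof)
  rownames(m) <- c("hk1", "hk2", "hk3", "gA", "gB")
  ds <- BhotExperiment(m, rowData = data.frame(
    housekeeping = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    row.names = rownames(m)))
  norm <- renormalizeHousekeeping(ds)
  sh <- colData(norm)$hk_shift
  # the +1 sample is pulled down by exactly 1 relative to the others,
  # which share identical hk profiles hence identical shifts
  expect_equal(unname(sh["s2"] - sh["s1"]), -1, tolerance = 1e-12)
  expect_equal(unname(sh["s3"]), unname(sh["s1"]), tolerance = 1e-12)
  expect_equal(unname(exprs(norm)["gA", "s2"] - exprs(norm)["gA", "s1"]),
               0, tolerance = 1e-12)
  # every sample's hk geometric mean now equals the cohort mean; samples
  # already at the mean are fixed points
  gm <- colMeans(exprs(norm)[1:3, ])
  expect_lt(diff(range(gm)), 1e-12)
  again <- renormalizeHousekeeping(norm)
  expect_equal(exprs(again), exprs(norm), tolerance = 1e-12)
  expect_error(renormalizeHousekeeping(ds, c("hk1", "hk2", "nope")),
               "nope")
  expect_error(renormalizeHousekeeping(ds, c("hk1", "hk2")), "at least 3")
})

test_that("hk renormalization does not inflate housekeeping CV", {
  sim <- simulateBhot(smallConfig())
  hk <- housekeeping(sim$dataset)
  pre <- computeCV(sim$dataset)
  post <- computeCV(renormalizeHousekeeping(sim$dataset))
  expect_lte(mean(post$cv[hk]), mean(pre$cv[hk]) + 1e-8)
})

test_that("CV follows its linear-scale definition", {
  m <- rbind(const = c(8, 8, 8), g123 = log2(c(1, 2, 3)),
             g10x = log2(c(10, 20, 30)))
  colnames(m) <- paste0("s", 1:3)
  ds <- BhotExperiment(m)
  cv <- computeCV(ds)
  expect_identical(cv["const", "cv"], 0)
  expect_equal(cv["g123", "cv"], 50)           # sd 1, mean 2
  expect_equal(cv["g10x", "cv"], cv["g123", "cv"], tolerance = 1e-12)
})

test_that("low-CV dropping removes the quantile plus housekeeping", {
  sim <- simulateBhot(smallConfig())
  ds <- sim$dataset
  n_hk <- sum(housekeeping(ds))
  out <- dropLowCV(ds, quantile = 0.05)
  expect_gte(nrow(out), nrow(ds) - floor(0.05 * nrow(ds)) - n_hk)
  expect_identical(sum(housekeeping(out)), 0L)
  # quantile 0 with no housekeeping genes is the identity
  no_hk <- ds[!housekeeping(ds), ]
  expect_identical(nrow(dropLowCV(no_hk, quantile = 0)), nrow(no_hk))
})
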