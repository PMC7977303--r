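# bhotmodel

Classification and heterogeneity modelling of kidney-allograft gene
expression on the Banff Human Organ Transplant (BHOT) panel.

## What this package is for

The BHOT panel is a 770-gene NanoString codeset meant as a surrogate
for whole-transcriptome microarrays on kidney-transplant biopsies,
including formalin-fixed archival tissue. A central question for
anyone using it is how well a panel-sized feature space identifies the
six diagnostic summary classes of allograft pathology — ABMR, TCMR,
MIXED, AKI, NO REJECTION, NORMAL — and how stable those calls are per
sample when the features or the model change.

`bhotmodel` implements that evaluation as a reusable, tested pipeline:

* **Synthetic cohorts** (`simulateBhot`, `bhotFixtureConfig`) with the
  structure the analysis assumes: class-shifted gene modules
  (inflammatory, interferon, endothelial, injury, tubular,
  glomerular), discrete within-class subtypes plus a continuous
  disease-severity effect, three planted batches expressed in
  low-variance genes, and a near-zero-CV housekeeping block — with
  full ground truth for recovery tests. Defaults emulate an archival
  cohort of 764 samples x 667 genes (ABMR 105, AKI 28, MIXED 28,
  TCMR 67, NO REJECTION 514, NORMAL 22).
* **Ingest and batch handling** (`ingestExpression`,
  `renormalizeHousekeeping`, `computeCV`, `detectBatches`,
  `batchNormalize`, `dropLowCV`): GEO series-matrix or TSV input,
  panel subsetting with an exclusion list, explicit diagnosis-label
  mapping, housekeeping renormalization, UMAP batch detection on
  genes with linear CV <= 5%, scalar per-batch correction, and the
  lowest-5%-CV gene filter.
* **Three PC parsing strategies** (`derivePBPC`, `deriveCPPC`,
  `deriveUPC`): supervised contrast-based components (per-gene linear
  models vs NO REJECTION at BH-FDR 0.005, eigenvalue >= 3), one
  component per gene set (eigenvalue > 5), and unsupervised
  components, all on robust-standardized data (median/MAD, winsorized
  at +/-4).
* **Validated classifiers** (`fitPredict`, `evaluatePredictions`,
  `activeEffects`, `compareModels`): adaptive elastic-net multinomial
  regression, random forest, extra trees, LDA, gradient boosting and
  PLS-DA, all scored out-of-fold under stratified K-fold CV, with
  confusion matrices, per-class AUROC, log-loss, and elastic-net /
  linear-model feature selection.
* **Heterogeneity analysis** (`perSampleDiscordance`,
  `disparityProbability`, `kmeansSelect`, `cubicClusteringCriterion`,
  `contingencyDx`, `dxDistributionSummary`): per-sample
  (dis)agreement across feature bundles, probability disparities of
  misassigned samples, K-means cluster-count selection by Sarle's
  cubic clustering criterion, diagnosis-by-cluster contingency, and
  per-diagnosis distribution summaries with a Monte-Carlo dip test
  for biphasic classes.
* **A discretized Bayesian network** (`discretizeFeatures`,
  `learnTAN`, `bayesFactors`, `evaluateTAN`): two-bin supervised
  discretization, tree-augmented naive Bayes with MDL-pruned
  structure, per-(class, state) Bayes factors with KL divergences,
  and exact posterior inference.

## Worked example

```r
library(bhotmodel)

cfg <- bhotFixtureConfig()          # the default 764 x 667 cohort
sim <- simulateBhot(cfg)
sim$dataset
#> BhotExperiment: 667 genes x 764 samples
#> diagnoses: ABMR=105, AKI=28, MIXED=28, NOREJECTION=514, NORMAL=22, TCMR=67
#> batches: 1, 2, 3
#> housekeeping genes: 40

bm <- detectBatches(sim$dataset, seed = 2)
bm
#> BatchModel: 3 batch(es) over 764 samples, 40 reference genes
#> relative offsets (log2): 1=0.000, 2=0.060, 3=0.140

ds <- dropLowCV(batchNormalize(sim$dataset, bm))
pbpc <- derivePBPC(ds)
cppc <- deriveCPPC(ds, fixtureCatalog(cfg))
upc  <- deriveUPC(ds)
bundles <- makeBundles(pbpc = pbpc, cppc = cppc, upc = upc)

pred <- fitPredict(bundles$ALL, diagnosis(ds), folds = 10, seed = 3)
evaluatePredictions(pred)
#> ModelReport [multinomial-logistic-elasticnet on ALL]: n = 764
#> percent error 28.7 | accuracy 0.713 | mean AUROC 0.852 | log-loss 0.781
#>              assigned
#> true          ABMR AKI MIXED NOREJECTION NORMAL TCMR
#>   ABMR          38   1     0          56      0   10
#>   AKI            9   3     0          16      0    0
#>   MIXED         12   1     0          13      0    2
#>   NOREJECTION   16   2     1         480      6    9
#>   NORMAL         0   0     0          15      7    0
#>   TCMR          13   1     0          35      1   17

clusters <- kmeansSelect(bundles$ALL, seed = 4)
clusters
#> ClusterAssignment: K = 13 over 764 samples (max CCC = 10.15)

pred_cl <- fitPredict(bundles$ALL, factor(clusters$cluster),
                      folds = 10, seed = 3)
evaluatePredictions(pred_cl)$percent_error
#> [1] 2.9

disparityProbability(pred)[c("mean_disparity", "mean_concordant")]
#> $mean_disparity   0.59
#> $mean_concordant  0.79
```

The example shows the package's central finding in miniature: the
validated multinomial model misassigns ~29% of samples against the
annotated diagnosis (most confusion flowing into the large,
heterogeneous NO REJECTION class), the misassigned samples carry
systematically lower assigned-class probabilities (0.59 vs 0.79), and
re-targeting the same features at their own CCC-selected K-means
clusters drops the confusion error to ~3%.

The methods vignette (`vignettes/bhot-workflow.Rmd`) documents the
model assumptions, the generator calibration, and all numerical
choices.

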