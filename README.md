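# scInflamed

Discovery and pharmacogenomic characterization of *inflamed* tumor-cell
states from single-cell RNA-seq.

## What problem this solves

Tumors — triple-negative breast cancers in particular — contain rare
transcriptionally distinct tumor-cell subpopulations. A recurrent one is
an **inflamed state**: cells with elevated expression of a module of
interferon-stimulated genes (ISGs) driven by cGAS-STING signaling. Such
cells are chemoresistant, enriched in post-treatment residual disease, and
associated with early recurrence. Finding them, and connecting them to
drug response and clinical outcome, takes a chain of analyses that
`scInflamed` implements as one tested pipeline:

- **Subpopulation discovery** — QC filters (gene in ≥ 3 cells, 200–2,500
  genes/cell, < 5% mitochondrial UMIs), log-normalization, top-2,000
  variable genes by the variance-stabilizing (vst) ranking, covariate
  regression, PCA, jackstraw selection of significant components, and
  silhouette-optimal K-means (Louvain available) with one-vs-rest
  Wilcoxon marker tests.
- **Module scoring** — per-cell score of a gene module *M* against
  expression-matched controls,
  `score(c) = mean_{g∈M} x_gc − mean_{g∈ctrl} x_gc`, with controls drawn
  from 25 abundance bins (100 per module gene); inflamed-cell calling
  above the normal-tissue maximum score, with samples flagged at > 1%
  inflamed cells; hypergeometric over-representation and preranked
  running-sum enrichment (rankings of the form −log10 p × sign lfc).
- **CNV inference** — chromosome-ordered 100-gene moving averages of
  centered expression, Ward clustering into subclones, and
  state-subclone association tests.
- **Pharmacogenomic screen** — per-compound Pearson correlation of bulk
  module scores with normalized −log IC50 across a cell-line panel
  (negative r = resistance association), plus 4-parameter-logistic IC50
  and growth-rate-inhibition metrics
  (GR = 2^(log2(x/x0)/log2(x_ctrl/x0)) − 1, GR50).
- **Clinical outcomes** — paired pre/post-chemotherapy score tests,
  TPM > 0 expressing fractions, top-tertile ISG-high stratification, and
  Kaplan-Meier / log-rank survival.
- **Synthetic data** — a negative-binomial generator that plants a rare
  inflamed subpopulation, CNV subclones, a drug-response panel with a
  calibrated planted correlation, paired cohorts, and survival cohorts,
  all with exact ground truth, so every stage is testable without the
  original accessions.

The data containers are Bioconductor-native: counts live in a
`SingleCellExperiment` (genes × cells), gene sets in a `GeneModule`,
results in small S4 classes with accessors.

## Worked example

Simulate 2,000 cells with a 4% inflamed subpopulation (41-gene module,
log2 fold-change 1), recover it, and screen a drug panel:

```r
library(scInflamed)

cfg <- simConfig(nCells = 2000, nGenes = 1000, inflamedFraction = 0.04,
                 moduleLog2FC = 1, seed = 7)
sce <- simulateScCounts(cfg)
sce <- normalizeLog(filterCellsGenes(sce))
hvgs <- selectHVG(sce, nTop = 600)
umi <- log10(Matrix::colSums(SummarizedExperiment::assay(sce, "counts")))
scaled <- scaleAndRegress(sce, features = hvgs, covariates = umi)
sig <- jackstrawPCs(scaled, nComponents = 12, nPerm = 30,
                    permFraction = 0.02, seed = 8)
pca <- runPCA(scaled, max(sig, 2))
cl <- clusterOptimal(cellEmbeddings(pca)[, sig, drop = FALSE],
                     kRange = 2:8, seed = 9)
cl
#> ClusterAssignment: 3 clusters by kmeans
#>    0    1    2
#> 1069  848   83

isg <- GeneModule("ISG", cfg$moduleGenes)
scores <- moduleScore(sce, isg, seed = 10)
sort(tapply(scoreValues(scores), clusterLabels(cl), mean), decreasing = TRUE)
#>      2      0      1
#>  0.574 -0.029 -0.036
```

Cluster 2 (83 of 2,000 cells, 4.2%) is the high-scoring candidate; against
the generator's ground truth it contains the planted state almost exactly
(precision 0.964, recall 1.000). The module score per cluster shows the
characteristic pattern: one small cluster far above the rest.

```r
panel <- simulateBulkPanel(84, 90, isg, plantedCompoundIndex = 7,
                           plantedR = -0.4, seed = 11)
bulkScores <- bulkModuleScore(panel$expr, isg, seed = 12)
screen <- rankScreen(correlateScoreResponse(bulkScores, panel$panel))
head(as.data.frame(screen)[, c("compound", "r", "n", "p", "significant")], 3)
#>   compound          r  n            p significant
#> 1  cmpd007 -0.3751744 74 0.0009890649        TRUE
#> 2  cmpd060 -0.3028319 75 0.0082692594        TRUE
#> 3  cmpd041 -0.2809129 75 0.0146348098        TRUE
```

The planted compound (`cmpd007`, true r = −0.4) tops the
resistance-association ranking with r̂ = −0.375 over the 74 cell lines
with observed response. Finally, a 42-patient survival cohort with a
planted hazard ratio of 3 for the ISG-high tertile:

```r
surv <- simulateSurvivalCohort(42, 1/3, hazardRatio = 3, seed = 13)
lr <- logrankTest(surv$cohort)
sprintf("log-rank chi-square = %.2f, p = %.2e", lr$statistic, lr$p)
#> "log-rank chi-square = 22.75, p = 1.85e-06"
```

`runPipeline(pipelineConfig(seed = 1), "out/")` runs all stages from one
config and writes per-stage CSVs plus a checksummed manifest; two runs
with the same config and seed are byte-identical.

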