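#' Simulation configuration for synthetic scRNA-seq counts
#'
#' Builds a validated configuration for [simulateScCounts()]. The generator
#' plants a rare "inflamed" subpopulation with elevated expression of a
#' designated gene module (by default a 41-gene ISG-like module spread evenly
#' over the gene universe) and, optionally, chromosome-segment copy-number
#' subclones that act multiplicatively on expression. Membership of both the
#' inflamed state and the subclones is assigned by deterministic quota (the
#' first `floor(fraction * nCells)` cells of a seeded shuffle), so planted
#' counts are exact.
#'
#' @param nCells,nGenes numbers of cells and genes.
#' @param inflamedFraction proportion of cells in the inflamed state
#'   (default 0.04, the rare-subpopulation regime).
#' @param moduleGenes character vector of module genes; must be a subset of
#'   the simulated gene universe (`gene0001` ... ). `NULL` selects 41 genes
#'   evenly spaced over the universe.
#' @param moduleLog2FC log2 fold-change applied to module genes in inflamed
#'   cells.
#' @param nbDispersion negative-binomial dispersion; per-gene variance is
#'   `mu + mu^2 * nbDispersion`. Must be positive.
#' @param meanLibSize,libSizeCV mean and coefficient of variation of the
#'   log-normal per-cell library-size factors.
#' @param subclones list of subclones, each a list with elements `fraction`,
#'   `copyRatio`, and either `genes` (character vector) or `chrom` plus
#'   optional `start`/`end` base-pair bounds. Fractions must sum to at most
#'   1. The default plants two moderate chromosome-level subclones
#'   (25% of cells with a 1.3x chr2 gain, 20% with a 0.75x chr5 loss, 15%
#'   with a 1.25x chr8 gain), emulating the
#'   subclonal aneuploidy of TNBC cell lines; pass `list()` for a
#'   CNV-free population.
#' @param nChromosomes number of chromosomes the gene universe is split into
#'   (consecutive, equally sized blocks named "1", "2", ...).
#' @param abundanceSdLog log-normal spread of the per-gene baseline
#'   abundances.
#' @param moduleAbundanceQ quantile range of the abundance distribution
#'   from which module-gene baselines are drawn; ISG transcripts are
#'   reliably detected, so the default places them in the upper half.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return a validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(nCells = 100, nGenes = 200, seed = 1)
#' @export
simConfig <- function(nCells = 5000L, nGenes = 2000L,
                      inflamedFraction = 0.04, moduleGenes = NULL,
                      moduleLog2FC = 1, nbDispersion = 0.2,
                      meanLibSize = 6000, libSizeCV = 0.35,
                      subclones = list(
                        list(fraction = 0.25, chrom = "2", copyRatio = 1.3),
                        list(fraction = 0.20, chrom = "5", copyRatio = 0.75),
                        list(fraction = 0.15, chrom = "8", copyRatio = 1.25)),
                      nChromosomes = 10L,
                      abundanceSdLog = 1.6, moduleAbundanceQ = c(0.7, 0.99),
                      seed = 1L) {
  nCells <- as.integer(nCells); nGenes <- as.integer(nGenes)
  stopifnot(nCells >= 1L, nGenes >= 2L)
  if (inflamedFraction < 0 || inflamedFraction > 1)
    stop("inflamedFraction must lie in [0, 1]")
  if (nbDispersion <= 0) stop("nbDispersion must be positive")
  if (meanLibSize <= 0 || libSizeCV <= 0)
    stop("meanLibSize and libSizeCV must be positive")
  geneNames <- sprintf("gene%04d", seq_len(nGenes))
  if (is.null(moduleGenes)) {
    nMod <- min(41L, nGenes)
    moduleGenes <- geneNames[unique(round(seq(1, nGenes, length.out = nMod)))]
  } else if (!all(moduleGenes %in% geneNames)) {
    stop("module gene(s) not in the simulated gene universe: ",
         paste(setdiff(moduleGenes, geneNames), collapse = ", "))
  }
  if (length(subclones)) {
    fr <- vapply(subclones, function(s) s$fraction, numeric(1))
    if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-9)
      stop("subclone fractions must lie in [0,1] and sum to at most 1")
    for (s in subclones)
      if (is.null(s$copyRatio) || s$copyRatio <= 0)
        stop("each subclone needs a positive copyRatio")
  }
  cfg <- list(nCells = nCells, nGenes = nGenes,
              inflamedFraction = inflamedFraction,
              moduleGenes = moduleGenes, moduleLog2FC = moduleLog2FC,
              nbDispersion = nbDispersion, meanLibSize = meanLibSize,
              libSizeCV = libSizeCV, subclones = subclones,
              nChromosomes = as.integer(nChromosomes),
              abundanceSdLog = abundanceSdLog,
              moduleAbundanceQ = moduleAbundanceQ, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# baseline gene abundances (normalized to sum 1), drawn within the current
# RNG scope; module genes emulate ISG transcripts, which are well detected,
# so their baselines come from the upper quantile band of the abundance
# distribution (config$moduleAbundanceQ)
.drawAbundance <- function(config, uni) {
  rho <- stats::rlnorm(config$nGenes, meanlog = 0,
                       sdlog = config$abundanceSdLog)
  im <- which(uni$gene %in% config$moduleGenes)
  if (length(im))
    rho[im] <- stats::qlnorm(
      stats::runif(length(im), config$moduleAbundanceQ[1],
                   config$moduleAbundanceQ[2]),
      meanlog = 0, sdlog = config$abundanceSdLog)
  rho / sum(rho)
}

# gene universe layout: consecutive equal blocks of genes per chromosome,
# 1-based start coordinates spaced 100 kb apart
.geneUniverse <- function(cfg) {
  perChrom <- ceiling(cfg$nGenes / cfg$nChromosomes)
  idx <- seq_len(cfg$nGenes)
  chrom <- as.character((idx - 1L) %/% perChrom + 1L)
  start <- ((idx - 1L) %% perChrom) * 100000L + 1L
  data.frame(gene = sprintf("gene%04d", idx), chrom = chrom, start = start,
             stringsAsFactors = FALSE)
}

.subcloneGenes <- function(s, universe) {
  if (!is.null(s$genes)) {
    bad <- setdiff(s$genes, universe$gene)
    if (length(bad)) stop("subclone gene(s) not in universe: ",
                          paste(bad, collapse = ", "))
    return(s$genes)
  }
  sel <- universe$chrom == as.character(s$chrom)
  if (!is.null(s$start)) sel <- sel & universe$start >= s$start
  if (!is.null(s$end))   sel <- sel & universe$start <= s$end
  universe$gene[sel]
}

#' Simulate single-cell RNA-seq counts with planted ground truth
#'
#' Draws counts gene-wise from a negative binomial whose mean is
#' (baseline gene abundance) x (cell library factor) x
#' `2^(moduleLog2FC)` for module genes in inflamed cells x the subclone
#' copy-ratio for genes in the cell's subclone segment. Ground-truth labels
#' are stored in `colData` and the configuration in `metadata`.
#'
#' @param config a [simConfig()] object.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay (genes x cells), `colData` columns `inflamed`,
#'   `subclone`, `libFactor`, `rowData` columns `chrom`, `start`, `baseMean`,
#'   `inModule`, and `metadata(sce)$groundTruth`.
#' @examples
#' sce <- simulateScCounts(simConfig(nCells = 50, nGenes = 100, seed = 1))
#' table(SummarizedExperiment::colData(sce)$inflamed)
#' @export
simulateScCounts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  uni <- .geneUniverse(config)
  n <- config$nCells; p <- config$nGenes
  .withSeed(config$seed, {
    rho <- if (!is.null(config$fixedAbundance)) config$fixedAbundance
      else .drawAbundance(config, uni)
    sigma <- sqrt(log(1 + config$libSizeCV^2))
    lib <- config$meanLibSize *
      stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
    inflamed <- rep(FALSE, n)
    inflamed[sample.int(n)[seq_len(.quota(config$inflamedFraction, n))]] <- TRUE
    subclone <- rep("none", n)
    if (length(config$subclones)) {
      perm <- sample.int(n)
      at <- 0L
      for (j in seq_along(config$subclones)) {
        q <- .quota(config$subclones[[j]]$fraction, n)
        if (q > 0) subclone[perm[(at + 1L):(at + q)]] <- paste0("clone", j)
        at <- at + q
      }
    }
    inMod <- uni$gene %in% config$moduleGenes
    mu <- outer(rho, lib)                      # genes x cells
    if (config$moduleLog2FC != 0 && any(inflamed) && any(inMod))
      mu[inMod, inflamed] <- mu[inMod, inflamed] * 2^config$moduleLog2FC
    for (j in seq_along(config$subclones)) {
      g <- uni$gene %in% .subcloneGenes(config$subclones[[j]], uni)
      cc <- subclone == paste0("clone", j)
      if (any(g) && any(cc))
        mu[g, cc] <- mu[g, cc] * config$subclones[[j]]$copyRatio
    }
    counts <- matrix(stats::rnbinom(n * p, mu = mu,
                                    size = 1 / config$nbDispersion),
                     nrow = p, ncol = n,
                     dimnames = list(uni$gene, sprintf("cell%05d", seq_len(n))))
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(counts, "CsparseMatrix")),
      rowData = S4Vectors::DataFrame(chrom = uni$chrom, pos = uni$start,
                                     baseMean = rho, inModule = inMod,
                                     row.names = uni$gene),
      colData = S4Vectors::DataFrame(inflamed = inflamed,
                                     subclone = factor(subclone),
                                     libFactor = lib / config$meanLibSize,
                                     row.names = colnames(counts)))
    S4Vectors::metadata(sce)$config <- config
    S4Vectors::metadata(sce)$groundTruth <- list(
      inflamedLabels = stats::setNames(inflamed, colnames(counts)),
      subcloneLabels = stats::setNames(subclone, colnames(counts)),
      trueModuleMeans = stats::setNames(rho * config$meanLibSize, uni$gene),
      moduleGenes = config$moduleGenes)
    sce
  })
}

#' Simulate a bulk cell-line expression + drug-response panel
#'
#' Emulates a pharmacogenomic panel: a per-line latent module activity drives
#' the module genes' bulk expression; the planted compound's normalized
#' -log IC50 is `plantedR * z + sqrt(1 - plantedR^2) * noise`, where `z` is
#' the standardized realized module score of the generated expression
#' (computed with [bulkModuleScore()]), so the population correlation with
#' the realized score equals `plantedR` and the zero-noise `|plantedR| = 1`
#' case is exact. All other compounds are independent standard-normal noise;
#' a configurable fraction of response entries is missing completely at
#' random.
#'
#' @param nLines,nCompounds panel dimensions (default 84 x 90).
#' @param module a [GeneModule].
#' @param plantedCompoundIndex 1-based column index of the planted compound.
#' @param plantedR target correlation in `[-1, 1]`; negative means high
#'   module score associates with resistance (lower -log IC50).
#' @param nGenes number of background genes added to the module genes.
#' @param missingRate missing-completely-at-random rate for response entries.
#' @param seed integer seed.
#' @return list with `expr` (genes x lines), `panel` (lines x compounds,
#'   NA where missing), and `groundTruth` (planted drug name, `plantedR`,
#'   latent activity, realized scores).
#' @examples
#' gm <- GeneModule("ISG", sprintf("isg%02d", 1:10))
#' sim <- simulateBulkPanel(20, 5, gm, plantedCompoundIndex = 2,
#'                          plantedR = -0.5, seed = 1)
#' dim(sim$panel)
#' @export
simulateBulkPanel <- function(nLines = 84L, nCompounds = 90L, module,
                              plantedCompoundIndex = 1L, plantedR = -0.4,
                              nGenes = 500L, missingRate = 0.1, seed = 1L) {
  stopifnot(is(module, "GeneModule"), nLines >= 3L, nCompounds >= 1L)
  if (abs(plantedR) > 1) stop("|plantedR| must be at most 1")
  if (plantedCompoundIndex < 1L || plantedCompoundIndex > nCompounds)
    stop("plantedCompoundIndex out of range")
  mg <- moduleGenes(module)
  genes <- c(mg, sprintf("bg%04d", seq_len(max(nGenes, 50L))))
  lines <- sprintf("line%03d", seq_len(nLines))
  cmpds <- sprintf("cmpd%03d", seq_len(nCompounds))
  .withSeed(seed, {
    latent <- stats::rnorm(nLines)
    base <- stats::rnorm(length(genes), mean = 5, sd = 1.5)
    expr <- matrix(stats::rnorm(length(genes) * nLines, sd = 0.5),
                   nrow = length(genes),
                   dimnames = list(genes, lines)) + base
    expr[mg, ] <- expr[mg, ] + rep(latent, each = length(mg))
    sc <- bulkModuleScore(expr, module, seed = stageSeed(seed, "bulkscore"))
    z <- scoreValues(sc)
    z <- (z - mean(z)) / stats::sd(z)
    panel <- matrix(stats::rnorm(nLines * nCompounds), nrow = nLines,
                    dimnames = list(lines, cmpds))
    panel[, plantedCompoundIndex] <-
      plantedR * z + sqrt(1 - plantedR^2) * stats::rnorm(nLines)
    if (missingRate > 0)
      panel[stats::runif(length(panel)) < missingRate] <- NA_real_
    list(expr = expr, panel = panel,
         groundTruth = list(plantedDrug = cmpds[plantedCompoundIndex],
                            plantedR = plantedR, latent = latent,
                            scores = z))
  })
}

#' Simulate a paired pre/post-treatment single-cell cohort
#'
#' Per patient, two samples are drawn with [simulateScCounts()] using
#' `inflamedFraction = preFraction` and `postFraction` respectively
#' (emulating inflamed-cell enrichment in post-chemotherapy residual
#' disease). Per-sample seeds are derived from `config$seed` and the
#' patient/timepoint names, so samples are independent but reproducible.
#'
#' @param nPatients number of patients (each contributes two samples).
#' @param preFraction,postFraction inflamed fractions of the pre- and
#'   post-treatment samples.
#' @param config base [simConfig()]; its `inflamedFraction` is overridden.
#' @return list with `samples` (named list of SingleCellExperiment,
#'   "P1_pre", "P1_post", ...) and `index` (data.frame sample/patient/
#'   timepoint).
#' @export
simulatePairedCohort <- function(nPatients = 4L, preFraction = 0.04,
                                 postFraction = 0.4, config) {
  if (nPatients < 1L) stop("nPatients must be at least 1")
  if (preFraction < 0 || preFraction > 1 || postFraction < 0 || postFraction > 1)
    stop("fractions must lie in [0, 1]")
  stopifnot(inherits(config, "SimConfig"))
  samples <- list()
  idx <- NULL
  uni <- .geneUniverse(config)
  for (p in seq_len(nPatients)) {
    # the two timepoints sample the same tumor: they share the patient's
    # baseline gene abundances and differ only in inflamed fraction and in
    # the cells drawn
    rhoP <- .withSeed(stageSeed(config$seed, sprintf("patient%d_rho", p)),
                      .drawAbundance(config, uni))
    for (tp in c("pre", "post")) {
      cfg <- config
      cfg$fixedAbundance <- rhoP
      cfg$inflamedFraction <- if (tp == "pre") preFraction else postFraction
      cfg$seed <- stageSeed(config$seed, sprintf("patient%d_%s", p, tp))
      nm <- sprintf("P%d_%s", p, tp)
      samples[[nm]] <- simulateScCounts(cfg)
      idx <- rbind(idx, data.frame(sample = nm, patient = sprintf("P%d", p),
                                   timepoint = tp, stringsAsFactors = FALSE))
    }
  }
  list(samples = samples, index = idx)
}

#' Simulate a two-group survival cohort
#'
#' Exponential event times with rate `baselineRate * hazardRatio` for the
#' ISG-high stratum and `baselineRate` otherwise, with independent
#' exponential censoring. Group membership is assigned by deterministic
#' quota after a seeded shuffle.
#'
#' @param nPatients cohort size.
#' @param highFraction proportion assigned to the ISG-high stratum.
#' @param hazardRatio multiplicative hazard of the high stratum (> 0).
#' @param baselineRate event rate of the low stratum, per month (> 0).
#' @param censorRate censoring rate; 0 means no censoring.
#' @param seed integer seed.
#' @return list with `cohort` (data.frame id/time/event/stratum) and
#'   `groundTruth`.
#' @examples
#' sim <- simulateSurvivalCohort(42, 1/3, hazardRatio = 3, seed = 1)
#' table(sim$cohort$stratum)
#' @export
simulateSurvivalCohort <- function(nPatients = 42L, highFraction = 1/3,
                                   hazardRatio = 3, baselineRate = 0.05,
                                   censorRate = 0.02, seed = 1L) {
  if (highFraction < 0 || highFraction > 1)
    stop("highFraction must lie in [0, 1]")
  if (hazardRatio <= 0 || baselineRate <= 0)
    stop("hazardRatio and baselineRate must be positive")
  if (censorRate < 0) stop("censorRate must be non-negative")
  n <- as.integer(nPatients)
  if (n < 2L) stop("nPatients must be at least 2")
  .withSeed(seed, {
    high <- rep(FALSE, n)
    high[sample.int(n)[seq_len(.quota(highFraction, n))]] <- TRUE
    evt <- stats::rexp(n, rate = baselineRate * ifelse(high, hazardRatio, 1))
    cen <- if (censorRate > 0) stats::rexp(n, rate = censorRate) else
      rep(Inf, n)
    cohort <- data.frame(
      id = sprintf("pt%03d", seq_len(n)),
      time = pmin(evt, cen),
      event = as.integer(evt <= cen),
      stratum = factor(ifelse(high, "ISG-high", "ISG-low"),
                       levels = c("ISG-low", "ISG-high")),
      stringsAsFactors = FALSE)
    list(cohort = cohort,
         groundTruth = list(hazardRatio = hazardRatio,
                            highFraction = highFraction,
                            highLabels = stats::setNames(high, cohort$id)))
  })
}
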