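#' Build and validate a pipeline configuration
#'
#' One declarative configuration drives [runPipeline()]. Every stage block
#' is validated up front, before any stage runs, and the configuration
#' round-trips losslessly through YAML ([writePipelineConfig()] /
#' [readPipelineConfig()]). All randomness derives from the single `seed`
#' via [stageSeed()], so toggling one stage never changes another stage's
#' draws.
#'
#' @param seed global integer seed.
#' @param stages named logical list toggling simulate, qc, discovery,
#'   scoring, cnv, screen, outcomes.
#' @param simulate arguments for [simConfig()] (used when the simulate
#'   stage is enabled).
#' @param input list with `countsPath` and `format` for reading a real
#'   matrix when simulate is disabled.
#' @param qc,hvg,discovery,scoring,cnv,screen,survival stage parameter
#'   blocks; see the corresponding stage functions for meanings.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
    stages = list(simulate = TRUE, qc = TRUE, discovery = TRUE,
                  scoring = TRUE, cnv = TRUE, screen = TRUE,
                  outcomes = TRUE),
    simulate = list(nCells = 1200L, nGenes = 600L, inflamedFraction = 0.04,
                    moduleLog2FC = 1),
    input = list(countsPath = NULL, format = "mtx10x"),
    qc = list(minCellsPerGene = 3L, minGenesPerCell = 100L,
              maxGenesPerCell = 2500L, maxMitoFraction = 0.05,
              mitoPrefix = "MT-"),
    hvg = list(nTop = 500L, loessSpan = 0.3),
    discovery = list(nComponents = 15L, nPerm = 30L, permFraction = 0.02,
                     alpha = 0.05, kRange = 2:8, nInit = 5L,
                     method = "kmeans"),
    scoring = list(nBins = 25L, nCtrl = 100L, cutoffQuantile = 1,
                   statistic = "mean"),
    cnv = list(window = 100L, clip = 3, maxK = 6L),
    screen = list(nLines = 84L, nCompounds = 90L, plantedR = -0.4,
                  plantedCompoundIndex = 7L, missingRate = 0.1,
                  minN = 10L, alpha = 0.05),
    survival = list(nPatients = 42L, highFraction = 1/3, hazardRatio = 3,
                    baselineRate = 0.05, censorRate = 0.02)) {
  cfg <- list(seed = as.integer(seed), stages = stages, simulate = simulate,
              input = input, qc = qc, hvg = hvg, discovery = discovery,
              scoring = scoring, cnv = cnv, screen = screen,
              survival = survival)
  .validatePipelineConfig(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

.validatePipelineConfig <- function(cfg) {
  need <- c("simulate", "qc", "discovery", "scoring", "cnv", "screen",
            "outcomes")
  if (!all(need %in% names(cfg$stages)))
    stop("stages must name: ", paste(need, collapse = ", "))
  if (isTRUE(cfg$stages$simulate)) {
    do.call(simConfig, c(cfg$simulate, list(seed = 0L)))  # validates
  } else if (is.null(cfg$input$countsPath)) {
    stop("either enable the simulate stage or provide input$countsPath")
  }
  with(cfg$qc, stopifnot(minGenesPerCell < maxGenesPerCell,
                         maxMitoFraction >= 0, maxMitoFraction <= 1))
  with(cfg$discovery, stopifnot(nPerm >= 20, alpha >= 0, alpha <= 1,
                                all(kRange >= 2)))
  with(cfg$scoring, stopifnot(nBins >= 1, nCtrl >= 1))
  with(cfg$cnv, stopifnot(window >= 1, clip > 0))
  with(cfg$screen, stopifnot(abs(plantedR) <= 1, nLines >= 3))
  with(cfg$survival, stopifnot(hazardRatio > 0, baselineRate > 0))
  invisible(TRUE)
}

#' @rdname pipelineConfig
#' @param cfg a `PipelineConfig`.
#' @param path file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw[intersect(names(raw),
                                        names(formals(pipelineConfig)))])
}

.writeStage <- function(outDir, stage, name, df) {
  dir <- file.path(outDir, stage)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, name)
  if (file.exists(f)) stop("output exists (write-once violated): ", f)
  utils::write.csv(df, f, row.names = FALSE)
  f
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order simulate -> qc -> discovery ->
#' scoring -> cnv -> screen -> outcomes, each consuming the previous
#' stage's outputs, and writes per-stage CSV outputs plus a run manifest
#' (`manifest.json`) into `outDir`. The manifest records the configuration
#' hash, per-stage seeds, the package version and the MD5 checksum of every
#' output file; two runs with the same configuration and seed produce
#' byte-identical manifests. A stage failure aborts the run with the stage
#' name in the error.
#'
#' @param config a [pipelineConfig()] (or path to a YAML config).
#' @param outDir output directory; must not already contain a manifest.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  .validatePipelineConfig(config)
  if (file.exists(file.path(outDir, "manifest.json")))
    stop("outDir already holds a completed run (write-once)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  files <- character()
  warns <- character()
  stage <- "init"
  runStage <- function(name, enabled, fn) {
    stage <<- name
    if (!isTRUE(enabled)) return(NULL)
    withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  env <- new.env()
  runStage("simulate", TRUE, function() {
    if (isTRUE(config$stages$simulate)) {
      seeds$simulate <<- stageSeed(config$seed, "simulate")
      env$sce <- simulateScCounts(
        do.call(simConfig, c(config$simulate,
                             list(seed = seeds$simulate))))
      gt <- S4Vectors::metadata(env$sce)$groundTruth
      env$module <- GeneModule("ISG", gt$moduleGenes)
      files <<- c(files, .writeStage(outDir, "simulate", "groundtruth.csv",
        data.frame(cell = colnames(env$sce),
                   inflamed = gt$inflamedLabels,
                   subclone = gt$subcloneLabels)))
    } else {
      env$sce <- readCountMatrix(config$input$countsPath,
                                 config$input$format)
      env$module <- NULL
    }
  })

  runStage("qc", config$stages$qc, function() {
    env$sce <- do.call(filterCellsGenes, c(list(env$sce), config$qc))
    env$sce <- normalizeLog(env$sce)
    files <<- c(files, .writeStage(outDir, "qc", "cell_metrics.csv",
      data.frame(cell = colnames(env$sce),
                 detectedGenes = Matrix::colSums(
                   SummarizedExperiment::assay(env$sce, "counts") > 0),
                 totalUMI = Matrix::colSums(
                   SummarizedExperiment::assay(env$sce, "counts")))))
  })

  runStage("discovery", config$stages$discovery, function() {
    seeds$discovery <<- stageSeed(config$seed, "discovery")
    hvgs <- selectHVG(env$sce, nTop = min(config$hvg$nTop,
                                          nrow(env$sce)),
                      loessSpan = config$hvg$loessSpan)
    totalUMI <- Matrix::colSums(
      SummarizedExperiment::assay(env$sce, "counts"))
    env$scaled <- scaleAndRegress(env$sce, features = hvgs,
                                  covariates = log10(totalUMI))
    d <- config$discovery
    sig <- jackstrawPCs(env$scaled,
                        nComponents = min(d$nComponents,
                                          min(dim(env$scaled)) - 1L),
                        nPerm = d$nPerm, permFraction = d$permFraction,
                        alpha = d$alpha, seed = seeds$discovery)
    if (!length(sig)) sig <- 1L
    pca <- runPCA(env$scaled, nComponents = max(sig))
    env$emb <- cellEmbeddings(pca)[, sig, drop = FALSE]
    env$clusters <- clusterOptimal(env$emb, kRange = d$kRange,
                                   nInit = d$nInit, seed = seeds$discovery,
                                   method = d$method)
    files <<- c(files,
      .writeStage(outDir, "discovery", "clusters.csv",
        data.frame(cell = colnames(env$sce),
                   cluster = clusterLabels(env$clusters))),
      .writeStage(outDir, "discovery", "criterion_trace.csv",
                  criterionTrace(env$clusters)))
  })

  runStage("scoring", config$stages$scoring, function() {
    if (is.null(env$module)) stop("no gene module available for scoring")
    seeds$scoring <<- stageSeed(config$seed, "scoring")
    sc <- config$scoring
    env$scores <- moduleScore(env$sce, env$module, nBins = sc$nBins,
                              nCtrl = sc$nCtrl, seed = seeds$scoring,
                              statistic = sc$statistic)
    # normal-tissue reference: same universe with no inflamed cells
    normCfg <- do.call(simConfig, c(config$simulate,
      list(seed = stageSeed(config$seed, "normalref"))))
    normCfg$inflamedFraction <- 0
    normSce <- normalizeLog(do.call(filterCellsGenes,
      c(list(simulateScCounts(normCfg)), config$qc)))
    normScores <- moduleScore(normSce, env$module, nBins = sc$nBins,
                              nCtrl = sc$nCtrl, seed = seeds$scoring)
    env$calls <- classifyInflamed(env$scores, normScores,
                                  cutoffQuantile = sc$cutoffQuantile)
    files <<- c(files, .writeStage(outDir, "scoring", "scores.csv",
      data.frame(cell = colnames(env$sce),
                 score = scoreValues(env$scores),
                 inflamed = env$calls$inflamed)))
  })

  runStage("cnv", config$stages$cnv, function() {
    rd <- SummarizedExperiment::rowData(env$sce)
    geneMap <- data.frame(gene = rownames(env$sce), chrom = rd$chrom,
                          start = rd$pos)
    centered <- relativeExpression(env$sce, clip = config$cnv$clip)
    prof <- smoothCNV(centered, geneMap, window = config$cnv$window,
                      clip = config$cnv$clip)
    env$subclones <- clusterSubclones(prof, maxK = config$cnv$maxK)
    assoc <- if (!is.null(env$calls))
      stateSubcloneAssociation(env$subclones$labels, env$calls$inflamed,
                               seed = stageSeed(config$seed, "cnv"))
      else NULL
    files <<- c(files, .writeStage(outDir, "cnv", "subclones.csv",
      data.frame(cell = colnames(env$sce),
                 subclone = env$subclones$labels,
                 stateAssocP = if (is.null(assoc)) NA else assoc$p)))
  })

  runStage("screen", config$stages$screen, function() {
    if (is.null(env$module)) stop("no gene module available for the screen")
    seeds$screen <<- stageSeed(config$seed, "screen")
    s <- config$screen
    sim <- simulateBulkPanel(s$nLines, s$nCompounds, env$module,
                             plantedCompoundIndex = s$plantedCompoundIndex,
                             plantedR = s$plantedR,
                             missingRate = s$missingRate,
                             seed = seeds$screen)
    bs <- bulkModuleScore(sim$expr, env$module,
                          seed = stageSeed(config$seed, "screenscore"))
    env$screen <- rankScreen(correlateScoreResponse(bs, sim$panel,
                                                    minN = s$minN,
                                                    alpha = s$alpha))
    files <<- c(files, .writeStage(outDir, "screen", "screen.csv",
                                   as.data.frame(env$screen)))
  })

  runStage("outcomes", config$stages$outcomes, function() {
    seeds$outcomes <<- stageSeed(config$seed, "outcomes")
    sv <- config$survival
    sim <- simulateSurvivalCohort(sv$nPatients, sv$highFraction,
                                  sv$hazardRatio, sv$baselineRate,
                                  sv$censorRate, seed = seeds$outcomes)
    lr <- logrankTest(sim$cohort)
    km <- kaplanMeier(sim$cohort$time, sim$cohort$event)
    env$outcomes <- list(logrank = lr, km = km)
    files <<- c(files,
      .writeStage(outDir, "outcomes", "cohort.csv", sim$cohort),
      .writeStage(outDir, "outcomes", "km.csv", km),
      .writeStage(outDir, "outcomes", "logrank.csv",
        data.frame(statistic = lr$statistic, p = lr$p)))
  })

  cfgFile <- file.path(outDir, "config.yaml")
  writePipelineConfig(config, cfgFile)
  manifest <- list(
    package = as.character(utils::packageVersion("scInflamed")),
    configHash = unname(tools::md5sum(cfgFile)),
    seed = config$seed,
    stageSeeds = seeds,
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(files))),
                                      substring(sort(files),
                                                nchar(outDir) + 2L))),
    warnings = warns)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
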