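#' Quality-control filtering of cells and genes
#'
#' Applies the standard scRNA-seq QC filters in a fixed order: (1) genes
#' detected (count > 0) in fewer than `minCellsPerGene` cells are removed;
#' (2) cells whose detected-gene count falls outside
#' `[minGenesPerCell, maxGenesPerCell]` are removed; (3) cells whose
#' mitochondrial UMI fraction is at least `maxMitoFraction` are removed.
#' Steps are sequential: each filter sees the matrix left by the previous
#' one. Filtering is idempotent with respect to the cell filters only when
#' gene detection counts remain above threshold; re-running on the output is
#' a no-op for matrices in the stable regime.
#'
#' @param sce SingleCellExperiment (or matrix) of non-negative integer
#'   counts, genes x cells.
#' @param minCellsPerGene keep genes detected in at least this many cells.
#' @param minGenesPerCell,maxGenesPerCell detected-gene bounds per cell
#'   (defaults 200 and 2500; raise the upper bound to 8000 for deeply
#'   sequenced lines).
#' @param maxMitoFraction cells with mitochondrial UMI fraction at or above
#'   this value are removed.
#' @param mitoPrefix feature-name prefix identifying mitochondrial genes.
#' @return the filtered object, same class as the input.
#' @examples
#' sce <- simulateScCounts(simConfig(nCells = 300, nGenes = 300,
#'                                   meanLibSize = 2000, seed = 1))
#' dim(filterCellsGenes(sce, minGenesPerCell = 10))
#' @export
filterCellsGenes <- function(sce, minCellsPerGene = 3L,
                             minGenesPerCell = 200L, maxGenesPerCell = 2500L,
                             maxMitoFraction = 0.05, mitoPrefix = "MT-") {
  if (minGenesPerCell >= maxGenesPerCell)
    stop("minGenesPerCell must be below maxGenesPerCell")
  if (maxMitoFraction < 0 || maxMitoFraction > 1)
    stop("maxMitoFraction must lie in [0, 1]")
  counts <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "counts") else sce
  .checkCounts(counts)
  detected <- counts > 0
  keepGenes <- Matrix::rowSums(detected) >= minCellsPerGene
  if (!any(keepGenes)) stop("all genes filtered out (minCellsPerGene)")
  counts2 <- counts[keepGenes, , drop = FALSE]
  genesPerCell <- Matrix::colSums(counts2 > 0)
  keepCells <- genesPerCell >= minGenesPerCell & genesPerCell <= maxGenesPerCell
  if (!any(keepCells)) stop("all cells filtered out (gene-count bounds)")
  counts3 <- counts2[, keepCells, drop = FALSE]
  mito <- startsWith(rownames(counts3), mitoPrefix)
  if (any(mito)) {
    frac <- Matrix::colSums(counts3[mito, , drop = FALSE]) /
      pmax(Matrix::colSums(counts3), 1)
    keepMito <- frac < maxMitoFraction
    if (!any(keepMito)) stop("all cells filtered out (mitochondrial fraction)")
  } else keepMito <- rep(TRUE, ncol(counts3))
  gsel <- rownames(counts)[keepGenes]
  csel <- colnames(counts2)[keepCells][keepMito]
  if (is(sce, "SummarizedExperiment")) sce[gsel, csel] else
    counts[gsel, csel, drop = FALSE]
}

#' Library-size log-normalization
#'
#' `lognorm = ln(1 + scaleFactor * count / cellTotal)`, stored as the
#' `lognorm` assay. Doubling all counts of a cell leaves its normalized
#' vector unchanged.
#'
#' @param sce SingleCellExperiment with a `counts` assay (or a matrix).
#' @param scaleFactor library-size scale (default 1e4).
#' @return the input with a `lognorm` assay added (or the lognorm matrix).
#' @export
normalizeLog <- function(sce, scaleFactor = 1e4) {
  counts <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "counts") else sce
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("cell(s) with zero total counts: ",
         paste(head(bad, 5), collapse = ", "))
  }
  ln <- counts %*% Matrix::Diagonal(x = scaleFactor / totals)
  ln <- log1p(ln)
  dimnames(ln) <- dimnames(counts)
  if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "lognorm") <- ln
    sce
  } else ln
}

#' Highly variable gene selection by variance-stabilizing transform
#'
#' Ranks genes by standardized variance: a loess trend of log10(variance) on
#' log10(mean) is fitted over genes from the raw counts; each gene's counts
#' are standardized by its trend-predicted standard deviation, clipped at
#' `sqrt(nCells)`, and the variance of the standardized, clipped values is
#' the ranking statistic.
#'
#' @param sce SingleCellExperiment with `counts`, or a count matrix.
#' @param nTop number of genes to return (default 2000).
#' @param loessSpan span of the mean-variance trend fit.
#' @param clipMax clip bound for standardized values; default `sqrt(nCells)`.
#' @return character vector of the top `nTop` genes in decreasing order of
#'   standardized variance, with the full statistics in
#'   `attr(, "stats")`.
#' @export
selectHVG <- function(sce, nTop = 2000L, loessSpan = 0.3, clipMax = NULL) {
  counts <- .asMatrix(sce, if (is(sce, "SummarizedExperiment")) "counts")
  n <- ncol(counts)
  if (nTop > nrow(counts)) stop("nTop exceeds the number of genes")
  if (is.null(clipMax)) clipMax <- sqrt(n)
  mu <- rowMeans(counts)
  v <- rowSums((counts - mu)^2) / (n - 1)
  fit <- rep(NA_real_, nrow(counts))
  ok <- v > 0 & mu > 0
  lo <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loessSpan,
                     degree = 2)
  fit[ok] <- 10^stats::fitted(lo)
  sdExp <- sqrt(fit)
  z <- (counts - mu) / sdExp
  z <- pmin(z, clipMax)
  z <- pmax(z, -clipMax)
  stdVar <- rowSums((z - rowMeans(z))^2) / (n - 1)
  stdVar[!ok] <- 0
  ord <- order(-stdVar, rownames(counts))
  res <- rownames(counts)[ord][seq_len(nTop)]
  attr(res, "stats") <- data.frame(gene = rownames(counts), mean = mu,
                                   variance = v, expectedVar = fit,
                                   standardizedVar = stdVar,
                                   row.names = NULL)
  res
}

#' Per-gene covariate regression, scaling and clipping
#'
#' For each gene, ordinary least squares of log-normalized expression on the
#' covariates (with intercept); residuals are scaled to unit variance and
#' clipped at `±clip`. Zero-variance residual genes are set to all-zero
#' rows so the matrix shape is stable. With no covariates this reduces to
#' per-gene centering and scaling.
#'
#' @param sce SingleCellExperiment with a `lognorm` assay, or a lognorm
#'   matrix (genes x cells).
#' @param features genes to scale (default: all rows).
#' @param covariates numeric matrix (cells x q) or vector of per-cell
#'   covariates, e.g. total UMI counts and cell-cycle scores; `NULL` for
#'   none.
#' @param clip clip bound on the scaled residuals (default 10).
#' @return scaled matrix, `length(features)` x cells.
#' @export
scaleAndRegress <- function(sce, features = NULL, covariates = NULL,
                            clip = 10) {
  expr <- .asMatrix(sce, if (is(sce, "SummarizedExperiment")) "lognorm")
  if (is.null(features)) features <- rownames(expr)
  miss <- setdiff(features, rownames(expr))
  if (length(miss)) stop("features absent from the matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  expr <- expr[features, , drop = FALSE]
  n <- ncol(expr)
  X <- matrix(1, nrow = n, ncol = 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per cell")
    if (any(!is.finite(covariates))) stop("covariates must be finite")
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear covariates: design matrix rank ", qrX$rank,
         " < ", ncol(X), " columns")
  # residuals for all genes at once: R = Y - X (X'X)^-1 X'Y, Y = t(expr)
  B <- qr.coef(qrX, t(expr))
  R <- t(expr) - X %*% B
  sds <- sqrt(colSums(R^2) / (n - 1))
  scaled <- t(R) / ifelse(sds > 1e-12, sds, 1)
  scaled[sds <= 1e-12, ] <- 0
  scaled <- pmin(pmax(scaled, -clip), clip)
  dimnames(scaled) <- list(features, colnames(expr))
  scaled
}

#' Cell-cycle phase scores
#'
#' Scores S-phase and G2/M gene lists with [moduleScore()]; the returned
#' vectors are intended as covariates for [scaleAndRegress()] so cell-cycle
#' differences are regressed out.
#'
#' @param sce SingleCellExperiment with `lognorm`, or matrix.
#' @param sGenes,g2mGenes [GeneModule] objects for the two phase programs.
#' @param nBins,nCtrl,seed control-gene settings passed to [moduleScore()].
#' @return data.frame with columns `S` and `G2M`, one row per cell.
#' @export
cellCycleScores <- function(sce, sGenes, g2mGenes, nBins = 25L, nCtrl = 100L,
                            seed = 1L) {
  s <- scoreValues(moduleScore(sce, sGenes, nBins = nBins, nCtrl = nCtrl,
                               seed = seed))
  g <- scoreValues(moduleScore(sce, g2mGenes, nBins = nBins, nCtrl = nCtrl,
                               seed = seed))
  data.frame(S = s, G2M = g)
}
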