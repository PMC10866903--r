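#' Read gene modules from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then genes.
#'
#' @param path GMT file path.
#' @return named list of [GeneModule] objects.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  mods <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    GeneModule(f[1], unique(f[-(1:2)]))
  })
  stats::setNames(mods, vapply(mods, moduleName, character(1)))
}

#' Write gene modules to a GMT file
#'
#' @param modules a [GeneModule] or list of them.
#' @param path output path.
#' @export
writeGMT <- function(modules, path) {
  if (is(modules, "GeneModule")) modules <- list(modules)
  lines <- vapply(modules, function(m)
    paste(c(moduleName(m), "na", moduleGenes(m)), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Read a count matrix (10x MTX triplet or dense CSV)
#'
#' The MTX dialect expects `matrix.mtx`, `barcodes.tsv` and `features.tsv`
#' in one directory (features: id, symbol, type; genes are rows). The CSV
#' dialect is a dense genes x cells table whose first column holds gene
#' names.
#'
#' @param path directory (mtx10x) or file (csv).
#' @param format `"mtx10x"` or `"csv"`.
#' @return a SingleCellExperiment with an integer sparse `counts` assay.
#' @export
readCountMatrix <- function(path, format = c("mtx10x", "csv")) {
  format <- match.arg(format)
  if (format == "mtx10x") {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) if (!file.exists(f))
      stop("missing file of the MTX triplet: ", f)
    m <- tryCatch(Matrix::readMM(mtx), error = function(e)
      stop("malformed MatrixMarket file '", mtx, "': ",
           conditionMessage(e)))
    if (is(m, "nsparseMatrix")) m <- m * 1   # pattern matrix -> numeric
    barcodes <- readLines(bc)
    features <- utils::read.delim(ft, header = FALSE,
                                  stringsAsFactors = FALSE)
    if (nrow(m) != nrow(features))
      stop("dimension mismatch: matrix has ", nrow(m),
           " rows but features.tsv lists ", nrow(features), " genes")
    if (ncol(m) != length(barcodes))
      stop("dimension mismatch: matrix has ", ncol(m),
           " columns but barcodes.tsv lists ", length(barcodes), " cells")
    counts <- methods::as(m, "CsparseMatrix")
    dimnames(counts) <- list(features[[1]], barcodes)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    counts <- methods::as(as.matrix(df[, -1, drop = FALSE]),
                          "CsparseMatrix")
    rownames(counts) <- df[[1]]
  }
  .checkCounts(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
}

#' Write a count matrix (10x MTX triplet or dense CSV)
#'
#' Inverse of [readCountMatrix()]; `read(write(M)) == M` exactly for
#' integer counts.
#'
#' @param sce SingleCellExperiment (or matrix) with counts.
#' @param path output directory (mtx10x) or file (csv).
#' @param format `"mtx10x"` or `"csv"`.
#' @export
writeCountMatrix <- function(sce, path, format = c("mtx10x", "csv")) {
  format <- match.arg(format)
  counts <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "counts") else sce
  if (format == "mtx10x") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
    utils::write.table(
      data.frame(rownames(counts), rownames(counts), "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(gene = rownames(counts),
                     as.matrix(counts), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene coordinate map
#'
#' Tab-separated table with columns gene, chromosome, start. Coordinates
#' are treated as 1-based; BED-like 0-based starts are converted with
#' `zeroBased = TRUE`.
#'
#' @param path TSV path (header optional; autodetected by checking whether
#'   the third field of the first line is numeric).
#' @param zeroBased whether starts are 0-based (BED convention).
#' @return data.frame with columns `gene`, `chrom`, `start`.
#' @export
readGeneMap <- function(path, zeroBased = FALSE) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  hasHeader <- is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.delim(path, header = hasHeader,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("gene map needs columns gene, chrom, start")
  df <- df[, 1:3]
  names(df) <- c("gene", "chrom", "start")
  df$start <- as.integer(df$start) + as.integer(zeroBased)
  if (anyDuplicated(df$gene)) stop("duplicate gene names in gene map")
  if (any(df$start <= 0)) stop("coordinates must be positive")
  df
}
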