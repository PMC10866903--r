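#' Gene-module score with expression-matched control genes
#'
#' Genes are placed into `nBins` equal-size bins by average expression over
#' observations. For each module gene, `nCtrl` control genes are sampled
#' (seeded, with replacement) from its bin and pooled as a unique control
#' set. The score of each observation is the mean (or sum) over module genes
#' of its expression minus the corresponding reduction over the pooled
#' control genes; control subtraction makes the score exactly zero on a
#' constant matrix and cancels any per-observation constant added to all
#' genes.
#'
#' @param sce SingleCellExperiment with a `lognorm` assay, or a numeric
#'   matrix (genes x observations).
#' @param module a [GeneModule]; genes absent from the matrix are dropped
#'   with a warning (error if none remain).
#' @param nBins number of expression bins (default 25); must not exceed the
#'   number of genes.
#' @param nCtrl control genes sampled per module gene (default 100).
#' @param seed integer seed for control sampling.
#' @param statistic `"mean"` (default) or `"sum"` reduction over genes. The
#'   sum is `nModuleGenes` times the mean, so the two are scale-equivalent
#'   for a fixed module.
#' @param kind observation kind recorded in the result.
#' @return a [ModuleScores-class] with one finite score per observation.
#' @examples
#' m <- matrix(rpois(2000, 5), nrow = 40,
#'             dimnames = list(sprintf("g%02d", 1:40), NULL))
#' gm <- GeneModule("toy", c("g01", "g05", "g09"))
#' moduleScore(log1p(m), gm, nBins = 5, seed = 1)
#' @export
moduleScore <- function(sce, module, nBins = 25L, nCtrl = 100L, seed = 1L,
                        statistic = c("mean", "sum"), kind = "cell") {
  statistic <- match.arg(statistic)
  expr <- .asMatrix(sce, if (is(sce, "SummarizedExperiment")) "lognorm")
  stopifnot(is(module, "GeneModule"))
  genes <- intersect(moduleGenes(module), rownames(expr))
  dropped <- setdiff(moduleGenes(module), genes)
  if (length(dropped))
    warning(length(dropped), " module gene(s) absent from the matrix: ",
            paste(head(dropped, 5), collapse = ", "))
  if (!length(genes))
    stop("no module gene present in the matrix")
  if (nBins > nrow(expr))
    stop("nBins exceeds the number of genes")
  avg <- rowMeans(expr)
  ord <- order(avg, rownames(expr))            # deterministic tie-break
  sizes <- diff(round(seq(0, nrow(expr), length.out = nBins + 1)))
  binOf <- integer(nrow(expr))
  binOf[ord] <- rep(seq_len(nBins), times = sizes)
  names(binOf) <- rownames(expr)
  byBin <- split(rownames(expr), binOf)
  ctrl <- .withSeed(seed, {
    unique(unlist(lapply(genes, function(g) {
      pool <- byBin[[as.character(binOf[g])]]
      pool[sample.int(length(pool), nCtrl, replace = TRUE)]
    })))
  })
  modMean <- colMeans(expr[genes, , drop = FALSE])
  ctrlMean <- colMeans(expr[ctrl, , drop = FALSE])
  sc <- modMean - ctrlMean
  if (statistic == "sum") sc <- sc * length(genes)
  new("ModuleScores", scores = sc, kind = kind,
      module = moduleName(module), nBins = as.integer(nBins),
      nCtrl = as.integer(nCtrl), seed = as.integer(seed),
      statistic = statistic)
}

#' Module score for bulk samples
#'
#' Identical algorithm to [moduleScore()] with observations = bulk samples
#' (e.g. cell lines of a pharmacogenomic panel, columns of the matrix).
#'
#' @param bulkExpr genes x samples numeric matrix.
#' @inheritParams moduleScore
#' @return a [ModuleScores-class] with `kind = "bulk"`.
#' @export
bulkModuleScore <- function(bulkExpr, module, nBins = 25L, nCtrl = 100L,
                            seed = 1L, statistic = c("mean", "sum")) {
  moduleScore(bulkExpr, module, nBins = nBins, nCtrl = nCtrl, seed = seed,
              statistic = match.arg(statistic), kind = "bulk")
}

#' Call inflamed cells against a normal-tissue cutoff
#'
#' The cutoff is a quantile of the normal-tissue score distribution
#' (default 1.0, i.e. the normal maximum, so every normal cell is excluded);
#' tumor cells strictly above it are called inflamed. Per-sample inflamed
#' fractions are computed and samples with a fraction above `flagThreshold`
#' (default 1%) are flagged.
#'
#' @param tumorScores,normalScores [ModuleScores-class] objects (or named
#'   numeric vectors) computed with identical module/bin/control settings.
#' @param cutoffQuantile quantile of the normal scores used as cutoff.
#' @param sampleIds per-tumor-cell sample labels; `NULL` treats all cells as
#'   one sample.
#' @param flagThreshold per-sample fraction above which a sample is flagged.
#' @return list with `inflamed` (per-cell logical), `cutoff`, `fractions`
#'   (per sample) and `flagged` (per sample logical).
#' @export
classifyInflamed <- function(tumorScores, normalScores, cutoffQuantile = 1.0,
                             sampleIds = NULL, flagThreshold = 0.01) {
  ts <- if (is(tumorScores, "ModuleScores")) scoreValues(tumorScores) else
    tumorScores
  ns <- if (is(normalScores, "ModuleScores")) scoreValues(normalScores) else
    normalScores
  if (!length(ns)) stop("empty normal score set: no data-driven cutoff")
  if (is(tumorScores, "ModuleScores") && is(normalScores, "ModuleScores")) {
    same <- tumorScores@module == normalScores@module &&
      tumorScores@nBins == normalScores@nBins &&
      tumorScores@nCtrl == normalScores@nCtrl
    if (!same) stop("tumor and normal scores use different module settings")
  }
  cutoff <- unname(stats::quantile(ns, cutoffQuantile, type = 7))
  inflamed <- ts > cutoff
  if (is.null(sampleIds)) sampleIds <- rep("sample1", length(ts))
  fractions <- tapply(inflamed, sampleIds, mean)
  list(inflamed = inflamed, cutoff = cutoff,
       fractions = fractions, flagged = fractions > flagThreshold)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between a query gene list and a gene set, within a stated
#' universe.
#'
#' @param query character vector; must be a subset of `universe`.
#' @param geneSet a [GeneModule] or character vector; intersected with the
#'   universe (error if the intersection is empty).
#' @param universe character vector of all considered genes.
#' @return list with `p`, `overlap`, `expected`, `setSize`, `querySize`.
#' @examples
#' oraHypergeometric(letters[1:5], letters[1:5], letters[1:20])$p  # 1/choose(20,5)
#' @export
oraHypergeometric <- function(query, geneSet, universe) {
  if (is(geneSet, "GeneModule")) geneSet <- moduleGenes(geneSet)
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  set <- intersect(geneSet, universe)
  if (!length(set)) stop("gene set does not intersect the universe")
  k <- length(intersect(query, set))
  m <- length(set); n <- length(universe) - m; K <- length(query)
  p <- stats::phyper(k - 1, m, n, K, lower.tail = FALSE)
  list(p = p, overlap = k, expected = K * m / length(universe),
       setSize = m, querySize = K)
}

# running-sum enrichment score for set positions `hits` (indices into the
# decreasing-sorted scores)
.runningES <- function(absW, hits, N) {
  Nh <- length(hits)
  inc <- numeric(N)
  tot <- sum(absW[hits])
  inc[hits] <- if (tot > 0) absW[hits] / tot else 1 / Nh
  inc[-hits] <- -1 / (N - Nh)
  rs <- cumsum(inc)
  i <- which.max(abs(rs))
  # symmetric tie-break: prefer the extreme of larger absolute value; on an
  # exact tie take the earlier position (which.max does)
  rs[i]
}

#' Preranked gene-set enrichment
#'
#' Classical running-sum enrichment on a ranked gene list: hit increments
#' weighted by `|score|^weight`, miss decrements `1/(N - Nh)`; the
#' enrichment score (ES) is the extreme deviation of the running sum. The
#' null is built from seeded gene-label permutations; NES is the ES divided
#' by the mean absolute same-signed null ES, and p is the same-signed
#' permutation tail probability. When a single set is tested, FDR equals p.
#' Intended for rankings such as `-log10(p) * sign(log2FC)` from a
#' differential-expression comparison; gene sets outside the size bounds
#' (defaults 15 and 500 after intersection) are skipped with the reason
#' recorded.
#'
#' @param ranked named numeric vector of finite ranking scores (any order;
#'   sorted decreasingly internally).
#' @param geneSet a [GeneModule] or character vector.
#' @param nPerm number of gene-label permutations.
#' @param weight exponent on `|score|` for hit increments.
#' @param seed integer seed.
#' @param minSize,maxSize set-size bounds after intersection.
#' @return one-row data.frame: set, size, ES, NES, p, FDR, direction,
#'   reason (NA when tested).
#' @export
prerankedEnrichment <- function(ranked, geneSet, nPerm = 1000L, weight = 1,
                                seed = 1L, minSize = 15L, maxSize = 500L) {
  if (is(geneSet, "GeneModule")) {
    setName <- moduleName(geneSet); geneSet <- moduleGenes(geneSet)
  } else setName <- "geneSet"
  if (any(!is.finite(ranked))) stop("ranking scores must be finite")
  ord <- order(ranked, decreasing = TRUE)
  sorted <- ranked[ord]
  N <- length(sorted)
  hits <- which(names(sorted) %in% geneSet)
  Nh <- length(hits)
  if (Nh < minSize || Nh > maxSize) {
    reason <- sprintf("set size %d outside [%d, %d]", Nh, minSize, maxSize)
    warning("skipping ", setName, ": ", reason)
    return(data.frame(set = setName, size = Nh, ES = NA_real_,
                      NES = NA_real_, p = NA_real_, FDR = NA_real_,
                      direction = NA_real_, reason = reason))
  }
  absW <- abs(sorted)^weight
  es <- .runningES(absW, hits, N)
  nullES <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
    .runningES(absW, sample.int(N, Nh), N), numeric(1)))
  same <- nullES[sign(nullES) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- if (length(same))
    (1 + sum(abs(same) >= abs(es))) / (1 + length(same)) else
    1 / (1 + nPerm)
  data.frame(set = setName, size = Nh, ES = es, NES = nes, p = p, FDR = p,
             direction = sign(es), reason = NA_character_)
}
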