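#' @import methods
#' @importFrom stats approx chisq.test coef cor cutree dist hclust kmeans
#'   loess lowess median nls p.adjust pchisq pnorm predict pt phyper
#'   quantile rbinom rexp rnbinom rnorm runif sd setNames t.test var
#'   wilcox.test complete.cases
#' @importFrom utils head read.csv read.delim write.csv packageVersion
NULL

#' GeneModule: a named gene set
#'
#' Container for a gene module (signature), e.g. the 41-gene
#' interferon-stimulated-gene (ISG) module used to define the inflamed
#' tumor-cell state. Genes are stored as unique symbols.
#'
#' @slot name single character, module name.
#' @slot genes character vector of unique, non-empty gene names.
#'
#' @examples
#' gm <- GeneModule("ISG", c("ISG15", "IFIT3", "OAS2"))
#' moduleGenes(gm)
#' @export
setClass("GeneModule",
  representation(name = "character", genes = "character"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("'name' must be a single non-empty string")
    if (length(object@genes) == 0L)
      return("module must contain at least one gene")
    if (anyDuplicated(object@genes))
      return("gene names must be unique")
    if (any(!nzchar(object@genes)))
      return("gene names must be non-empty")
    TRUE
  }
)

#' @param name module name.
#' @param genes character vector of gene names.
#' @rdname GeneModule-class
#' @export
GeneModule <- function(name, genes) {
  new("GeneModule", name = as.character(name), genes = as.character(genes))
}

#' ModuleScores: per-observation module activity scores
#'
#' Control-normalized gene-module scores, one per observation (single cell or
#' bulk sample), together with the metadata needed to reproduce them
#' (number of expression bins, control genes per module gene, seed, and
#' whether the mean or the sum reduction was used).
#'
#' @slot scores named numeric vector, one finite score per observation.
#' @slot kind `"cell"` or `"bulk"`.
#' @slot module module name the scores refer to.
#' @slot nBins,nCtrl,seed integer control-sampling metadata.
#' @slot statistic `"mean"` or `"sum"`.
#' @export
setClass("ModuleScores",
  representation(scores = "numeric", kind = "character", module = "character",
                 nBins = "integer", nCtrl = "integer", seed = "integer",
                 statistic = "character"),
  validity = function(object) {
    if (any(!is.finite(object@scores))) return("scores must be finite")
    if (!object@kind %in% c("cell", "bulk"))
      return("kind must be 'cell' or 'bulk'")
    if (!object@statistic %in% c("mean", "sum"))
      return("statistic must be 'mean' or 'sum'")
    TRUE
  }
)

#' PCAResult: truncated principal component decomposition
#'
#' @slot embeddings cells x components matrix of cell coordinates
#'   (left singular vectors scaled by singular values).
#' @slot loadings genes x components matrix with orthonormal columns; the
#'   sign of each component is fixed so its largest-magnitude loading is
#'   positive.
#' @slot explainedVariance per-component variance, non-increasing.
#' @export
setClass("PCAResult",
  representation(embeddings = "matrix", loadings = "matrix",
                 explainedVariance = "numeric"),
  validity = function(object) {
    k <- ncol(object@loadings)
    if (ncol(object@embeddings) != k)
      return("embeddings and loadings must have the same number of components")
    if (length(object@explainedVariance) != k)
      return("one explained-variance entry per component required")
    if (k > 1 && any(diff(object@explainedVariance) > 1e-8))
      return("explained variance must be non-increasing")
    ctp <- crossprod(object@loadings)
    if (max(abs(ctp - diag(k))) > 1e-4)
      return("loadings columns must be orthonormal")
    TRUE
  }
)

#' ClusterAssignment: a partition of cells into subpopulations
#'
#' @slot labels per-cell factor; levels are "0", "1", ... with cluster 0 the
#'   largest.
#' @slot k number of clusters.
#' @slot criterionTrace data.frame with columns `k` and `criterion`
#'   (mean silhouette for K-means, modularity for Louvain).
#' @slot method `"kmeans"` or `"graph"`.
#' @export
setClass("ClusterAssignment",
  representation(labels = "factor", k = "integer",
                 criterionTrace = "data.frame", method = "character"),
  validity = function(object) {
    if (nlevels(object@labels) != object@k)
      return("number of distinct labels must equal k")
    if (anyNA(object@labels)) return("every cell must be labeled")
    if (!object@method %in% c("kmeans", "graph"))
      return("method must be 'kmeans' or 'graph'")
    TRUE
  }
)

#' CNVProfile: smoothed expression-based copy-number profiles
#'
#' Chromosome-ordered moving averages of centered expression, an expression
#' proxy for large-scale copy-number variation. Rows are cells (hierarchical
#' clustering acts on them), columns are genes ordered by (chromosome, start).
#'
#' @slot profile cells x ordered-genes numeric matrix.
#' @slot geneOrder data.frame (gene, chrom, start) in column order of
#'   `profile`.
#' @slot window moving-average window in genes.
#' @slot clip clip bound applied to the centered expression before smoothing.
#' @slot recentered whether per-cell median re-centering was applied.
#' @export
setClass("CNVProfile",
  representation(profile = "matrix", geneOrder = "data.frame",
                 window = "integer", clip = "numeric", recentered = "logical"),
  validity = function(object) {
    if (ncol(object@profile) != nrow(object@geneOrder))
      return("geneOrder must describe the profile columns")
    go <- object@geneOrder
    for (ch in unique(go$chrom)) {
      s <- go$start[go$chrom == ch]
      if (is.unsorted(s)) return("gene order must be non-decreasing by start")
    }
    TRUE
  }
)

setMethod("show", "GeneModule", function(object) {
  cat("GeneModule", sQuote(object@name), "with", length(object@genes),
      "genes\n")
  cat(" ", paste(head(object@genes, 8), collapse = ", "),
      if (length(object@genes) > 8) "...", "\n")
})

setMethod("show", "ModuleScores", function(object) {
  cat("ModuleScores for module", sQuote(object@module),
      sprintf("(%d %s observations)\n", length(object@scores), object@kind))
  cat(sprintf("  statistic=%s, nBins=%d, nCtrl=%d, seed=%d\n",
              object@statistic, object@nBins, object@nCtrl, object@seed))
  print(summary(object@scores))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", object@k, "clusters by", object@method, "\n")
  print(table(object@labels))
})

setMethod("show", "CNVProfile", function(object) {
  cat("CNVProfile:", nrow(object@profile), "cells x",
      ncol(object@profile), "genes;",
      length(unique(object@geneOrder$chrom)), "chromosomes; window",
      object@window, "\n")
})

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", ncol(object@loadings), "components over",
      nrow(object@embeddings), "cells\n")
})
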