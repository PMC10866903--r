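#' Accessors for scInflamed classes
#'
#' Small accessor generics so slots are never reached into directly.
#'
#' @param x an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moduleName", function(x) standardGeneric("moduleName"))
#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("scoreKind", function(x) standardGeneric("scoreKind"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("criterionTrace", function(x) standardGeneric("criterionTrace"))
#' @rdname accessors
#' @export
setGeneric("cellEmbeddings", function(x) standardGeneric("cellEmbeddings"))
#' @rdname accessors
#' @export
setGeneric("geneLoadings", function(x) standardGeneric("geneLoadings"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("cnvMatrix", function(x) standardGeneric("cnvMatrix"))
#' @rdname accessors
#' @export
setGeneric("cnvGeneOrder", function(x) standardGeneric("cnvGeneOrder"))

#' @rdname accessors
#' @export
setMethod("moduleName", "GeneModule", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("scoreValues", "ModuleScores", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("scoreKind", "ModuleScores", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterAssignment", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("criterionTrace", "ClusterAssignment", function(x) x@criterionTrace)
#' @rdname accessors
#' @export
setMethod("cellEmbeddings", "PCAResult", function(x) x@embeddings)
#' @rdname accessors
#' @export
setMethod("geneLoadings", "PCAResult", function(x) x@loadings)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "PCAResult", function(x) x@explainedVariance)
#' @rdname accessors
#' @export
setMethod("cnvMatrix", "CNVProfile", function(x) x@profile)
#' @rdname accessors
#' @export
setMethod("cnvGeneOrder", "CNVProfile", function(x) x@geneOrder)
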