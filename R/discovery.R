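#' Principal component analysis of the scaled matrix
#'
#' Truncated singular value decomposition of the scaled expression matrix
#' (cells as observations, genes as variables). The decomposition is exact
#' up to numerical tolerance; the sign of each component is fixed by making
#' its largest-magnitude gene loading positive, so results are
#' deterministic.
#'
#' @param scaled genes x cells scaled matrix (from [scaleAndRegress()]).
#' @param nComponents number of components; must not exceed
#'   `min(cells, genes)`.
#' @return a [PCAResult-class] object.
#' @export
runPCA <- function(scaled, nComponents = 20L) {
  scaled <- .asMatrix(scaled)
  X <- t(scaled)                               # cells x genes
  k <- as.integer(nComponents)
  if (k < 1L || k > min(dim(X)))
    stop("nComponents must lie in [1, min(cells, genes)]")
  if (k <= 0.5 * min(dim(X)) && min(dim(X)) > 100L) {
    dec <- .withSeed(97L, irlba::irlba(X, nv = k, work = max(3L * k, k + 20L)))
    u <- dec$u; d <- dec$d; v <- dec$v
  } else {
    dec <- svd(X, nu = k, nv = k)
    u <- dec$u; d <- dec$d[seq_len(k)]; v <- dec$v
  }
  flip <- vapply(seq_len(k), function(i) {
    j <- which.max(abs(v[, i]))
    if (v[j, i] < 0) -1 else 1
  }, numeric(1))
  v <- sweep(v, 2, flip, "*")
  u <- sweep(u, 2, flip, "*")
  emb <- u * rep(d, each = nrow(u))
  dimnames(emb) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(v) <- list(colnames(X), paste0("PC", seq_len(k)))
  new("PCAResult", embeddings = emb, loadings = v,
      explainedVariance = d^2 / (nrow(X) - 1))
}

# squared correlation of each gene (row of `scaled`) with each embedding
# column; the jackstraw association statistic
.loadingStat <- function(scaled, emb) {
  gs <- scaled - rowMeans(scaled)
  gn <- sqrt(rowSums(gs^2))
  ec <- sweep(emb, 2, colMeans(emb))
  en <- sqrt(colSums(ec^2))
  r <- (gs %*% ec) / outer(gn, en)
  r[gn == 0, ] <- 0
  r^2
}

#' Jackstraw selection of significant principal components
#'
#' Builds a null distribution of gene-component association statistics by
#' repeatedly permuting a small random fraction of genes across cells and
#' re-computing the decomposition, so the null carries the same overfitting
#' as the observed statistics. Per component, observed squared
#' gene-embedding correlations are compared to the pooled null by a
#' one-sided Wilcoxon rank-sum test; components with p below `alpha` are
#' returned.
#'
#' @param scaled genes x cells scaled matrix.
#' @param nComponents components to assess.
#' @param nPerm number of permutation replicates (at least 20).
#' @param permFraction fraction of genes permuted per replicate; must give
#'   at least one gene.
#' @param alpha significance level per component.
#' @param seed integer seed.
#' @return integer vector of significant components (in order), with the
#'   per-component p-values in `attr(, "pValues")`.
#' @export
jackstrawPCs <- function(scaled, nComponents = 20L, nPerm = 100L,
                         permFraction = 0.01, alpha = 0.05, seed = 1L) {
  scaled <- .asMatrix(scaled)
  if (nPerm < 20L) stop("nPerm must be at least 20")
  p <- nrow(scaled)
  s <- floor(permFraction * p)
  if (s < 1L) stop("permFraction * nGenes must be at least 1")
  k <- as.integer(min(nComponents, min(dim(scaled)) - 1L))
  X <- t(scaled)                                   # cells x genes
  n <- nrow(X)
  useIrlba <- k <= 0.5 * min(dim(X)) && min(dim(X)) > 100L
  dec <- if (useIrlba)
    .withSeed(97L, irlba::irlba(X, nv = k, work = max(3L * k, k + 20L)))
  else { d0 <- svd(X, nu = k, nv = k); d0$d <- d0$d[seq_len(k)]; d0 }
  obs <- .loadingStat(scaled, dec$u * rep(dec$d, each = n))
  null <- .withSeed(seed, {
    out <- vector("list", nPerm)
    for (r in seq_len(nPerm)) {
      sel <- sample.int(p, s)
      Xp <- X
      for (g in sel) Xp[, g] <- Xp[sample.int(n), g]
      # null statistics tolerate a looser decomposition tolerance
      decP <- if (useIrlba) irlba::irlba(Xp, nv = k, v = dec$v, tol = 1e-3)
      else { dP <- svd(Xp, nu = k, nv = k); dP$d <- dP$d[seq_len(k)]; dP }
      out[[r]] <- .loadingStat(t(Xp[, sel, drop = FALSE]),
                               decP$u * rep(decP$d, each = n))
    }
    do.call(rbind, out)
  })
  pv <- vapply(seq_len(k), function(i)
    stats::wilcox.test(obs[, i], null[, i], alternative = "greater",
                       exact = FALSE)$p.value, numeric(1))
  res <- which(pv < alpha)
  attr(res, "pValues") <- pv
  res
}

.meanSilhouette <- function(labels, d) {
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

# relabel clusters by decreasing size; "0" is the largest
.relabelBySize <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(as.character(seq_along(tab) - 1L), names(tab))
  factor(map[as.character(labels)],
         levels = as.character(seq_along(tab) - 1L))
}

#' Silhouette-optimal clustering of cells
#'
#' Runs K-means over the significant-component embedding for each k in
#' `kRange` (with `nInit` seeded restarts) and picks the k maximizing the
#' mean silhouette width (Euclidean distance, subsampled to at most
#' `maxSilCells` cells). Clusters are relabeled by decreasing size so
#' cluster "0" is the largest. `method = "graph"` instead builds a shared
#' nearest-neighbor graph and scans Louvain resolutions, choosing the
#' modularity-optimal partition.
#'
#' @param emb cells x components embedding matrix.
#' @param kRange candidate cluster numbers (K-means).
#' @param nInit K-means restarts per k.
#' @param seed integer seed.
#' @param method `"kmeans"` (default) or `"graph"`.
#' @param maxSilCells silhouette subsample cap.
#' @param resolutions Louvain resolution grid (graph method).
#' @param knn neighbors for the graph method.
#' @return a [ClusterAssignment-class].
#' @export
clusterOptimal <- function(emb, kRange = 2:12, nInit = 10L, seed = 1L,
                           method = c("kmeans", "graph"),
                           maxSilCells = 5000L,
                           resolutions = c(0.2, 0.4, 0.6, 0.8, 1, 1.5, 2),
                           knn = 20L) {
  method <- match.arg(method)
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (all(apply(emb, 2, function(x) diff(range(x)) < 1e-12)))
    stop("no cluster structure: all embedding points are identical")
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) stop("kRange must intersect [2, nCells - 1]")
  .withSeed(seed, {
    sub <- if (n > maxSilCells) sort(sample.int(n, maxSilCells)) else
      seq_len(n)
    d <- dist(emb[sub, , drop = FALSE])
    if (method == "kmeans") {
      fits <- lapply(kRange, function(k)
        stats::kmeans(emb, centers = k, nstart = nInit, iter.max = 100L))
      crit <- vapply(seq_along(kRange), function(i)
        .meanSilhouette(fits[[i]]$cluster[sub], d), numeric(1))
      best <- which.max(crit)
      labels <- fits[[best]]$cluster
      trace <- data.frame(k = kRange, criterion = crit)
    } else {
      nn <- .knnIndices(emb, knn)
      g <- .snnGraph(nn)
      parts <- lapply(resolutions, function(res)
        igraph::cluster_louvain(g, resolution = res)$membership)
      crit <- vapply(parts, function(m)
        igraph::modularity(g, m), numeric(1))
      best <- which.max(crit)
      labels <- parts[[best]]
      trace <- data.frame(k = vapply(parts, function(m)
        length(unique(m)), integer(1)), criterion = crit,
        resolution = resolutions)
    }
    labels <- .relabelBySize(labels)
    names(labels) <- rownames(emb)
    new("ClusterAssignment", labels = labels, k = nlevels(labels),
        criterionTrace = trace, method = method)
  })
}

.knnIndices <- function(emb, k) {
  n <- nrow(emb)
  k <- min(k, n - 1L)
  d2 <- as.matrix(dist(emb))
  t(vapply(seq_len(n), function(i) order(d2[i, ])[2:(k + 1L)], integer(k)))
}

.snnGraph <- function(nn) {
  n <- nrow(nn); k <- ncol(nn)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  # shared-neighbor (Jaccard) weights on the union of directed kNN edges
  adj <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  pair <- unique(cbind(pmin(from, to), pmax(from, to)))
  w <- shared[pair] / (2 * k - shared[pair])
  keep <- w > 1 / 15
  igraph::graph_from_data_frame(
    data.frame(from = pair[keep, 1], to = pair[keep, 2], weight = w[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' One-vs-rest Wilcoxon marker genes
#'
#' For each cluster, genes passing the expression-fraction and fold-change
#' prefilters are tested against all other cells by a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction). P-values are
#' Bonferroni-adjusted over the genes tested within the cluster.
#' `log2FC` is `log2(mean(expm1(in)) + 1) - log2(mean(expm1(out)) + 1)`
#' on the log-normalized data.
#'
#' @param sce SingleCellExperiment with `lognorm`, or a lognorm matrix.
#' @param clusters a [ClusterAssignment-class] or per-cell factor.
#' @param minPct minimum expression fraction (in either group) to test.
#' @param minAbsLog2FC minimum absolute log2 fold-change to test.
#' @return data.frame with columns cluster, gene, log2FC, p, pAdj, pctIn,
#'   pctOut.
#' @export
markerGenesWilcoxon <- function(sce, clusters, minPct = 0.1,
                                minAbsLog2FC = 0.25) {
  expr <- .asMatrix(sce, if (is(sce, "SummarizedExperiment")) "lognorm")
  labels <- if (is(clusters, "ClusterAssignment")) clusterLabels(clusters)
    else factor(clusters)
  if (length(labels) != ncol(expr))
    stop("one cluster label per cell required")
  small <- names(which(table(labels) < 3))
  if (length(small))
    stop("cluster(s) with fewer than 3 cells: ",
         paste(small, collapse = ", "))
  N <- ncol(expr)
  ranks <- t(apply(expr, 1, rank))             # global ranks, one-vs-rest
  tieTerm <- apply(expr, 1, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  pos <- expr > 0
  out <- list()
  for (cl in levels(labels)) {
    inC <- labels == cl
    n1 <- sum(inC); n2 <- N - n1
    meanIn <- rowMeans(expm1(expr[, inC, drop = FALSE]))
    meanOut <- rowMeans(expm1(expr[, !inC, drop = FALSE]))
    lfc <- log2(meanIn + 1) - log2(meanOut + 1)
    pctIn <- rowMeans(pos[, inC, drop = FALSE])
    pctOut <- rowMeans(pos[, !inC, drop = FALSE])
    keep <- pmax(pctIn, pctOut) >= minPct & abs(lfc) >= minAbsLog2FC
    if (!any(keep)) next
    W <- rowSums(ranks[keep, inC, drop = FALSE]) - n1 * (n1 + 1) / 2
    vW <- (n1 * n2 / 12) *
      ((N + 1) - tieTerm[keep] / (N * (N - 1)))
    z <- (W - n1 * n2 / 2) / sqrt(pmax(vW, .Machine$double.eps))
    p <- 2 * stats::pnorm(-abs(z))
    out[[cl]] <- data.frame(cluster = cl, gene = rownames(expr)[keep],
                            log2FC = lfc[keep], p = p,
                            pAdj = pmin(p * sum(keep), 1),
                            pctIn = pctIn[keep], pctOut = pctOut[keep],
                            W = W, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Top marker genes per cluster
#'
#' Sorts each cluster's markers by adjusted p-value, breaking ties by larger
#' absolute log2 fold-change (then gene name), and returns the top `n`.
#'
#' @param table marker table from [markerGenesWilcoxon()].
#' @param n genes per cluster (default 50).
#' @return named list of character vectors, one per cluster.
#' @export
topMarkers <- function(table, n = 50L) {
  if (is.null(table) || !nrow(table)) stop("marker table is empty")
  lapply(split(table, table$cluster), function(df) {
    df <- df[order(df$pAdj, -abs(df$log2FC), df$gene), ]
    head(df$gene, n)
  })
}
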