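#' Reference-centered relative expression
#'
#' Subtracts the reference-cell mean from each gene and clips the result,
#' the first step of expression-based CNV inference. By default the
#' reference is all cells (the appropriate choice for cell-line data with
#' no normal cells); an explicit normal-cell subset can be supplied.
#'
#' @param expr genes x cells log-normalized matrix (or SingleCellExperiment
#'   with a `lognorm` assay).
#' @param reference `"all"`, or a character/integer/logical selection of
#'   reference cells.
#' @param clip symmetric clip bound on the centered values (default 3).
#' @return centered, clipped genes x cells matrix.
#' @export
relativeExpression <- function(expr, reference = "all", clip = 3) {
  expr <- .asMatrix(expr, if (is(expr, "SummarizedExperiment")) "lognorm")
  if (identical(reference, "all")) {
    ref <- seq_len(ncol(expr))
  } else if (is.character(reference)) {
    ref <- which(colnames(expr) %in% reference)
  } else if (is.logical(reference)) {
    ref <- which(reference)
  } else {
    ref <- intersect(as.integer(reference), seq_len(ncol(expr)))
  }
  if (!length(ref)) stop("reference cells not found in the matrix")
  centered <- expr - rowMeans(expr[, ref, drop = FALSE])
  pmin(pmax(centered, -clip), clip)
}

# truncated moving average along columns of a cells x genes block
.movingAverage <- function(block, h) {
  n <- ncol(block)
  cs <- cbind(0, t(apply(block, 1, cumsum)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE])
  sweep(sm, 2, hi - lo + 1L, "/")
}

#' Chromosome-ordered moving-average CNV profile
#'
#' Genes are sorted by (chromosome, start) in karyotype order and a centered
#' moving average of half-width `floor(window/2)` is applied per cell within
#' each chromosome; the window is truncated at chromosome boundaries (never
#' crossing them). Optionally each cell's profile is re-centered by
#' subtracting its median smoothed value. Unmapped genes are dropped with a
#' warning.
#'
#' @param centered genes x cells centered matrix from
#'   [relativeExpression()].
#' @param geneMap data.frame with columns `gene`, `chrom`, `start`
#'   (1-based coordinates; see [readGeneMap()]).
#' @param window moving-average window in genes (default 100).
#' @param recenter subtract each cell's median smoothed value
#'   (default TRUE).
#' @param clip clip bound recorded in the profile metadata.
#' @return a [CNVProfile-class] (cells x ordered genes).
#' @export
smoothCNV <- function(centered, geneMap, window = 100L, recenter = TRUE,
                      clip = 3) {
  if (window < 1L) stop("window must be at least 1")
  stopifnot(all(c("gene", "chrom", "start") %in% names(geneMap)))
  mapped <- intersect(rownames(centered), geneMap$gene)
  unmapped <- setdiff(rownames(centered), geneMap$gene)
  if (!length(mapped)) stop("no gene of the matrix is in the gene map")
  if (length(unmapped))
    warning(length(unmapped), " unmapped gene(s) dropped")
  gm <- geneMap[match(mapped, geneMap$gene), ]
  ord <- order(.chromRank(gm$chrom), gm$start, gm$gene)
  gm <- gm[ord, ]
  X <- t(as.matrix(centered[gm$gene, , drop = FALSE]))  # cells x genes
  h <- as.integer(floor(window / 2))
  sm <- X
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    sm[, idx] <- .movingAverage(X[, idx, drop = FALSE], h)
  }
  if (recenter) sm <- sm - apply(sm, 1, stats::median)
  new("CNVProfile", profile = sm,
      geneOrder = data.frame(gene = gm$gene, chrom = gm$chrom,
                             start = gm$start, row.names = NULL),
      window = as.integer(window), clip = clip, recentered = recenter)
}

#' Hierarchical subclone clustering of CNV profiles
#'
#' Ward-linkage hierarchical clustering of Euclidean distances between
#' smoothed per-cell profiles. The dendrogram is cut at the k in
#' `[2, maxK]` maximizing the mean silhouette; if every candidate's mean
#' silhouette is below `minSil` (default 0.1), a single subclone (k = 1) is
#' reported, covering samples with no CNV structure.
#'
#' @param profile a [CNVProfile-class].
#' @param maxK maximum number of subclones.
#' @param minSil silhouette floor below which k = 1 is declared.
#' @return list with `labels` (per-cell factor, relabeled by decreasing
#'   size), `k`, `silhouette` (data.frame k/criterion), `hclust`, and
#'   `newick` (dendrogram as a Newick string).
#' @export
clusterSubclones <- function(profile, maxK = 8L, minSil = 0.1) {
  stopifnot(is(profile, "CNVProfile"))
  M <- cnvMatrix(profile)
  n <- nrow(M)
  if (n < 2L) stop("at least 2 cells required")
  d <- dist(M)
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:min(maxK, n - 1)
  crit <- vapply(ks, function(k)
    .meanSilhouette(stats::cutree(hc, k), d), numeric(1))
  if (all(crit < minSil)) {
    labels <- factor(rep("0", n))
    k <- 1L
  } else {
    k <- ks[which.max(crit)]
    labels <- .relabelBySize(stats::cutree(hc, k))
  }
  names(labels) <- rownames(M)
  phy <- ape::as.phylo(hc)
  list(labels = labels, k = k,
       silhouette = data.frame(k = ks, criterion = crit),
       hclust = hc, newick = ape::write.tree(phy))
}

#' Association between a cell state and CNV subclones
#'
#' k x 2 contingency table of subclone membership against a per-cell binary
#' state, tested by chi-square; when any expected count is below 5 an exact
#' permutation test on the chi-square statistic is used instead. With a
#' single subclone the association is undefined and p = 1 is returned with
#' a flag.
#'
#' @param subclones per-cell subclone labels.
#' @param state per-cell logical (e.g. inflamed calls).
#' @param nPerm permutations for the exact fallback.
#' @param seed integer seed.
#' @return list with `table`, `statistic`, `p`, `method`,
#'   `singleSubclone` flag.
#' @export
stateSubcloneAssociation <- function(subclones, state, nPerm = 2000L,
                                     seed = 1L) {
  if (length(subclones) != length(state))
    stop("subclones and state must have the same length")
  subclones <- factor(subclones)
  state <- factor(as.logical(state), levels = c(FALSE, TRUE))
  tab <- table(subclone = subclones, state = state)
  if (nlevels(subclones) < 2L)
    return(list(table = tab, statistic = NA_real_, p = 1,
                method = "undefined", singleSubclone = TRUE))
  suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    obs <- ct$statistic
    stateVec <- as.logical(state)
    perm <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
      t2 <- table(subclones, sample(stateVec))
      suppressWarnings(stats::chisq.test(t2, correct = FALSE)$statistic)
    }, numeric(1)))
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + nPerm)
    list(table = tab, statistic = unname(obs), p = p,
         method = "permutation", singleSubclone = FALSE)
  } else {
    list(table = tab, statistic = unname(ct$statistic),
         p = ct$p.value, method = "chi-square", singleSubclone = FALSE)
  }
}
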