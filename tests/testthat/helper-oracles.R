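# independent oracles used by the tests; each reimplements the checked
# quantity from first principles, never through the package's code paths

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

countsOf <- function(sce) as.matrix(assay(sce, "counts"))

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# area under the ROC curve of `scores` for binary `labels`
auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force sequential QC filter: gene detection filter, then cell
# gene-count bounds, then mitochondrial fraction
bruteForceFilter <- function(m, minCells, minGenes, maxGenes, maxMito,
                             prefix = "MT-") {
  keepG <- apply(m, 1, function(x) sum(x > 0)) >= minCells
  m <- m[keepG, , drop = FALSE]
  ng <- apply(m, 2, function(x) sum(x > 0))
  m <- m[, ng >= minGenes & ng <= maxGenes, drop = FALSE]
  mito <- grepl(paste0("^", prefix), rownames(m))
  if (any(mito)) {
    fr <- apply(m, 2, function(x) sum(x[mito]) / max(sum(x), 1))
    m <- m[, fr < maxMito, drop = FALSE]
  }
  m
}

# exact two-sample rank-sum: enumerate every assignment of the pooled
# values to the first group; returns the W statistic and exact two-sided p
exactRankSum <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  Wobs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  r <- rank(pool)
  Wall <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (N - n1) / 2
  p <- mean(abs(Wall - mu) >= abs(Wobs - mu) - 1e-12)
  list(W = Wobs, p = p)
}

# two-group log-rank from the defining O-E / V sums over event times
handLogrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# product-limit estimator written directly from its definition
handKM <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- numeric(0)
  for (t in ts) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- c(out, s)
  }
  data.frame(time = ts, survival = out)
}

# classical running-sum enrichment score, independent implementation
handES <- function(sortedScores, inSet, weight = 1) {
  N <- length(sortedScores)
  w <- abs(sortedScores)^weight
  inc <- ifelse(inSet, w / sum(w[inSet]), -1 / (N - sum(inSet)))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# OLS residuals through the normal equations
handResiduals <- function(y, X) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% b)
}

# lognorm matrix from a small simulated experiment
lognormOf <- function(sce) as.matrix(assay(normalizeLog(sce), "lognorm"))

smallSim <- function(nCells = 200, nGenes = 150, seed = 1, ...) {
  simulateScCounts(simConfig(nCells = nCells, nGenes = nGenes, seed = seed,
                             ...))
}
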