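test_that("PCA is an exact truncated decomposition with fixed signs", {
  set.seed(1)
  X <- matrix(rnorm(60 * 40), nrow = 40)          # genes x cells
  p <- runPCA(X, 10)
  sv <- svd(t(X))
  expect_equal(sqrt(explainedVariance(p) * (60 - 1)), sv$d[1:10],
               tolerance = 1e-8)
  L <- geneLoadings(p)
  expect_equal(unname(crossprod(L)), diag(10), tolerance = 1e-8)
  for (i in 1:10) expect_gt(L[which.max(abs(L[, i])), i], 0)
  # completeness: full-rank reconstruction
  pf <- runPCA(X, 40)
  expect_lt(max(abs(cellEmbeddings(pf) %*% t(geneLoadings(pf)) - t(X))),
            1e-8)
  # rank-1 matrix concentrates all variance on one component
  r1 <- runPCA(outer(rnorm(30), rnorm(50)), 5)
  ev <- explainedVariance(r1)
  expect_gt(ev[1], 1e-6)
  expect_lt(max(ev[-1]) / ev[1], 1e-10)
  expect_error(runPCA(X, 100), "nComponents")
})

test_that("jackstraw flags a planted factor and respects alpha", {
  set.seed(2)
  factorLoad <- rnorm(80)
  emb <- rnorm(200)
  X <- outer(factorLoad, emb) * 1.5 + matrix(rnorm(80 * 200), 80)
  js <- jackstrawPCs(X, nComponents = 8, nPerm = 30, permFraction = 0.05,
                     seed = 1)
  expect_true(1 %in% js)
  js0 <- jackstrawPCs(X, nComponents = 8, nPerm = 30, permFraction = 0.05,
                      alpha = 0, seed = 1)
  expect_length(js0, 0)
  expect_error(jackstrawPCs(X, nPerm = 30, permFraction = 1e-4), "at least")
  expect_error(jackstrawPCs(X, nPerm = 5), "nPerm")
})

test_that("jackstraw is calibrated on pure noise", {
  flagged <- 0L; tested <- 0L
  for (s in 1:10) {
    set.seed(s + 40)
    X <- matrix(rnorm(80 * 150), nrow = 80)
    js <- jackstrawPCs(X, nComponents = 8, nPerm = 25, permFraction = 0.05,
                       seed = s)
    flagged <- flagged + length(js)
    tested <- tested + 8L
  }
  # expected alpha * tested = 4; reject only gross miscalibration
  expect_lte(flagged, qbinom(0.999, tested, 0.05))
})

test_that("silhouette-optimal K-means recovers well-separated blobs", {
  set.seed(3)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  truth <- rep(1:3, c(80, 60, 40))
  emb <- centers[truth, ] + matrix(rnorm(360, sd = 0.5), ncol = 2)
  cl <- clusterOptimal(emb, kRange = 2:6, seed = 1)
  expect_identical(nClusters(cl), 3L)
  expect_equal(ari(clusterLabels(cl), truth), 1)
  # cluster "0" is the largest
  expect_identical(unname(which.max(table(clusterLabels(cl)))), 1L)
  expect_identical(as.character(clusterLabels(cl)[1]), "0")
  tr <- criterionTrace(cl)
  expect_identical(tr$k, 2:6)
})

test_that("clustering is invariant to duplication and cell order", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(100, sd = 0.4), ncol = 2),
               matrix(rnorm(100, sd = 0.4) + 6, ncol = 2))
  cl1 <- clusterOptimal(emb, kRange = 2:5, seed = 1)
  dup <- clusterOptimal(rbind(emb, emb), kRange = 2:5, seed = 1)
  expect_identical(nClusters(dup), nClusters(cl1))
  expect_equal(ari(clusterLabels(dup)[1:100],
                   clusterLabels(dup)[101:200]), 1)
  perm <- sample(nrow(emb))
  cl2 <- clusterOptimal(emb[perm, ], kRange = 2:5, seed = 1)
  expect_equal(ari(clusterLabels(cl1)[perm], clusterLabels(cl2)), 1)
  expect_error(clusterOptimal(matrix(1, 30, 2), kRange = 2:5),
               "no cluster structure")
})

test_that("the chosen k tracks 5-7 planted states within one", {
  hits <- 0L
  for (s in 1:6) {
    set.seed(s + 10)
    kTrue <- sample(5:7, 1)
    centers <- matrix(rnorm(kTrue * 6, sd = 4), nrow = kTrue)
    truth <- sample(rep_len(seq_len(kTrue), 420))
    emb <- centers[truth, ] + matrix(rnorm(420 * 6, sd = 0.7), ncol = 6)
    cl <- clusterOptimal(emb, kRange = 2:10, seed = s)
    if (abs(nClusters(cl) - kTrue) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("graph clustering provides the same interface", {
  set.seed(5)
  emb <- rbind(matrix(rnorm(160, sd = 0.5), ncol = 2),
               matrix(rnorm(160, sd = 0.5) + 7, ncol = 2))
  cl <- clusterOptimal(emb, method = "graph", seed = 1)
  expect_s4_class(cl, "ClusterAssignment")
  truth <- rep(1:2, each = 80)
  expect_gte(nClusters(cl), 2L)
  # every community is pure with respect to the two blobs
  purity <- tapply(truth, clusterLabels(cl),
                   function(x) max(table(x)) / length(x))
  expect_true(all(purity == 1))
})

test_that("marker statistics equal the rank-sum statistic", {
  set.seed(6)
  x <- c(1.2, 3.4, 0.3, 5.5, 2.2, 0.1, 4.4, 1.1, 2.9, 3.3, 0.7, 1.9)
  grp <- factor(rep(c("0", "1"), each = 6))
  m <- matrix(x, nrow = 1, dimnames = list("g1", sprintf("c%02d", 1:12)))
  tab <- markerGenesWilcoxon(m, grp, minPct = 0, minAbsLog2FC = 0)
  w0 <- wilcox.test(x[1:6], x[7:12])$statistic
  expect_equal(tab$W[tab$cluster == "0"], unname(w0))
  oracle <- exactRankSum(x[1:6], x[7:12])
  expect_equal(tab$W[tab$cluster == "0"], oracle$W)
})

test_that("an exclusively expressed gene is the top marker", {
  set.seed(7)
  m <- matrix(rpois(40 * 60, 3) + 0.0, nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  m <- log1p(m)
  grp <- factor(rep(c("0", "1"), c(45, 15)))
  m["g05", ] <- 0
  m["g05", grp == "1"] <- log1p(8)
  tab <- markerGenesWilcoxon(m, grp)
  t1 <- tab[tab$cluster == "1", ]
  expect_identical(t1$gene[which.min(t1$p)], "g05")
  expect_gt(t1$log2FC[t1$gene == "g05"], 0)
  expect_error(markerGenesWilcoxon(m, factor(rep(c("a", "b"),
                                                 c(58, 2)))), "b")
})

test_that("marker p-values are calibrated and rank-invariant", {
  set.seed(8)
  m <- matrix(rnorm(600 * 120), nrow = 600,
              dimnames = list(sprintf("g%03d", 1:600), NULL))
  grp <- factor(rep(c("0", "1"), each = 60))
  tab <- markerGenesWilcoxon(m, grp, minPct = 0, minAbsLog2FC = 0)
  p0 <- tab$p[tab$cluster == "0"]
  expect_gt(suppressWarnings(ks.test(p0, "punif")$p.value), 0.01)
  # monotone transform of expression leaves p unchanged
  tab2 <- markerGenesWilcoxon(exp(m / 3), grp, minPct = 0,
                              minAbsLog2FC = 0)
  expect_equal(tab$p[tab$cluster == "0"], tab2$p[tab2$cluster == "0"],
               tolerance = 1e-12)
})

test_that("top markers sort by adjusted p with fold-change tie-break", {
  tab <- data.frame(cluster = "0",
                    gene = c("a", "b", "c", "d"),
                    log2FC = c(1, -2, 0.5, 3),
                    p = c(0.01, 0.01, 0.2, 0.001),
                    pAdj = c(0.04, 0.04, 0.8, 0.004),
                    pctIn = 1, pctOut = 0)
  top <- topMarkers(tab, n = 3)[["0"]]
  expect_identical(top, c("d", "b", "a"))
  expect_identical(length(topMarkers(tab, n = 50)[["0"]]), 4L)
  set.seed(9)
  rnd <- data.frame(cluster = "0", gene = sprintf("g%02d", 1:30),
                    log2FC = rnorm(30), p = runif(30),
                    pAdj = runif(30), pctIn = 1, pctOut = 0)
  top2 <- topMarkers(rnd, n = 30)[["0"]]
  oracle <- rnd$gene[order(rnd$pAdj, -abs(rnd$log2FC), rnd$gene)]
  expect_identical(top2, oracle)
  expect_error(topMarkers(rnd[0, ]), "empty")
})
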