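geneMapFor <- function(genes, chrom = "1") {
  data.frame(gene = genes, chrom = chrom, start = seq_along(genes))
}

test_that("relative expression centers on the reference and clips", {
  m <- matrix(c(2, 2, 2, 10, 1, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  out <- relativeExpression(m, clip = 3)
  expect_true(all(out["g1", ] == 0))
  expect_equal(unname(out["g2", ]), c(3, -3, -1))   # 10-5 clipped to 3
  set.seed(1)
  r <- matrix(rnorm(50 * 20), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  expect_equal(relativeExpression(r, clip = 1e6), r - rowMeans(r),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(relativeExpression(r, reference = "nope"), "reference")
})

test_that("the truncated moving average matches the hand computation", {
  m <- matrix(c(0, 0, 3, 0, 0), nrow = 5, ncol = 2,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  pr <- smoothCNV(m, geneMapFor(paste0("g", 1:5)), window = 3,
                  recenter = FALSE)
  expect_equal(unname(cnvMatrix(pr)[1, ]), c(0, 1, 1, 1, 0))
  const <- matrix(2, nrow = 5, ncol = 3,
                  dimnames = list(paste0("g", 1:5), NULL))
  expect_true(all(cnvMatrix(smoothCNV(const, geneMapFor(paste0("g", 1:5)),
                                      window = 3, recenter = FALSE)) == 2))
  expect_error(smoothCNV(m, geneMapFor(paste0("g", 1:5)), window = 0),
               "window")
  expect_warning(smoothCNV(rbind(m, zz = 0), geneMapFor(paste0("g", 1:5)),
                           window = 3), "unmapped")
})

test_that("smoothing never crosses chromosome boundaries", {
  genes <- paste0("g", 1:10)
  gmap <- data.frame(gene = genes, chrom = rep(c("1", "2"), each = 5),
                     start = rep(1:5, 2))
  m <- matrix(rep(c(1, -1), each = 5), nrow = 10, ncol = 2,
              dimnames = list(genes, NULL))
  sm <- cnvMatrix(smoothCNV(m, gmap, window = 5, recenter = FALSE))
  expect_true(all(sm[, 1:5] == 1))
  expect_true(all(sm[, 6:10] == -1))
})

test_that("smoothing is linear before re-centering", {
  set.seed(2)
  genes <- sprintf("g%02d", 1:30)
  gmap <- data.frame(gene = genes, chrom = rep(c("1", "2"), each = 15),
                     start = rep(1:15, 2))
  A <- matrix(rnorm(30 * 8), nrow = 30, dimnames = list(genes, NULL))
  B <- matrix(rnorm(30 * 8), nrow = 30, dimnames = list(genes, NULL))
  sAB <- cnvMatrix(smoothCNV(A + B, gmap, window = 7, recenter = FALSE))
  sA <- cnvMatrix(smoothCNV(A, gmap, window = 7, recenter = FALSE))
  sB <- cnvMatrix(smoothCNV(B, gmap, window = 7, recenter = FALSE))
  expect_equal(sAB, sA + sB, tolerance = 1e-12)
})

test_that("cell permutation permutes profile rows and nothing else", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:20)
  m <- matrix(rnorm(20 * 10), nrow = 20,
              dimnames = list(genes, sprintf("c%02d", 1:10)))
  pr <- smoothCNV(m, geneMapFor(genes), window = 5)
  perm <- sample(10)
  pr2 <- smoothCNV(m[, perm], geneMapFor(genes), window = 5)
  expect_equal(cnvMatrix(pr2), cnvMatrix(pr)[perm, ], tolerance = 1e-12)
  expect_identical(cnvGeneOrder(pr2), cnvGeneOrder(pr))
})

test_that("gene ordering follows karyotype order", {
  genes <- c("gA", "gB", "gC", "gD")
  gmap <- data.frame(gene = genes, chrom = c("X", "2", "10", "2"),
                     start = c(5, 9, 1, 2))
  m <- matrix(0, nrow = 4, ncol = 2, dimnames = list(genes, NULL))
  pr <- smoothCNV(m, gmap, window = 1)
  expect_identical(cnvGeneOrder(pr)$gene, c("gD", "gB", "gC", "gA"))
})

test_that("planted subclones are recovered by hierarchical clustering", {
  cfg <- simConfig(nCells = 160, nGenes = 600, seed = 4,
                   inflamedFraction = 0, moduleLog2FC = 0,
                   nChromosomes = 6,
                   subclones = list(list(fraction = 0.5, chrom = "2",
                                         copyRatio = 1.5)))
  sce <- normalizeLog(simulateScCounts(cfg))
  gmap <- data.frame(gene = rownames(sce),
                     chrom = rowData(sce)$chrom, start = rowData(sce)$pos)
  pr <- smoothCNV(relativeExpression(sce), gmap, window = 100)
  sub <- clusterSubclones(pr, maxK = 6)
  truth <- colData(sce)$subclone
  expect_gte(ari(sub$labels, truth), 0.9)
  expect_match(sub$newick, "^\\(")
  # duplicated cells always co-assigned
  m2 <- cnvMatrix(pr)
  pr2 <- methods::new("CNVProfile", profile = rbind(m2, m2[1:5, ]),
                      geneOrder = cnvGeneOrder(pr), window = 100L,
                      clip = 3, recentered = TRUE)
  sub2 <- clusterSubclones(pr2, maxK = 6)
  expect_identical(as.character(sub2$labels[1:5]),
                   as.character(sub2$labels[161:165]))
})

test_that("a CNV-free population collapses to a single subclone", {
  # with >= 2x the window of genes per chromosome (the realistic regime),
  # smoothed noise profiles sit below the k = 1 silhouette floor
  k1 <- 0L
  for (s in 1:5) {
    cfg <- simConfig(nCells = 300, nGenes = 600, seed = s,
                     inflamedFraction = 0, moduleLog2FC = 0,
                     nChromosomes = 3, subclones = list())
    sce <- normalizeLog(simulateScCounts(cfg))
    gmap <- data.frame(gene = rownames(sce), chrom = rowData(sce)$chrom,
                       start = rowData(sce)$pos)
    pr <- smoothCNV(relativeExpression(sce), gmap, window = 100)
    if (clusterSubclones(pr, maxK = 5)$k == 1L) k1 <- k1 + 1L
  }
  expect_gte(k1, 4L)
})

test_that("state-subclone association matches hand-computed chi-square", {
  sub <- rep(c("s1", "s2"), each = 10)
  state <- rep(c(TRUE, FALSE), each = 10)
  res <- stateSubcloneAssociation(sub, state)
  expect_equal(unname(res$statistic), 20, tolerance = 1e-10)
  # perfectly nested state in a small cohort: exact permutation p
  sub2 <- rep(c("a", "b", "c"), each = 6)
  state2 <- sub2 == "a"
  res2 <- stateSubcloneAssociation(sub2, state2, nPerm = 500, seed = 1)
  expect_identical(res2$method, "permutation")
  expect_lte(res2$p, 3 / 501)
  one <- stateSubcloneAssociation(rep("s1", 10), rep(c(TRUE, FALSE), 5))
  expect_identical(one$p, 1)
  expect_true(one$singleSubclone)
  expect_error(stateSubcloneAssociation(sub, state[1:5]), "length")
})

test_that("independent state and subclone labels are rarely flagged", {
  rej <- 0L
  for (s in 1:30) {
    set.seed(s)
    sub <- sample(rep(c("s1", "s2", "s3"), each = 40))
    state <- sample(c(rep(TRUE, 30), rep(FALSE, 90)))
    if (stateSubcloneAssociation(sub, state, seed = s)$p < 0.05)
      rej <- rej + 1L
  }
  expect_lte(rej, qbinom(0.999, 30, 0.05))
})
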