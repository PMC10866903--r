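test_that("module score is exactly zero on a constant matrix", {
  m <- matrix(3, nrow = 60, ncol = 25,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  sc <- moduleScore(m, GeneModule("m", c("g01", "g10", "g30")), nBins = 10,
                    seed = 1)
  expect_true(all(scoreValues(sc) == 0))
})

test_that("a single-gene module scores against its bin mean", {
  set.seed(1)
  m <- matrix(rep(seq(0.1, 5, length.out = 50), 20), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  m <- m + matrix(rnorm(50 * 20, sd = 0.01), 50)
  sc <- moduleScore(m, GeneModule("solo", "g10"), nBins = 25, nCtrl = 300,
                    seed = 2)
  binMates <- c("g09", "g10")        # 25 equal bins of 2 over sorted means
  expect_equal(unname(scoreValues(sc)),
               unname(m["g10", ] - colMeans(m[binMates, ])),
               tolerance = 1e-12)
})

test_that("control subtraction cancels per-observation constants", {
  set.seed(2)
  m <- matrix(rnorm(80 * 30), nrow = 80,
              dimnames = list(sprintf("g%02d", 1:80), NULL))
  gm <- GeneModule("m", c("g03", "g22", "g61"))
  a <- scoreValues(moduleScore(m, gm, nBins = 8, seed = 5))
  shifted <- m + rep(rnorm(30), each = 80)
  b <- scoreValues(moduleScore(shifted, gm, nBins = 8, seed = 5))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("module scoring validates its inputs", {
  m <- matrix(1:20, nrow = 5, dimnames = list(paste0("g", 1:5), NULL))
  suppressWarnings(
    expect_error(moduleScore(m, GeneModule("m", "absent")),
                 "no module gene"))
  expect_warning(moduleScore(m, GeneModule("m", c("g1", "zz")), nBins = 2,
                             seed = 1), "absent")
  expect_error(moduleScore(m, GeneModule("m", "g1"), nBins = 50), "nBins")
  sum1 <- moduleScore(m, GeneModule("m", c("g1", "g3")), nBins = 2,
                      seed = 1, statistic = "sum")
  mean1 <- moduleScore(m, GeneModule("m", c("g1", "g3")), nBins = 2,
                       seed = 1, statistic = "mean")
  expect_equal(scoreValues(sum1), scoreValues(mean1) * 2)
})

test_that("bulk scores are stable under duplication and track the latent", {
  set.seed(3)
  gm <- GeneModule("ISG", sprintf("isg%02d", 1:20))
  sim <- simulateBulkPanel(50, 3, gm, plantedCompoundIndex = 1,
                           plantedR = 0, nGenes = 60, seed = 4)
  one <- bulkModuleScore(sim$expr[, 1, drop = FALSE], gm, nBins = 10,
                         seed = 1)
  expect_true(is.finite(scoreValues(one)))
  dup <- bulkModuleScore(cbind(sim$expr, sim$expr), gm, seed = 1)
  v <- scoreValues(dup)
  expect_equal(v[1:50], setNames(v[51:100], names(v[1:50])))
  sc <- bulkModuleScore(sim$expr, gm, seed = 1)
  expect_gte(cor(sim$groundTruth$latent, scoreValues(sc),
                 method = "spearman"), 0.9)
})

test_that("the normal-maximum cutoff gives order-statistic behavior", {
  set.seed(4)
  fr <- vapply(1:200, function(i) {
    normal <- rnorm(99)
    tumor <- rnorm(60)
    classifyInflamed(tumor, normal)$fractions[[1]]
  }, numeric(1))
  expect_gt(mean(fr), 0.004)         # expectation 1/100
  expect_lt(mean(fr), 0.022)
})

test_that("inflamed calling flags exactly the enriched sample", {
  set.seed(5)
  normal <- rnorm(300)
  tumor <- c(rnorm(200), ifelse(seq_len(200) <= 80, rnorm(200) + 6,
                                rnorm(200)))
  ids <- rep(c("sampleA", "sampleB"), each = 200)
  res <- classifyInflamed(tumor, normal, sampleIds = ids)
  expect_true(res$flagged[["sampleB"]])
  expect_false(res$flagged[["sampleA"]])
  low <- classifyInflamed(rnorm(100) - 50, normal)
  expect_identical(sum(low$inflamed), 0L)
  expect_false(any(low$flagged))
  expect_error(classifyInflamed(tumor, numeric(0)), "empty normal")
})

test_that("raising the cutoff never increases an inflamed fraction", {
  set.seed(6)
  normal <- rnorm(150); tumor <- rnorm(400) + 1
  qs <- c(0.8, 0.9, 0.95, 1)
  fr <- vapply(qs, function(q)
    classifyInflamed(tumor, normal, cutoffQuantile = q)$fractions[[1]],
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("hypergeometric ORA matches closed forms and pmf summation", {
  res <- oraHypergeometric(letters[1:5], letters[1:5], letters[1:20])
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(res$overlap, 5L)
  near1 <- oraHypergeometric(letters[6:10], letters[1:2], letters[1:20])
  expect_gt(near1$p, 0.4)
  set.seed(7)
  for (i in 1:10) {
    uni <- paste0("u", 1:30)
    set <- sample(uni, 8); query <- sample(uni, 10)
    k <- length(intersect(set, query))
    res <- oraHypergeometric(query, set, uni)
    expect_equal(res$p, sum(dhyper(k:8, 8, 22, 10)), tolerance = 1e-12)
  }
  expect_error(oraHypergeometric("zzz", letters[1:3], letters[1:20]),
               "subset")
})

test_that("enrichment of a top-ranked set is maximal and significant", {
  set.seed(8)
  r <- setNames(sort(rnorm(60), decreasing = TRUE), sprintf("g%02d", 1:60))
  res <- prerankedEnrichment(r, GeneModule("top", names(r)[1:16]),
                             nPerm = 500, minSize = 10, seed = 1)
  expect_equal(res$ES, 1, tolerance = 1e-9)
  expect_lte(res$p, 0.02)
  expect_identical(res$FDR, res$p)
})

test_that("enrichment score is antisymmetric under score negation", {
  set.seed(9)
  r <- setNames(rnorm(80), sprintf("g%02d", 1:80))
  gs <- GeneModule("s", sample(names(r), 20))
  a <- prerankedEnrichment(r, gs, nPerm = 50, minSize = 10, seed = 1)
  b <- prerankedEnrichment(-r, gs, nPerm = 50, minSize = 10, seed = 1)
  expect_equal(a$ES, -b$ES, tolerance = 1e-12)
})

test_that("tiny enrichment instances match the hand-computed running sum", {
  r <- setNames(c(5, 4, 3, 2, 1, 0.5), paste0("g", 1:6))
  for (set in list(c("g1", "g2"), c("g3", "g6"), c("g5", "g6"))) {
    res <- suppressWarnings(
      prerankedEnrichment(r, GeneModule("s", set), nPerm = 100,
                          minSize = 1, seed = 1))
    expect_equal(res$ES, handES(r, names(r) %in% set), tolerance = 1e-12)
  }
})

test_that("enrichment agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(10)
  r <- setNames(rnorm(150), sprintf("g%03d", 1:150))
  gs <- sample(names(r), 25)
  mine <- prerankedEnrichment(r, GeneModule("s", gs), nPerm = 100, seed = 1)
  so <- sort(r, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(so, which(names(so) %in% gs), gseaParam = 1)
  expect_equal(mine$ES, ref, tolerance = 1e-10)
})

test_that("uniformly interleaved sets are not called enriched", {
  ok <- 0L
  for (s in 1:10) {
    r <- setNames(seq(10, 0.1, length.out = 100) + 0.001 * s,
                  sprintf("g%03d", 1:100))
    gs <- names(r)[seq(3, 100, by = 5)]
    res <- prerankedEnrichment(r, GeneModule("s", gs), nPerm = 200,
                               seed = s)
    if (res$p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("sets outside the size bounds are skipped with a reason", {
  r <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  expect_warning(
    res <- prerankedEnrichment(r, GeneModule("tiny", names(r)[1:4]),
                               nPerm = 50, seed = 1),
    "size")
  expect_true(is.na(res$ES))
  expect_match(res$reason, "outside")
})
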