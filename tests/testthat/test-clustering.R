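# Slope vectors, k-means in slope space, the pattern grammar, and
# congruence classification.

test_that("slope vectors are exact for affine profiles and quadratics at interior days", {
  days <- c(-2, 0, 2, 4, 6, 8)
  # affine profiles: every slope equals the generating slope
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    cur <- conditionMeanCurves(makeTce(rbind(a + b * days), rbind(a + b * days), days = days))
    sv <- slopeVectors(cur)
    expect_equal(unname(sv@slopes[1, ]), rep(b, 6), tolerance = 1e-12)
  }
  # linear grid example: values (0,2,...,10) -> all slopes 1
  cur <- conditionMeanCurves(makeTce(rbind(seq(0, 10, 2)), rbind(seq(0, 10, 2)), days = days))
  expect_equal(unname(slopeVectors(cur)@slopes[1, ]), rep(1, 6))
  # constant profile -> zero slopes
  cur0 <- conditionMeanCurves(makeTce(rbind(rep(4, 6)), rbind(rep(4, 6)), days = days))
  expect_equal(unname(slopeVectors(cur0)@slopes[1, ]), rep(0, 6))
  # central differences are exact for quadratics at interior days
  curQ <- conditionMeanCurves(makeTce(rbind(days^2), rbind(days^2), days = days))
  sq <- slopeVectors(curQ)@slopes[1, ]
  expect_equal(unname(sq[2:5]), 2 * days[2:5])  # derivative 2 * day
  expect_equal(unname(sq[3]), 4)                # (x(4) - x(0)) / 4 at day 2
})

test_that("k-means separates well-separated slope archetypes and is deterministic", {
  set.seed(32)
  t1 <- archetypeTemplate("rise"); t2 <- archetypeTemplate("fall-constant")
  days <- c(-2, 0, 2, 4, 6, 8)
  n <- 30
  epi <- rbind(
    matrix(rep(8 + 5 * t1, n), n, byrow = TRUE),
    matrix(rep(8 + 5 * t2, n), n, byrow = TRUE)
  ) + matrix(rnorm(2 * n * 6, 0, 0.01), 2 * n)
  tce <- makeTce(epi, epi, days = days)
  prof <- slopeVectors(conditionMeanCurves(tce))
  m <- fitKmeans(prof, k = 2, seed = 1, nRestarts = 10)
  expect_gt(m@bssTss, 0.99)
  # perfect 2-way partition (both conditions share the layout)
  grp <- rep(rep(1:2, each = n), 2)
  expect_identical(length(unique(m@cluster[grp == 1])), 1L)
  expect_identical(length(unique(m@cluster[grp == 2])), 1L)
  expect_false(unique(m@cluster[grp == 1]) == unique(m@cluster[grp == 2]))

  m2 <- fitKmeans(prof, k = 2, seed = 1, nRestarts = 10)
  expect_identical(m@cluster, m2@cluster)
  expect_equal(m@centroids, m2@centroids)
})

test_that("k equal to the number of distinct observations gives BSS/TSS = 1", {
  set.seed(33)
  epi <- matrix(rnorm(18), 3)
  prof <- slopeVectors(conditionMeanCurves(makeTce(epi, epi + 1)))
  # 3 genes x 2 conditions but epi and ing slopes coincide -> 3 distinct rows
  m <- fitKmeans(prof, k = 3, seed = 2, nRestarts = 5)
  expect_equal(m@totWithinss, 0, tolerance = 1e-20)
  expect_equal(m@bssTss, 1)
})

test_that("identical slope observations make BSS/TSS undefined", {
  cur <- conditionMeanCurves(makeTce(matrix(5, 4, 6), matrix(7, 4, 6)))
  prof <- slopeVectors(cur)
  expect_error(fitKmeans(prof, k = 2), "identical")
})

test_that("pattern grammar labels and collapses slope signs", {
  expect_identical(labelPattern(rep(1, 6), 0.1), "rise")
  expect_identical(labelPattern(c(1, -1, 1, -1, 1, -1), 0.1),
                   "rise-fall-rise-fall-rise-fall")
  expect_identical(labelPattern(c(1, 1, 0, 0, -1, -1), 0.1),
                   "rise-constant-fall")
  expect_identical(labelPattern(c(-1, -1, 0, 0, 0, 0), 0.1), "fall-constant")
  expect_error(labelPattern(1:3, -0.5), ">= 0")
})

test_that("congruence classification matches a counting oracle and conserves genes", {
  patterns <- c("constant", "rise", "fall-constant")
  genes <- paste0("g", 1:10)
  clEpi <- c(1L, 1L, 2L, 3L, 2L, 2L, 1L, 3L, 3L, 2L)
  clIng <- c(1L, 2L, 2L, 3L, 3L, 2L, 1L, 1L, 3L, 1L)
  model <- new("ClusterModel",
               k = 3L, centroids = matrix(0, 3, 6),
               cluster = c(clEpi, clIng),
               gene = rep(genes, 2),
               condition = rep(c("epi", "ing"), each = 10),
               bssTss = 0.5, totWithinss = 1, patterns = patterns,
               seed = 1L, nRestarts = 1L, days = c(-2, 0, 2, 4, 6, 8))
  cg <- congruenceClassification(model)
  rec <- congruenceRecords(cg)
  rec <- rec[match(genes, rec$gene), ]
  expect_equal(rec$congruent, clEpi == clIng)
  expect_identical(sum(rec$congruent) + sum(!rec$congruent), 10L)
  # counting oracle over combinations
  oracle <- table(paste(clEpi, clIng, sep = "-"))
  got <- setNames(cg@combinations$count, cg@combinations$combination)
  expect_equal(unname(got[names(oracle)]), unname(as.integer(oracle)))
  # cluster 1 has the "constant" pattern; one-side-constant flag
  expect_identical(cg@constantCluster, 1L)
  expect_equal(rec$one_side_constant, xor(clEpi == 1L, clIng == 1L))
})

test_that("permuting cluster ids preserves the congruent/divergent partition", {
  genes <- paste0("g", 1:8)
  clEpi <- c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L)
  clIng <- c(1L, 3L, 3L, 2L, 2L, 1L, 1L, 2L)
  mk <- function(e, i) new("ClusterModel",
    k = 3L, centroids = matrix(0, 3, 6), cluster = c(e, i),
    gene = rep(genes, 2), condition = rep(c("epi", "ing"), each = 8),
    bssTss = 0.5, totWithinss = 1, patterns = c("a", "b", "c"),
    seed = 1L, nRestarts = 1L, days = c(-2, 0, 2, 4, 6, 8))
  perm <- c(3L, 1L, 2L)
  r1 <- congruenceRecords(congruenceClassification(mk(clEpi, clIng)))
  r2 <- congruenceRecords(congruenceClassification(mk(perm[clEpi], perm[clIng])))
  expect_equal(r1$congruent[match(genes, r1$gene)],
               r2$congruent[match(genes, r2$gene)])
})

test_that("a gene missing one condition is rejected", {
  model <- new("ClusterModel",
               k = 2L, centroids = matrix(0, 2, 6),
               cluster = c(1L, 2L, 1L),
               gene = c("g1", "g1", "g2"),
               condition = c("epi", "ing", "epi"),
               bssTss = 0.5, totWithinss = 1, patterns = c("a", "b"),
               seed = 1L, nRestarts = 1L, days = c(-2, 0, 2, 4, 6, 8))
  expect_error(congruenceClassification(model), "missing a condition")
})

test_that("BSS/TSS diagnostic rises with k", {
  sim <- simulateTimecourse(nGenes = 60, fractionDivergent = 0.5,
                            noiseSd = 0.1, seed = 21)
  prof <- slopeVectors(conditionMeanCurves(sim$experiment))
  prof_bss <- bssTssProfile(prof, ks = c(2, 4, 8), seed = 3, nRestarts = 5)
  expect_true(all(diff(prof_bss) > 0))
  expect_true(all(prof_bss >= 0 & prof_bss <= 1))
})
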