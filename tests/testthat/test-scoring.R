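# The four divergence scores, significance and instability flags,
# consensus scaling and the selection rules.

test_that("integral scores match closed-form rectangle and triangle cases", {
  cur <- makeCurvesWithDiff(rbind(
    rep(2, 6),                 # constant offset 2
    c(0, 0, 2, 4, 4, 4),       # linear 0 -> 4 over the middle interval
    rep(0, 6)
  ))
  ints <- integralScores(cur)
  expect_equal(ints["g1", "whole"], 20, tolerance = 1e-12)  # 2 x 10
  expect_equal(ints["g2", "middle"], 8, tolerance = 1e-12)  # triangle
  expect_equal(unname(ints["g3", ]), rep(0, 4))
  expect_equal(ints["g1", "early"], 4, tolerance = 1e-12)
  expect_error(integralScores(cur, list(bad = c(-1, 3))), "day grid")
})

test_that("dynamic score captures drift and ignores symmetric transients", {
  days <- c(-2, 0, 2, 4, 6, 8)
  cur <- makeCurvesWithDiff(rbind(days + 2,            # slope 1, duration 10
                                  rep(3, 6),           # constant
                                  c(0, 1, 2, 2, 1, 0)))  # symmetric about day 3
  dyn <- dynamicScore(cur)
  expect_equal(unname(dyn["g1"]), 10, tolerance = 1e-12)
  expect_equal(unname(dyn["g2"]), 0)
  # OLS slope of the symmetric profile by normal equations is 0
  tc <- days - mean(days)
  expect_equal(sum(tc * c(0, 1, 2, 2, 1, 0)) / sum(tc^2), 0)
  expect_equal(unname(dyn["g3"]), 0, tolerance = 1e-12)
})

test_that("peak score is the max median-centered excursion", {
  cur <- makeCurvesWithDiff(rbind(
    rep(2, 6),                # pure offset
    c(0, 0, 0, 0, 0, 5),      # single spike
    c(1, 1, 1, 4, 1, 1)       # offset + spike 3
  ))
  pk <- peakScore(cur)
  expect_equal(unname(pk), c(0, 5, 3), tolerance = 1e-12)
})

test_that("relevance score is log1p of the count with zero for unknown genes", {
  counts <- data.frame(gene = c("a", "b", "c"), count = c(0, 9, 3))
  rel <- relevanceScore(c("a", "b", "c", "d", "e"), counts)
  expect_equal(unname(rel), c(0, log(10), log(4), 0, 0))
  expect_equal(unname(rel["b"]), 2.302585, tolerance = 1e-6)
  # equal counts give equal scores
  expect_equal(unname(rel["c"]), log1p(3))
  expect_error(relevanceScore("a", data.frame(gene = "a", count = -1)), ">= 0")
})

test_that("instability index ranks replicate variance and the quantile flag works", {
  sim <- simulateTimecourse(nGenes = 100, noiseSd = 0.2, seed = 3)
  tce <- sim$experiment
  x <- log2Values(tce)
  # identical replicates -> zero index
  cd <- SummarizedExperiment::colData(tce)
  for (d in days(tce)) for (cc in conditionLevels(tce)) {
    idx <- which(cd$condition == cc & cd$day == d)
    x["gene0001", idx] <- x["gene0001", idx[1]]
  }
  # one gene with replicates inflated x100
  x["gene0002", ] <- x["gene0002", ] * 100
  tce2 <- TimeCourseExperiment(x, cd$condition, cd$day, cd$replicate)
  idx2 <- instabilityIndex(tce2)
  expect_equal(unname(idx2["gene0001"]), 0)
  expect_identical(names(which.max(idx2)), "gene0002")
  expect_true(flagUnstable(idx2, 0.95)["gene0002"])
  expect_false(any(flagUnstable(idx2, 1)))

  single <- makeTce(matrix(1:6, 1), matrix(1:6, 1), nRep = 1)
  expect_error(instabilityIndex(single), "2 replicates")
})

test_that("robust-z significance matches its closed form and degenerates safely", {
  # symmetric construction: 100 base values with median 0 and
  # median absolute deviation 25, invariant to the added probe
  base <- c(-(1:50), 0, 1:49)

  atMedian <- c(base, 0)
  res <- scoreSignificance(atMedian)
  expect_equal(res$p[101], 0.5)
  expect_false(res$significant[101])

  # probe at median + 3 x 1.4826 MAD: z = 3, p ~ 0.00135
  probe <- 3 * 1.4826 * 25
  r2 <- scoreSignificance(c(base, probe))
  expect_equal(r2$z[101], 3, tolerance = 1e-9)
  expect_equal(r2$p[101], pnorm(3, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(r2$significant[101])

  expect_false(any(scoreSignificance(rep(1, 20))$significant))
  expect_error(scoreSignificance(1:5), "at least 10")
})

test_that("consensus scaling pins the extremes to 1 and 0", {
  dyn <- c(5, 1, 3); pk <- c(4, 0, 2); int <- c(30, 2, 10); rel <- c(3, 0, 1)
  cons <- consensusScores(dyn, pk, int, rel)
  expect_equal(cons[1], 1)   # maximal in all four
  expect_equal(cons[2], 0)   # minimal in all four
  expect_true(cons[3] > 0 && cons[3] < 1)
  # exactly two genes -> {0, 1}
  expect_setequal(consensusScores(c(1, 2), c(1, 2), c(1, 2), c(1, 2)), c(0, 1))
  # a constant score contributes 0 for everyone but does not break scaling
  expect_equal(consensusScores(c(1, 2), c(3, 3), c(1, 2), c(1, 2)),
               c(0, 1))
})

test_that("raising one raw score never worsens a gene's consensus rank", {
  set.seed(9)
  for (i in 1:20) {
    n <- 15
    dyn <- runif(n); pk <- runif(n); int <- runif(n); rel <- runif(n)
    g <- sample(n, 1)
    before <- rank(-consensusScores(dyn, pk, int, rel), ties.method = "min")[g]
    pk2 <- pk; pk2[g] <- pk2[g] + runif(1, 0.1, 2)
    after <- rank(-consensusScores(dyn, pk2, int, rel), ties.method = "min")[g]
    expect_lte(after, before)
  }
})

test_that("scores depend only on the between-condition difference", {
  set.seed(4)
  epi <- matrix(rnorm(30, 8), 5); ing <- matrix(rnorm(30, 8), 5)
  shift <- matrix(rep(rnorm(5, 0, 3), 6), 5)  # gene-specific constant
  c1 <- conditionMeanCurves(makeTce(epi, ing))
  c2 <- conditionMeanCurves(makeTce(epi + shift, ing + shift))
  expect_equal(dynamicScore(c1), dynamicScore(c2))
  expect_equal(peakScore(c1), peakScore(c2))
  expect_equal(integralScores(c1), integralScores(c2))
})

test_that("candidate selection requires all four flags and stability", {
  flags <- expand.grid(sig_dynamic = c(TRUE, FALSE), sig_peak = c(TRUE, FALSE),
                       sig_integral = c(TRUE, FALSE), sig_relevance = c(TRUE, FALSE),
                       unstable = c(TRUE, FALSE))
  flags$gene <- paste0("g", seq_len(nrow(flags)))
  got <- selectCandidates(flags)
  oracle <- flags$gene[with(flags, sig_dynamic & sig_peak & sig_integral &
                              sig_relevance & !unstable)]
  expect_setequal(got, oracle)
  expect_length(got, 1L)  # only the all-TRUE, stable row survives
})

test_that("upper-quartile selection keeps strictly-above-Q3 genes", {
  cons <- setNames(1:8, paste0("g", 1:8))
  expect_setequal(selectTopSet(cons), c("g7", "g8"))  # Q3 = 6.25
  tied <- setNames(rep(0.5, 10), paste0("g", 1:10))
  expect_length(selectTopSet(tied), 0L)
  few <- setNames(c(0.1, 0.9, 0.5), paste0("g", 1:3))
  expect_warning(kept <- selectTopSet(few), "fewer than 4")
  expect_setequal(kept, names(few))
})

test_that("scoreGenes assembles a coherent sorted table", {
  sim <- simulateTimecourse(nGenes = 150, fractionDivergent = 0.1, seed = 12)
  lit <- simulateLiteratureCounts(sim$truth$gene,
                                  sim$truth$gene[sim$truth$divergent], seed = 13)
  st <- scoreGenes(sim$experiment, lit)
  tab <- scoreTable(st)
  expect_identical(nrow(tab), 150L)
  expect_true(!is.unsorted(rev(tab$consensus)))
  expect_equal(max(tab$consensus), 1)
  expect_equal(min(tab$consensus), 0)
  expect_true(all(tab$dynamic >= 0 & tab$peak >= 0 & tab$relevance >= 0))
  expect_true(all(selectCandidates(st) %in% tab$gene))
})
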