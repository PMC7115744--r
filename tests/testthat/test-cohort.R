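# Cohort validation statistics: group assignment, Spearman, the
# Mann-Whitney wrapper and adjusted regression.

test_that("obesity groups follow the BMI and vis/sc ratio rules and partition the cohort", {
  cohort <- data.frame(
    bmi = c(24, 40, 40, 31, 29.9),
    vis_sc_ratio = c(2, 0.3, 0.5, 0.4, 0.01)
  )
  g <- assignGroups(cohort)
  expect_equal(as.character(g),
               c("lean", "sc_obese", "vis_obese", "vis_obese", "lean"))
  expect_false(anyNA(g))  # every subject in exactly one group

  cc <- simulateCohort(seed = 2)
  gg <- assignGroups(cc$cohort)
  expect_identical(sum(table(gg)), 63L)
  expect_error(assignGroups(data.frame(bmi = 20, vis_sc_ratio = -1)), ">= 0")
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearmanAssoc(1:3, 3:1)$rho, -1)
  expect_equal(spearmanAssoc(1:3, 3:1)$p, 0)
  expect_equal(spearmanAssoc(1:4, c(2, 4, 6, 8))$rho, 1)

  # tied data against an explicit average-rank Pearson computation
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearmanAssoc(x, y)
  expect_equal(res$rho, oracle, tolerance = 1e-12)

  # agreement with the standard implementation (estimate and t-approx p)
  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(25); b <- 0.5 * a + rnorm(25)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    got <- spearmanAssoc(a, b)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(42)
  for (i in 1:15) {
    x <- rnorm(30); y <- rnorm(30)
    base <- spearmanAssoc(x, y)$rho
    expect_equal(spearmanAssoc(exp(x), y)$rho, base)
    expect_equal(spearmanAssoc(x, y^3)$rho, base)
  }
})

test_that("Spearman handles missing pairs and degenerate input", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  res <- spearmanAssoc(x, y)
  expect_identical(res$n, 3L)
  d <- spearmanAssoc(rep(1, 10), rnorm(10))
  expect_true(d$degenerate)
  expect_true(is.na(d$rho))
  expect_error(spearmanAssoc(1:2, 2:1), "3 complete pairs")
})

test_that("Mann-Whitney wrapper reproduces exact and degenerate cases", {
  res <- mannWhitneyTest(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_true(res$exact)

  tie <- mannWhitneyTest(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tie$U, 4.5)
  expect_equal(tie$p, 1)
  expect_true(tie$allTies)

  expect_error(mannWhitneyTest(numeric(), 1:3), "nonempty")

  # exact branch agrees with the enumeration oracle on random data
  set.seed(43)
  for (i in 1:10) {
    a <- sample(100, 4); b <- sample(100, 3) + 0.5
    got <- mannWhitneyTest(a, b)
    ora <- enumMannWhitney(a, b)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
  }

  # large samples switch to the corrected normal approximation
  set.seed(44)
  big <- mannWhitneyTest(rnorm(30), rnorm(30))
  expect_false(big$exact)
  expect_true(big$p >= 0 && big$p <= 1)
})

test_that("adjusted regression recovers noiseless coefficients exactly", {
  set.seed(45)
  n <- 40
  bmi <- runif(n, 20, 45); age <- runif(n, 20, 80)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  expr <- 3 + 2 * bmi + 0.5 * age + 1 * (sex == "male")
  # a noiseless design triggers summary.lm's perfect-fit warning
  fit <- suppressWarnings(adjustedRegression(expr, bmi, age, sex))
  expect_equal(fit$beta[fit$term == "(Intercept)"], 3, tolerance = 1e-9)
  expect_equal(fit$beta[fit$term == "phenotype"], 2, tolerance = 1e-9)
  expect_equal(fit$beta[fit$term == "age"], 0.5, tolerance = 1e-9)
  expect_equal(fit$beta[fit$term == "sex_male"], 1, tolerance = 1e-9)
})

test_that("adjusted regression flags collinear designs by column name", {
  n <- 30
  age <- runif(n, 20, 80)
  sex <- rep(c("female", "male"), 15)
  expr <- rnorm(n)
  expect_error(adjustedRegression(expr, age, age, sex), "collinear.*age")
})

test_that("null phenotype gives coefficients within sampling error", {
  set.seed(46)
  ok <- 0L
  for (i in 1:200) {
    n <- 60
    bmi <- runif(n, 20, 45); age <- runif(n, 20, 80)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    expr <- rnorm(n)  # independent of everything
    fit <- adjustedRegression(expr, bmi, age, sex)
    j <- fit$term == "phenotype"
    if (abs(fit$beta[j]) < 3 * fit$se[j]) ok <- ok + 1L
  }
  expect_gte(ok / 200, 0.95)
})

test_that("association and group-comparison tables cover every gene-depot cell", {
  cc <- simulateCohort(genes = c("A", "B"), seed = 9,
                       targets = data.frame(gene = "A", depot = "sc",
                                            phenotype = "bmi", rho = -0.8))
  at <- associationTable(cc$cohort, c("A", "B"))
  expect_identical(nrow(at), 2L * 2L * 2L)
  expect_true(all(at$n <= 63))
  expect_true(all(at$rho >= -1 & at$rho <= 1))
  # the targeted cell shows the strongest negative correlation
  hit <- at[at$gene == "A" & at$depot == "sc" & at$phenotype == "bmi", ]
  expect_lt(hit$rho, -0.5)

  gt <- groupComparisonTable(cc$cohort, c("A", "B"))
  expect_identical(nrow(gt), 2L * 2L * 3L)  # 3 group pairs
  expect_true(all(gt$p >= 0 & gt$p <= 1))
})

test_that("simulated cohort recovers a target Spearman within 0.1 at n = 2000", {
  big <- simulateCohort(
    nSubjects = 2000,
    groupSizes = c(lean = 800, sc_obese = 600, vis_obese = 600),
    genes = "G",
    targets = data.frame(gene = "G", depot = "vis", phenotype = "whr", rho = 0.7),
    seed = 10
  )
  expect_lt(abs(spearmanAssoc(big$cohort$G_vis, big$cohort$whr)$rho - 0.7), 0.1)
})
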