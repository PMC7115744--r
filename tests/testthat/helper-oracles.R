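# Shared fixtures and independent oracles used across the test files.

# Build a TimeCourseExperiment whose condition-mean curves equal the
# given per-gene profiles exactly (replicates are identical copies
# unless noise is requested).
makeTce <- function(epi, ing, days = c(-2, 0, 2, 4, 6, 8), nRep = 2,
                    noiseSd = 0, seed = 1) {
  epi <- rbind(epi); ing <- rbind(ing)
  stopifnot(ncol(epi) == length(days), ncol(ing) == length(days))
  genes <- rownames(epi)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(epi)))
  grid <- expand.grid(replicate = seq_len(nRep), day = days,
                      condition = c("epi", "ing"), stringsAsFactors = FALSE)
  values <- matrix(0, nrow(epi), nrow(grid))
  set.seed(seed)
  for (j in seq_len(nrow(grid))) {
    m <- if (grid$condition[j] == "epi") epi else ing
    values[, j] <- m[, match(grid$day[j], days)] +
      if (noiseSd > 0) rnorm(nrow(epi), 0, noiseSd) else 0
  }
  rownames(values) <- genes
  TimeCourseExperiment(values, grid$condition, grid$day, grid$replicate,
                       paste(grid$condition, grid$day, grid$replicate, sep = "_"))
}

# Curves with prescribed difference d and flat ing baseline.
makeCurvesWithDiff <- function(d, days = c(-2, 0, 2, 4, 6, 8), base = 8) {
  d <- rbind(d)
  ing <- matrix(base, nrow(d), length(days))
  rownames(d) <- rownames(ing) <- paste0("g", seq_len(nrow(d)))
  conditionMeanCurves(makeTce(ing + d, ing, days = days))
}

# Brute-force triple-loop re-implementation of the DABG filter.
bruteForceFilter <- function(dabg, alpha, fraction) {
  kept <- character()
  for (g in unique(dabg$gene)) {
    sub <- dabg[dabg$gene == g, ]
    exons <- unique(sub$exon)
    for (s in unique(sub$sample)) {
      nHit <- 0L
      for (e in exons) {
        p <- sub$p[sub$exon == e & sub$sample == s]
        if (length(p) && p[1L] < alpha) nHit <- nHit + 1L
      }
      if (nHit / length(exons) >= fraction) {
        kept <- c(kept, g)
        break
      }
    }
  }
  kept
}

randomDabgTable <- function(nGenes, nExons, nSamples, alpha = 0.05) {
  tab <- expand.grid(
    gene = paste0("g", seq_len(nGenes)),
    exon = paste0("e", seq_len(nExons)),
    sample = paste0("s", seq_len(nSamples)),
    stringsAsFactors = FALSE
  )
  # mixture with mass near and exactly at alpha to probe the strict rule
  p <- runif(nrow(tab))
  atBoundary <- runif(nrow(tab)) < 0.05
  p[atBoundary] <- alpha
  tab$p <- p
  tab
}

# Exhaustive-enumeration Mann-Whitney oracle (no ties assumed): the
# exact two-sided p from the permutation distribution of U.
enumMannWhitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  uStat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u0 <- uStat(seq_len(na))
  us <- apply(utils::combn(na + nb, na), 2L, uStat)
  pLow <- mean(us <= u0)
  pHigh <- mean(us >= u0)
  p <- if (u0 > na * nb / 2) 2 * pHigh else 2 * pLow
  list(U = u0, p = min(1, p))
}

# Rank-based AUROC, independent of any classification package.
aurocOracle <- function(score, positive) {
  r <- rank(score)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
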