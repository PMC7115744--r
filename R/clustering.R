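# Slope-space k-means clustering of expression trajectories and
# congruent-versus-divergent dynamics classification.

.finiteDifferences <- function(m, t) {
  n <- length(t)
  s <- matrix(0, nrow(m), n, dimnames = dimnames(m))
  s[, 1L] <- (m[, 2L] - m[, 1L]) / (t[2L] - t[1L])
  s[, n] <- (m[, n] - m[, n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    for (j in 2:(n - 1L)) {
      s[, j] <- (m[, j + 1L] - m[, j - 1L]) / (t[j + 1L] - t[j - 1L])
    }
  }
  s
}

#' Slope vectors of condition-mean expression profiles
#'
#' Approximates the per-day derivative of every gene's condition-mean
#' curve: central differences `(x[i+1] - x[i-1]) / (day[i+1] -
#' day[i-1])` at interior days, one-sided differences at the two
#' endpoints (exact for affine profiles). The epi and ing profiles of a
#' gene enter as two separate observations, which is what makes "same
#' cluster in both depots" well-defined downstream.
#'
#' @param curves a [MeanCurves-class] object (>= 3 days).
#' @return a [SlopeProfiles-class] object (log2 units per day).
#' @export
slopeVectors <- function(curves) {
  stopifnot(is(curves, "MeanCurves"))
  t <- days(curves)
  if (length(t) < 3L) stop("at least 3 days required", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate days are not allowed", call. = FALSE)
  conds <- conditionLevels(curves)
  slopes <- do.call(rbind, lapply(conds, function(cc) {
    .finiteDifferences(meanCurve(curves, cc), t)
  }))
  gene <- rep(geneIds(curves), times = length(conds))
  condition <- rep(conds, each = length(geneIds(curves)))
  rownames(slopes) <- paste(gene, condition, sep = ".")
  new("SlopeProfiles", slopes = slopes, gene = gene,
      condition = condition, days = t)
}

# k-means++ seeding: D^2-weighted sampling of k distinct rows.
.kppInit <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (i in 2:k) {
      if (all(d2 == 0)) {
        # fewer distinct points than k; fall back to unused rows
        idx[i] <- setdiff(seq_len(n), idx[seq_len(i - 1L)])[1L]
      } else {
        idx[i] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[i], ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  idx
}

#' k-means clustering of pooled slope vectors
#'
#' Clusters all (gene, condition) slope observations jointly with
#' Lloyd's algorithm, k-means++ seeding, and the best of `nRestarts`
#' restarts by total within-cluster sum of squares (exact ties broken
#' by the lowest restart index). Reports the between-SS / total-SS
#' compactness ratio and labels each centroid with its schematic
#' rise/constant/fall pattern.
#'
#' @param profiles a [SlopeProfiles-class] object.
#' @param k number of clusters (default 8).
#' @param seed integer RNG seed; fits are deterministic under it.
#' @param nRestarts number of restarts.
#' @param epsilon slope tolerance for pattern labelling, or `"auto"`
#'   (see [autoEpsilon()]).
#' @return a [ClusterModel-class] object.
#' @export
fitKmeans <- function(profiles, k = 8, seed = 7, nRestarts = 25,
                      epsilon = "auto") {
  stopifnot(is(profiles, "SlopeProfiles"))
  x <- profiles@slopes
  k <- as.integer(k)
  if (nrow(x) < k) stop("need at least k observations", call. = FALSE)
  totss <- sum(scale(x, scale = FALSE)^2)
  if (totss == 0) {
    stop("all slope observations are identical; BSS/TSS is undefined",
         call. = FALSE)
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      centers <- x[.kppInit(x, k), , drop = FALSE]
      fit <- suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 200L,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
        best <- fit
      }
    }
  })
  eps <- if (identical(epsilon, "auto")) autoEpsilon(x) else epsilon
  new("ClusterModel",
      k = k,
      centroids = unname(best$centers),
      cluster = as.integer(best$cluster),
      gene = profiles@gene,
      condition = profiles@condition,
      bssTss = best$betweenss / best$totss,
      totWithinss = best$tot.withinss,
      patterns = apply(best$centers, 1L, labelPattern, epsilon = eps),
      seed = as.integer(seed),
      nRestarts = as.integer(nRestarts),
      days = profiles@days)
}

#' Data-driven tolerance for "constant" slopes
#'
#' The rise/constant/fall grammar compares slopes to zero, which is
#' measure-zero for real data; the default tolerance is `prop` times
#' the `q`-th quantile of the absolute slopes in the dataset.
#'
#' @param slopes numeric matrix (or vector) of slopes.
#' @param prop proportion of the reference quantile (default 0.1).
#' @param q reference quantile of `|slopes|` (default 0.95).
#' @return single nonnegative tolerance.
#' @export
autoEpsilon <- function(slopes, prop = 0.1, q = 0.95) {
  prop * stats::quantile(abs(slopes), q, names = FALSE)
}

#' Schematic pattern label of a slope vector
#'
#' Maps each per-day slope to `rise` (slope > epsilon), `fall`
#' (slope < -epsilon) or `constant` (within the tolerance), collapses
#' runs of identical symbols, and joins them with hyphens: the grammar
#' behind the eight schematic cluster shapes.
#'
#' @param slopes numeric slope vector (e.g. a centroid).
#' @param epsilon nonnegative tolerance around zero.
#' @return single pattern string, e.g. `"rise-constant-fall"`.
#' @examples
#' labelPattern(c(1, 1, 0, 0, -1, -1), epsilon = 0.1)
#' @export
labelPattern <- function(slopes, epsilon = 0) {
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  sym <- ifelse(slopes > epsilon, "rise",
                ifelse(slopes < -epsilon, "fall", "constant"))
  paste(rle(as.vector(sym))$values, collapse = "-")
}

#' Congruent vs divergent dynamics per gene
#'
#' Extracts, per gene, the (epi cluster, ing cluster) combination of
#' its two slope profiles. Congruent dynamics means both profiles fell
#' into the same cluster (same trajectory shape, possibly different
#' expression level); different clusters mean the gene responds to the
#' differentiation stimulus with different dynamics in the two depots.
#' Combinations in which exactly one side sits in the all-constant
#' cluster (a gene that responds in one depot only) are flagged.
#'
#' @param model a [ClusterModel-class] with both conditions assigned
#'   for every gene.
#' @return a [CongruenceResult-class] object.
#' @export
congruenceClassification <- function(model) {
  stopifnot(is(model, "ClusterModel"))
  conds <- unique(model@condition)
  if (length(conds) != 2L) {
    stop("exactly two conditions are required", call. = FALSE)
  }
  first <- if ("epi" %in% conds) "epi" else conds[1L]
  second <- setdiff(conds, first)
  byGene <- split(data.frame(condition = model@condition,
                             cluster = model@cluster,
                             stringsAsFactors = FALSE),
                  model@gene)
  bad <- names(byGene)[!vapply(byGene, function(d) setequal(d$condition, conds),
                               logical(1))]
  if (length(bad)) {
    stop(sprintf("gene(s) missing a condition: %s",
                 paste(utils::head(bad, 3L), collapse = ", ")), call. = FALSE)
  }
  genes <- names(byGene)
  clA <- vapply(byGene, function(d) d$cluster[d$condition == first][1L], integer(1))
  clB <- vapply(byGene, function(d) d$cluster[d$condition == second][1L], integer(1))
  constCl <- which(model@patterns == "constant")
  constCl <- if (length(constCl)) constCl[1L] else NA_integer_
  records <- data.frame(
    gene = genes,
    cluster_epi = unname(clA),
    cluster_ing = unname(clB),
    congruent = unname(clA == clB),
    pattern_epi = model@patterns[clA],
    pattern_ing = model@patterns[clB],
    combination = paste(clA, clB, sep = "-"),
    one_side_constant = if (is.na(constCl)) FALSE else unname(xor(clA == constCl, clB == constCl)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  tally <- as.data.frame(table(combination = records$combination),
                         stringsAsFactors = FALSE)
  names(tally)[2L] <- "count"
  tally <- tally[order(-tally$count, tally$combination), ]
  rownames(tally) <- NULL
  new("CongruenceResult", records = records, combinations = tally,
      constantCluster = constCl)
}

#' BSS/TSS compactness across candidate cluster counts
#'
#' Auxiliary diagnostic mirroring an elbow inspection: fits the
#' slope-space k-means for a range of k and reports each fit's
#' between-SS / total-SS ratio.
#'
#' @param profiles a [SlopeProfiles-class] object.
#' @param ks integer vector of cluster counts.
#' @param seed,nRestarts passed to [fitKmeans()].
#' @return named numeric vector of BSS/TSS per k.
#' @export
bssTssProfile <- function(profiles, ks = 2:12, seed = 7, nRestarts = 10) {
  ks <- ks[ks <= nrow(profiles@slopes)]
  stats::setNames(
    vapply(ks, function(k) {
      fitKmeans(profiles, k = k, seed = seed, nRestarts = nRestarts)@bssTss
    }, numeric(1)),
    as.character(ks)
  )
}
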