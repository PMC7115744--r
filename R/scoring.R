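# Transcript time-course divergence scoring: four per-gene scores
# (interval integrals, dynamic drift, transient peak, literature
# relevance), robust-z significance, replicate-instability flagging,
# and the consensus score.

#' Canonical scoring intervals
#'
#' The early interval covers the pre-induction phase (day -2 to day 0),
#' the middle interval the four days following induction (day 0 to day
#' 4), the late interval days 6 to 8, and `whole` the full experiment.
#' Days 4-6 belong to no named sub-interval and are covered only by
#' `whole`.
#'
#' @return named list of `c(lower, upper)` day bounds.
#' @export
defaultIntervals <- function() {
  list(early = c(-2, 0), middle = c(0, 4), late = c(6, 8), whole = c(-2, 8))
}

#' Interval integral scores
#'
#' Per gene and interval, the trapezoidal integral of the absolute
#' difference curve `|d(day)|` over the days falling inside the
#' interval (units: log2 x day). Highlights absolute expression
#' divergence localized in time.
#'
#' @param curves a [MeanCurves-class] object.
#' @param intervals named list of day bounds; every bound must lie on
#'   the day grid and each interval must span at least two grid days.
#' @return genes x intervals numeric matrix.
#' @examples
#' sim <- simulateTimecourse(nGenes = 10, seed = 1)
#' head(integralScores(conditionMeanCurves(sim$experiment)))
#' @export
integralScores <- function(curves, intervals = defaultIntervals()) {
  stopifnot(is(curves, "MeanCurves"))
  dayGrid <- days(curves)
  absd <- abs(diffCurves(curves))
  out <- vapply(intervals, function(b) {
    if (!all(b %in% dayGrid)) {
      stop("interval bounds must lie on the day grid", call. = FALSE)
    }
    idx <- which(dayGrid >= b[1] & dayGrid <= b[2])
    if (length(idx) < 2L) {
      stop("an interval must span at least two grid days", call. = FALSE)
    }
    apply(absd[, idx, drop = FALSE], 1L, pracma::trapz, x = dayGrid[idx])
  }, numeric(length(geneIds(curves))))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(geneIds(curves), names(intervals))
  out
}

#' Dynamic (drift) score
#'
#' The absolute least-squares slope of the difference curve `d(day)`
#' regressed on day, multiplied by the experiment duration: the total
#' log2 divergence accumulated by a slow, constant drift. A symmetric
#' transient contributes nothing.
#'
#' @param curves a [MeanCurves-class] object (>= 3 days).
#' @return named numeric vector (log2 units).
#' @export
dynamicScore <- function(curves) {
  stopifnot(is(curves, "MeanCurves"))
  t <- days(curves)
  if (length(t) < 3L) stop("at least 3 days required", call. = FALSE)
  tc <- t - mean(t)
  slope <- as.vector(diffCurves(curves) %*% tc) / sum(tc^2)
  stats::setNames(abs(slope) * (max(t) - min(t)), geneIds(curves))
}

#' Peak (transient) score
#'
#' The largest absolute deviation of the difference curve from its own
#' median across days. Median-centering removes any constant offset,
#' so the score responds only to fast transient divergence.
#'
#' @param curves a [MeanCurves-class] object (>= 3 days).
#' @return named numeric vector (log2 units).
#' @export
peakScore <- function(curves) {
  stopifnot(is(curves, "MeanCurves"))
  if (length(days(curves)) < 3L) stop("at least 3 days required", call. = FALSE)
  d <- diffCurves(curves)
  med <- apply(d, 1L, stats::median)
  stats::setNames(apply(abs(d - med), 1L, max), geneIds(curves))
}

#' Literature relevance score
#'
#' `ln(1 + count)` of the publications associating a gene with the
#' configured stimulus term (e.g. "fat distribution"); genes absent
#' from the count table score 0.
#'
#' @param genes character, genes to score.
#' @param counts data.frame (gene, count) or named nonnegative numeric.
#' @return named numeric vector.
#' @export
relevanceScore <- function(genes, counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$gene)
  }
  if (any(counts < 0)) stop("publication counts must be >= 0", call. = FALSE)
  n <- counts[genes]
  n[is.na(n)] <- 0
  stats::setNames(log1p(as.numeric(n)), genes)
}

#' Replicate-instability index
#'
#' Per gene, the mean (over all (condition, day) cells) of the sample
#' variance across replicates: high values mark genes whose apparent
#' divergence could be replicate noise.
#'
#' @param experiment a [TimeCourseExperiment-class] with >= 2
#'   replicates per cell.
#' @return named numeric vector (log2^2 units).
#' @export
instabilityIndex <- function(experiment) {
  stopifnot(is(experiment, "TimeCourseExperiment"))
  x <- log2Values(experiment)
  cd <- colData(experiment)
  cells <- split(seq_len(ncol(x)), list(cd$condition, cd$day), drop = TRUE)
  if (any(lengths(cells) < 2L)) {
    stop("at least 2 replicates per (condition, day) cell are required",
         call. = FALSE)
  }
  vars <- vapply(cells, function(idx) {
    m <- x[, idx, drop = FALSE]
    rowSums((m - rowMeans(m))^2) / (length(idx) - 1L)
  }, numeric(nrow(x)))
  stats::setNames(rowMeans(vars), rownames(x))
}

#' Flag unstable genes
#'
#' A gene is unstable iff its instability index strictly exceeds the
#' given quantile of all genes' indices.
#'
#' @param index numeric vector from [instabilityIndex()].
#' @param quantile flagging quantile in `[0, 1]` (1 flags nothing).
#' @return named logical vector.
#' @export
flagUnstable <- function(index, quantile = 0.95) {
  assertScalarProb(quantile, "quantile", openLeft = FALSE, openRight = FALSE)
  index > stats::quantile(index, quantile, names = FALSE)
}

#' Robust-z score significance against an empirical null
#'
#' Centers a score vector at its median and scales by 1.4826 x MAD
#' (falling back to the standard deviation when the MAD is zero; if
#' that is also zero no gene is significant). The one-sided upper
#' normal tail gives a per-gene p-value; most genes are assumed null.
#'
#' @param scores numeric vector of one score across >= 10 genes.
#' @param alpha significance level.
#' @return list with `z`, `p` and logical `significant`.
#' @export
scoreSignificance <- function(scores, alpha = 0.05) {
  if (length(scores) < 10L) {
    stop("at least 10 genes are required to estimate the empirical null",
         call. = FALSE)
  }
  assertScalarProb(alpha, "alpha")
  s <- stats::mad(scores)  # already scaled by 1.4826
  if (s == 0) s <- stats::sd(scores)
  if (s == 0) {
    z <- rep(0, length(scores))
    p <- rep(1, length(scores))
  } else {
    z <- (scores - stats::median(scores)) / s
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(z = z, p = p, significant = p < alpha)
}

#' Consensus score across the four divergence scores
#'
#' Min-max scales each score to `[0, 1]` across genes (a score constant
#' across all genes scales to 0 everywhere), averages the four scaled
#' scores, and min-max rescales the averages: the top-ranked gene
#' scores exactly 1 and the bottom-ranked gene exactly 0.
#'
#' @param dynamic,peak,integral,relevance numeric score vectors over
#'   the same >= 2 genes (integral: the whole-period value).
#' @return numeric consensus vector in `[0, 1]`.
#' @export
consensusScores <- function(dynamic, peak, integral, relevance) {
  n <- length(dynamic)
  if (n < 2L) stop("at least 2 genes required", call. = FALSE)
  stopifnot(length(peak) == n, length(integral) == n, length(relevance) == n)
  avg <- (scale01(dynamic) + scale01(peak) + scale01(integral) + scale01(relevance)) / 4
  scale01(avg)
}

#' Score all genes of a time-course experiment
#'
#' Runs the full scoring stage: condition mean curves, the four
#' divergence scores, per-score robust-z significance flags (integral:
#' significant in at least one interval), the replicate-instability
#' flag, and the consensus score (using the whole-period integral).
#'
#' @param experiment a [TimeCourseExperiment-class].
#' @param litCounts literature count table (data.frame gene/count or
#'   named numeric); `NULL` scores relevance 0 for every gene, in which
#'   case no gene can be significant in all four scores.
#' @param alpha per-score significance level.
#' @param instabilityQuantile instability flagging quantile.
#' @param intervals named list of integral intervals; must contain
#'   `whole`.
#' @return a [GeneScoreTable-class], rows sorted by consensus
#'   descending.
#' @examples
#' sim <- simulateTimecourse(nGenes = 200, seed = 1)
#' lit <- simulateLiteratureCounts(sim$truth$gene,
#'                                 sim$truth$gene[sim$truth$divergent], seed = 2)
#' st <- scoreGenes(sim$experiment, lit)
#' head(selectCandidates(st))
#' @export
scoreGenes <- function(experiment, litCounts = NULL, alpha = 0.05,
                       instabilityQuantile = 0.95,
                       intervals = defaultIntervals()) {
  stopifnot(is(experiment, "TimeCourseExperiment"))
  if (!"whole" %in% names(intervals)) {
    stop("'intervals' must contain a 'whole' interval", call. = FALSE)
  }
  curves <- conditionMeanCurves(experiment)
  genes <- geneIds(curves)
  dyn <- dynamicScore(curves)
  pk <- peakScore(curves)
  ints <- integralScores(curves, intervals)
  rel <- if (is.null(litCounts)) {
    stats::setNames(rep(0, length(genes)), genes)
  } else {
    relevanceScore(genes, litCounts)
  }
  idx <- instabilityIndex(experiment)
  unstable <- flagUnstable(idx, instabilityQuantile)

  sigDyn <- scoreSignificance(dyn, alpha)$significant
  sigPk <- scoreSignificance(pk, alpha)$significant
  sigRel <- scoreSignificance(rel, alpha)$significant
  sigIntMat <- apply(ints, 2L, function(s) scoreSignificance(s, alpha)$significant)
  sigInt <- apply(sigIntMat, 1L, any)

  consensus <- consensusScores(dyn, pk, ints[, "whole"], rel)

  tab <- data.frame(gene = genes, dynamic = unname(dyn), peak = unname(pk),
                    stringsAsFactors = FALSE)
  for (nm in colnames(ints)) tab[[paste0("integral_", nm)]] <- unname(ints[, nm])
  tab$relevance <- unname(rel)
  tab$instability_index <- unname(idx)
  tab$sig_dynamic <- unname(sigDyn)
  tab$sig_peak <- unname(sigPk)
  tab$sig_integral <- unname(sigInt)
  tab$sig_relevance <- unname(sigRel)
  tab$unstable <- unname(unstable)
  tab$consensus <- unname(consensus)
  tab <- tab[order(-tab$consensus, tab$gene), ]
  rownames(tab) <- NULL

  new("GeneScoreTable", table = tab, alpha = alpha,
      instabilityQuantile = instabilityQuantile, intervals = intervals)
}

#' @describeIn selectCandidates method for a scored experiment.
#' @export
setMethod("selectCandidates", "GeneScoreTable", function(x) {
  selectCandidates(x@table)
})

#' @describeIn selectCandidates method for a raw score table with the
#'   flag columns.
#' @export
setMethod("selectCandidates", "data.frame", function(x) {
  keep <- x$sig_dynamic & x$sig_peak & x$sig_integral & x$sig_relevance & !x$unstable
  x$gene[keep]
})

#' Upper-quartile consensus selection
#'
#' Keeps the genes whose consensus score strictly exceeds the 75th
#' percentile (linear-interpolation quantile) of the candidate
#' consensus scores; applied to 137 distinct scores this keeps exactly
#' 34 genes. With fewer than 4 candidates the set is returned unchanged
#' with a warning.
#'
#' @param consensus named numeric vector of candidate consensus scores.
#' @return character vector of selected gene ids.
#' @examples
#' selectTopSet(setNames(1:8, paste0("g", 1:8)))  # Q3 = 6.25 -> g7, g8
#' @export
selectTopSet <- function(consensus) {
  if (is.null(names(consensus))) {
    stop("'consensus' must be named by gene", call. = FALSE)
  }
  if (length(consensus) < 4L) {
    warning("fewer than 4 candidates; returning them unchanged")
    return(names(consensus))
  }
  q3 <- stats::quantile(consensus, 0.75, names = FALSE, type = 7)
  names(consensus)[consensus > q3]
}
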