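#' Expressed-gene filter from detection-above-background p-values
#'
#' A gene is considered expressed if, in at least one sample, at least
#' `fraction` of its exons are detected above background (p < `alpha`).
#' With the defaults this is the "half of its exons in at least one
#' sample at p < 0.05" rule.
#'
#' @param dabg long data.frame with columns `gene`, `exon`, `sample`,
#'   `p` (all p in `[0, 1]`).
#' @param alpha detection significance level (strict inequality).
#' @param fraction minimal detected-exon fraction, in `(0, 1]`.
#' @return character vector of kept genes, in first-appearance order.
#' @examples
#' tab <- data.frame(gene = "g1", exon = paste0("e", 1:4), sample = "s1",
#'                   p = c(0.01, 0.04, 0.2, 0.3))
#' filterExpressedGenes(tab)  # 2/4 detected -> kept
#' @export
filterExpressedGenes <- function(dabg, alpha = 0.05, fraction = 0.5) {
  need <- c("gene", "exon", "sample", "p")
  if (!is.data.frame(dabg) || !all(need %in% colnames(dabg)) || !nrow(dabg)) {
    stop("'dabg' must be a nonempty data.frame with columns gene, exon, sample, p",
         call. = FALSE)
  }
  assertScalarProb(alpha, "alpha")
  assertScalarProb(fraction, "fraction", openRight = FALSE)
  if (anyNA(dabg$p) || any(dabg$p < 0 | dabg$p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  gene <- factor(dabg$gene, levels = unique(dabg$gene))
  nExons <- vapply(split(dabg$exon, gene), function(e) length(unique(e)), integer(1))
  if (any(nExons == 0L)) stop("every gene needs at least one exon", call. = FALSE)
  key <- interaction(gene, factor(dabg$sample), drop = FALSE)
  hits <- tapply(dabg$p < alpha, key, sum, default = 0L)
  # tapply over an interaction returns gene-major within sample blocks;
  # reshape to genes x samples.
  mat <- matrix(hits, nrow = nlevels(gene),
                dimnames = list(levels(gene), NULL))
  frac <- mat / nExons[rownames(mat)]
  keep <- apply(frac, 1L, function(r) any(r >= fraction, na.rm = TRUE))
  levels(gene)[keep]
}

#' Replicate-averaged condition mean curves and their difference
#'
#' Averages the log2 expression of every gene over replicates within
#' each (condition, day) cell and derives the per-day difference curve
#' `d(day) = mean(condition 1) - mean(condition 2)` (epi minus ing for
#' the canonical depots). `d` is the per-time-point log2 fold-change
#' between conditions and feeds every downstream divergence score.
#'
#' @param experiment a [TimeCourseExperiment-class].
#' @return a [MeanCurves-class] object.
#' @export
conditionMeanCurves <- function(experiment) {
  stopifnot(is(experiment, "TimeCourseExperiment"))
  x <- log2Values(experiment)
  cd <- colData(experiment)
  dayGrid <- days(experiment)
  conds <- conditionLevels(experiment)
  means <- lapply(conds, function(cc) {
    m <- vapply(dayGrid, function(d) {
      idx <- which(cd$condition == cc & cd$day == d)
      if (!length(idx)) {
        stop(sprintf("missing (condition, day) cell: (%s, %s)", cc, d),
             call. = FALSE)
      }
      rowMeans(x[, idx, drop = FALSE])
    }, numeric(nrow(x)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    dimnames(m) <- list(rownames(x), as.character(dayGrid))
    m
  })
  names(means) <- conds
  new("MeanCurves",
      genes = rownames(x), days = dayGrid, conditions = conds,
      means = means, diff = means[[1L]] - means[[2L]])
}

#' Average log2 fold-change trajectory of a gene set
#'
#' Per day, the mean (over a gene set) of the between-condition
#' difference curve; with log2 inputs the difference is the log2
#' fold-change. Used to contrast the trajectory of all genes with that
#' of a selected gene set. The `absolute` summary averages `|d|` to
#' measure divergence magnitude irrespective of direction.
#'
#' @param curves a [MeanCurves-class] object.
#' @param geneSet character, nonempty subset of the curve genes.
#' @param summary `"signed"` (default) or `"absolute"`.
#' @param label gene-set label carried into the output.
#' @return data.frame (day, mean_log2fc, gene_set, summary).
#' @export
log2fcTrajectory <- function(curves, geneSet = geneIds(curves),
                             summary = c("signed", "absolute"),
                             label = "gene set") {
  stopifnot(is(curves, "MeanCurves"))
  summary <- match.arg(summary)
  if (!length(geneSet)) stop("'geneSet' must be nonempty", call. = FALSE)
  missing <- setdiff(geneSet, geneIds(curves))
  if (length(missing)) {
    stop(sprintf("unknown gene(s): %s", paste(utils::head(missing, 3L), collapse = ", ")),
         call. = FALSE)
  }
  d <- diffCurves(curves)[geneSet, , drop = FALSE]
  if (summary == "absolute") d <- abs(d)
  data.frame(
    day = days(curves),
    mean_log2fc = unname(colMeans(d)),
    gene_set = label,
    summary = summary,
    stringsAsFactors = FALSE
  )
}
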