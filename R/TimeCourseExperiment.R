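#' @include AllGenerics.R
NULL

#' Construct a TimeCourseExperiment
#'
#' Bundles a genes x samples log2 expression matrix with its sample
#' annotations. Samples belong to one of two conditions (by convention
#' the epididymal-like depot first, e.g. `"epi"`, and the inguinal-like
#' depot second, `"ing"`), were harvested on a common day grid, and are
#' replicated identically within every (condition, day) cell.
#'
#' @param values numeric matrix of log2 intensities, rownames = gene
#'   ids, one column per sample.
#' @param condition character/factor of per-sample condition labels
#'   (exactly two levels).
#' @param day numeric per-sample harvest day.
#' @param replicate integer per-sample replicate index.
#' @param sampleIds optional sample identifiers (default: column names
#'   of `values`, or generated).
#' @return a [TimeCourseExperiment-class] object.
#' @examples
#' sim <- simulateTimecourse(nGenes = 20, seed = 1)
#' tce <- sim$experiment
#' days(tce)
#' conditionLevels(tce)
#' @export
TimeCourseExperiment <- function(values, condition, day, replicate,
                                 sampleIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) {
    sampleIds <- paste(condition, day, replicate, sep = "_")
  }
  colnames(values) <- sampleIds
  cond <- factor(condition)
  if ("epi" %in% levels(cond)) {
    cond <- stats::relevel(cond, "epi")
  }
  cd <- DataFrame(
    condition = cond,
    day = as.numeric(day),
    replicate = as.integer(replicate),
    row.names = sampleIds
  )
  se <- SummarizedExperiment(assays = list(log2expr = values), colData = cd)
  new("TimeCourseExperiment", se)
}

#' @describeIn TimeCourseExperiment day grid (sorted unique days).
#' @param x a `TimeCourseExperiment`.
#' @export
setMethod("days", "TimeCourseExperiment", function(x) {
  sort(unique(as.numeric(colData(x)$day)))
})

#' @describeIn TimeCourseExperiment the two condition labels, first
#'   label defining the sign of downstream difference curves.
#' @export
setMethod("conditionLevels", "TimeCourseExperiment", function(x) {
  levels(factor(colData(x)$condition))
})

#' @describeIn TimeCourseExperiment gene identifiers.
#' @export
setMethod("geneIds", "TimeCourseExperiment", function(x) rownames(x))

#' @describeIn TimeCourseExperiment the log2 expression assay.
#' @export
setMethod("log2Values", "TimeCourseExperiment", function(x) {
  assay(x, "log2expr")
})

setMethod("show", "TimeCourseExperiment", function(object) {
  cd <- colData(object)
  nrep <- unique(as.vector(table(cd$condition, cd$day)))
  cat(sprintf(
    "TimeCourseExperiment: %d genes, %d samples (%s; days %s; %d replicates)\n",
    nrow(object), ncol(object),
    paste(conditionLevels(object), collapse = " vs "),
    paste(days(object), collapse = ","), nrep[1]
  ))
  callNextMethod()
})

setMethod("geneIds", "MeanCurves", function(x) x@genes)
setMethod("days", "MeanCurves", function(x) x@days)
setMethod("conditionLevels", "MeanCurves", function(x) x@conditions)
setMethod("diffCurves", "MeanCurves", function(x) x@diff)
setMethod("meanCurve", "MeanCurves", function(x, condition) {
  if (!condition %in% x@conditions) {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
  x@means[[condition]]
})

setMethod("show", "MeanCurves", function(object) {
  cat(sprintf(
    "MeanCurves: %d genes, days %s; difference = %s - %s\n",
    length(object@genes), paste(object@days, collapse = ","),
    object@conditions[1], object@conditions[2]
  ))
})

setMethod("scoreTable", "GeneScoreTable", function(x) x@table)
setMethod("geneIds", "GeneScoreTable", function(x) x@table$gene)

setMethod("show", "GeneScoreTable", function(object) {
  tab <- object@table
  cat(sprintf(
    "GeneScoreTable: %d genes scored (alpha = %g, instability quantile = %g)\n",
    nrow(tab), object@alpha, object@instabilityQuantile
  ))
  nsig <- sum(tab$sig_dynamic & tab$sig_peak & tab$sig_integral & tab$sig_relevance)
  cat(sprintf("  significant in all four scores: %d; unstable: %d\n",
              nsig, sum(tab$unstable)))
  if (nrow(tab)) {
    cat("  top of table (by consensus):\n")
    print(utils::head(tab[, c("gene", "dynamic", "peak", "relevance", "consensus")], 5L))
  }
})

setMethod("show", "SlopeProfiles", function(object) {
  cat(sprintf(
    "SlopeProfiles: %d observations (%d genes x %d conditions), days %s\n",
    nrow(object@slopes), length(unique(object@gene)),
    length(unique(object@condition)), paste(object@days, collapse = ",")
  ))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel: k = %d over %d slope observations; BSS/TSS = %.3f\n",
    object@k, length(object@cluster), object@bssTss
  ))
  for (i in seq_len(object@k)) {
    cat(sprintf("  cluster %d (n = %d): %s\n", i,
                sum(object@cluster == i), object@patterns[i]))
  }
})

setMethod("congruenceRecords", "CongruenceResult", function(x) x@records)

setMethod("show", "CongruenceResult", function(object) {
  rec <- object@records
  cat(sprintf(
    "CongruenceResult: %d genes; %d congruent, %d divergent dynamics\n",
    nrow(rec), sum(rec$congruent), sum(!rec$congruent)
  ))
  if (!is.na(object@constantCluster)) {
    cat(sprintf("  constant-pattern cluster: %d (%d divergent genes constant on one side)\n",
                object@constantCluster, sum(rec$one_side_constant)))
  }
  cat("  most frequent combinations:\n")
  print(utils::head(object@combinations, 5L))
})
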