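#' @include AllClasses.R
NULL

#' Day grid of an object
#' @param x an object with a day grid.
#' @return numeric vector of days, strictly increasing.
#' @export
setGeneric("days", function(x) standardGeneric("days"))

#' Condition levels of an object
#' @param x an object with two experimental conditions.
#' @return character vector of length 2.
#' @export
setGeneric("conditionLevels", function(x) standardGeneric("conditionLevels"))

#' Gene identifiers of an object
#' @param x an object carrying per-gene data.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Log2 expression matrix
#' @param x a `TimeCourseExperiment`.
#' @return numeric genes x samples matrix.
#' @export
setGeneric("log2Values", function(x) standardGeneric("log2Values"))

#' Difference curves (log2 fold-change per day)
#' @param x a `MeanCurves` object.
#' @return genes x days matrix of condition-mean differences.
#' @export
setGeneric("diffCurves", function(x) standardGeneric("diffCurves"))

#' Condition-mean expression matrix
#' @param x a `MeanCurves` object.
#' @param condition condition label.
#' @return genes x days matrix of replicate-averaged log2 values.
#' @export
setGeneric("meanCurve", function(x, condition) standardGeneric("meanCurve"))

#' Score table of a `GeneScoreTable`
#' @param x a `GeneScoreTable`.
#' @return data.frame of per-gene scores, flags and consensus.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' Per-gene congruence records
#' @param x a `CongruenceResult`.
#' @return data.frame with one row per gene.
#' @export
setGeneric("congruenceRecords", function(x) standardGeneric("congruenceRecords"))

#' Select stable multi-score-significant candidate genes
#'
#' Genes significant in all four divergence scores (dynamic, peak,
#' integral in at least one interval, relevance) that do not show
#' significant replicate instability.
#'
#' @param x a `GeneScoreTable` (or its score table as a data.frame).
#' @return character vector of candidate gene ids.
#' @export
setGeneric("selectCandidates", function(x) standardGeneric("selectCandidates"))
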