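#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' TimeCourseExperiment: a two-condition differentiation time course
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a
#' `log2expr` assay (genes x samples, log2 intensities) and sample
#' annotations `condition` (two levels, e.g. `epi`/`ing`), `day`
#' (position on the differentiation day grid) and `replicate`.
#' The design must be complete and balanced: every (condition, day)
#' cell carries the same number of replicates.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
  cd <- colData(object)
  need <- c("condition", "day", "replicate")
  if (!all(need %in% colnames(cd))) {
    return(sprintf("colData must contain columns: %s",
                   paste(need, collapse = ", ")))
  }
  if (length(SummarizedExperiment::assayNames(object)) < 1L ||
      !"log2expr" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'log2expr' is required")
  }
  x <- assay(object, "log2expr")
  if (!all(is.finite(x))) {
    return("all log2 expression values must be finite (missing values are not supported)")
  }
  cond <- factor(cd$condition)
  if (nlevels(cond) != 2L) {
    return("exactly two condition levels are required")
  }
  day <- as.numeric(cd$day)
  if (anyNA(day)) return("'day' must be numeric")
  tab <- table(cond, day)
  if (any(tab == 0L)) return("every (condition, day) cell needs at least one sample")
  if (length(unique(as.vector(tab))) != 1L) {
    return("replicate counts must be identical across (condition, day) cells")
  }
  if (is.null(rownames(object))) return("gene identifiers (rownames) are required")
  if (anyDuplicated(rownames(object))) return("gene identifiers must be unique")
  TRUE
})

#' MeanCurves: replicate-averaged expression profiles per condition
#'
#' Holds, per gene and condition, the arithmetic mean log2 expression at
#' each day of the grid, together with the derived difference curve
#' `d(day) = mean(first condition) - mean(second condition)` (log2
#' fold-change when the first condition is `epi` and the second `ing`).
#'
#' @slot genes character, gene identifiers.
#' @slot days numeric, strictly increasing day grid.
#' @slot conditions character of length 2; the difference curve is
#'   `conditions[1] - conditions[2]`.
#' @slot means named list of two genes x days matrices.
#' @slot diff genes x days matrix of difference curves.
#' @export
setClass("MeanCurves", representation(
  genes = "character",
  days = "numeric",
  conditions = "character",
  means = "list",
  diff = "matrix"
))

setValidity("MeanCurves", function(object) {
  if (length(object@conditions) != 2L) return("exactly two conditions required")
  if (!identical(sort(names(object@means)), sort(object@conditions))) {
    return("'means' must be named by the two conditions")
  }
  if (is.unsorted(object@days, strictly = TRUE)) {
    return("'days' must be strictly increasing")
  }
  dims <- c(length(object@genes), length(object@days))
  for (m in object@means) {
    if (!identical(dim(m), as.integer(dims))) return("mean matrix dimensions must be genes x days")
  }
  if (!identical(dim(object@diff), as.integer(dims))) {
    return("'diff' dimensions must be genes x days")
  }
  TRUE
})

#' SlopeProfiles: finite-difference slope vectors per gene and condition
#'
#' One row per (gene, condition) observation; columns are the per-day
#' slopes of the condition-mean expression profile (log2 units per day),
#' central differences at interior days and one-sided differences at the
#' endpoints.
#'
#' @slot slopes numeric matrix, observations x days.
#' @slot gene character, gene of each row.
#' @slot condition character, condition of each row.
#' @slot days numeric day grid.
#' @export
setClass("SlopeProfiles", representation(
  slopes = "matrix",
  gene = "character",
  condition = "character",
  days = "numeric"
))

setValidity("SlopeProfiles", function(object) {
  n <- nrow(object@slopes)
  if (length(object@gene) != n || length(object@condition) != n) {
    return("'gene' and 'condition' must have one entry per slope row")
  }
  if (ncol(object@slopes) != length(object@days)) {
    return("slope columns must match the day grid")
  }
  TRUE
})

#' ClusterModel: k-means fit in expression-slope space
#'
#' Result of [fitKmeans()]: centroids in slope space, the cluster
#' assignment of every (gene, condition) observation, the between-SS /
#' total-SS compactness diagnostic, and a schematic
#' rise/constant/fall pattern label per centroid.
#'
#' @slot k integer, number of clusters.
#' @slot centroids k x days matrix of slope-space centroids.
#' @slot cluster integer assignment per observation (1..k).
#' @slot gene,condition character, observation annotations.
#' @slot bssTss numeric, between-SS over total-SS.
#' @slot totWithinss numeric, total within-cluster SS of the chosen fit.
#' @slot patterns character, schematic pattern label per centroid.
#' @slot seed,nRestarts integer, fitting parameters.
#' @slot days numeric day grid.
#' @export
setClass("ClusterModel", representation(
  k = "integer",
  centroids = "matrix",
  cluster = "integer",
  gene = "character",
  condition = "character",
  bssTss = "numeric",
  totWithinss = "numeric",
  patterns = "character",
  seed = "integer",
  nRestarts = "integer",
  days = "numeric"
))

setValidity("ClusterModel", function(object) {
  if (object@bssTss < -1e-8 || object@bssTss > 1 + 1e-8) {
    return("'bssTss' must lie in [0, 1]")
  }
  if (any(object@cluster < 1L | object@cluster > object@k)) {
    return("cluster assignments must lie in 1..k")
  }
  if (nrow(object@centroids) != object@k) return("one centroid per cluster required")
  TRUE
})

#' CongruenceResult: congruent vs divergent dynamics per gene
#'
#' Result of [congruenceClassification()]: per gene, the cluster its
#' slope profile fell into under each condition, whether the two
#' clusters agree (congruent dynamics: same shape, possibly different
#' level), the schematic pattern of each side, and a tally of the
#' occurring cluster combinations.
#'
#' @slot records data.frame with one row per gene: `gene`,
#'   `cluster_epi`, `cluster_ing`, `congruent`, `pattern_epi`,
#'   `pattern_ing`, `combination`, `one_side_constant`.
#' @slot combinations data.frame tallying combinations, sorted by count.
#' @slot constantCluster integer id of the all-constant cluster (NA if
#'   no centroid collapses to the "constant" pattern).
#' @export
setClass("CongruenceResult", representation(
  records = "data.frame",
  combinations = "data.frame",
  constantCluster = "integer"
))

#' GeneScoreTable: divergence scores, flags and consensus per gene
#'
#' Result of [scoreGenes()]. The score table carries, per gene, the
#' dynamic (drift), peak (transient), interval-integral and literature
#' relevance scores, the replicate-instability index, the per-score
#' robust-z significance flags, the instability flag, and the consensus
#' score in [0, 1]; rows are sorted by consensus, descending.
#'
#' @slot table data.frame of scores and flags.
#' @slot alpha numeric, per-score significance level.
#' @slot instabilityQuantile numeric, quantile defining instability.
#' @slot intervals named list of interval day bounds.
#' @export
setClass("GeneScoreTable", representation(
  table = "data.frame",
  alpha = "numeric",
  instabilityQuantile = "numeric",
  intervals = "list"
))

setValidity("GeneScoreTable", function(object) {
  tab <- object@table
  need <- c("gene", "dynamic", "peak", "relevance", "instability_index",
            "sig_dynamic", "sig_peak", "sig_integral", "sig_relevance",
            "unstable", "consensus")
  if (!all(need %in% colnames(tab))) {
    return(sprintf("score table must contain columns: %s",
                   paste(setdiff(need, colnames(tab)), collapse = ", ")))
  }
  if (nrow(tab) && (min(tab$consensus) < -1e-12 || max(tab$consensus) > 1 + 1e-12)) {
    return("consensus scores must lie in [0, 1]")
  }
  TRUE
})
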