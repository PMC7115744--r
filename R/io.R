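# Tab-separated input/output for every pipeline stage. All tables are
# TSV with a header row; gene ids are opaque strings.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a time-course experiment as TSV
#'
#' The expression table has the gene id in the first column and one
#' column per sample; the sample sheet maps sample ids to condition,
#' day and replicate.
#'
#' @param experiment a [TimeCourseExperiment-class].
#' @param exprPath,samplesPath output/input file paths.
#' @return `writeTimecourse`: the paths, invisibly; `readTimecourse`:
#'   a [TimeCourseExperiment-class].
#' @export
writeTimecourse <- function(experiment, exprPath, samplesPath) {
  x <- log2Values(experiment)
  .writeTsv(data.frame(gene = rownames(x), x, check.names = FALSE), exprPath)
  cd <- colData(experiment)
  .writeTsv(data.frame(sample_id = rownames(cd),
                       condition = as.character(cd$condition),
                       day = cd$day, replicate = cd$replicate), samplesPath)
  invisible(c(exprPath, samplesPath))
}

#' @rdname writeTimecourse
#' @export
readTimecourse <- function(exprPath, samplesPath) {
  expr <- .readTsv(exprPath)
  ss <- .readTsv(samplesPath)
  values <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(values) <- expr[[1L]]
  values <- values[, ss$sample_id, drop = FALSE]
  TimeCourseExperiment(values, ss$condition, ss$day, ss$replicate,
                       sampleIds = ss$sample_id)
}

#' Write / read a long DABG p-value table
#' @param dabg data.frame (gene, exon, sample, p).
#' @param path file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
writeDabgTable <- function(dabg, path) .writeTsv(dabg, path)

#' @rdname writeDabgTable
#' @export
readDabgTable <- function(path) .readTsv(path)

#' Write / read a cohort table
#' @param cohort data.frame as produced by [simulateCohort()].
#' @param path file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
writeCohort <- function(cohort, path) .writeTsv(cohort, path)

#' @rdname writeCohort
#' @export
readCohort <- function(path) .readTsv(path)

#' Write / read a gene -> publication count table
#' @param counts data.frame (gene, count).
#' @param path file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
writeLiteratureCounts <- function(counts, path) .writeTsv(counts, path)

#' @rdname writeLiteratureCounts
#' @export
readLiteratureCounts <- function(path) .readTsv(path)

#' Write / read a plain gene list (one id per line, no header)
#' @param genes character vector.
#' @param path file path.
#' @return the genes (read) or the path, invisibly (write).
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname writeGeneList
#' @export
readGeneList <- function(path) readLines(path)
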