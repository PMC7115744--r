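# End-to-end orchestration: simulate -> filter -> score -> cluster ->
# cohort validation, with a machine-readable run report.

#' Pipeline configuration with study-condition defaults
#'
#' Collects every stage parameter with defaults matching the study
#' design where one is stated (alpha 0.05, k = 8, vis/sc ratio cutoff
#' 0.4, triplicates on days -2..8) and the package's fixed simulation
#' conditions otherwise. A single global seed is fanned out to
#' per-stage seeds by fixed offsets so each stage is individually
#' reproducible.
#'
#' @param nGenes,fractionDivergent,noiseSd,nReplicates,amplitudeRange
#'   simulation parameters (see [simulateTimecourse()]).
#' @param fractionExpressed fraction of genes marked DABG-expressed.
#' @param nExonsPerGene exons per gene in the simulated DABG table.
#' @param alpha per-score significance level (also the DABG detection
#'   level).
#' @param instabilityQuantile instability flagging quantile.
#' @param k,nRestarts,epsilon clustering parameters (see [fitKmeans()]).
#' @param clusterGenes which genes to cluster: `"candidates"` (the
#'   137-style stable multi-score-significant set, the default) or
#'   `"expressed"`.
#' @param cohortSize,targetRho cohort stage: cohort size and the target
#'   Spearman correlation of each top gene's sc expression with BMI.
#' @param ratioCutoff,leanBmiCutoff obesity-group cutoffs.
#' @param seed global integer seed.
#' @param outDir output directory (created if needed).
#' @return named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(nGenes = 2000,
                           fractionDivergent = 0.05,
                           noiseSd = 0.25,
                           nReplicates = 3,
                           amplitudeRange = c(2, 4),
                           fractionExpressed = 0.95,
                           nExonsPerGene = 4,
                           alpha = 0.05,
                           instabilityQuantile = 0.95,
                           k = 8,
                           nRestarts = 25,
                           epsilon = "auto",
                           clusterGenes = c("candidates", "expressed"),
                           cohortSize = 63,
                           targetRho = -0.5,
                           ratioCutoff = 0.4,
                           leanBmiCutoff = 30,
                           seed = 1,
                           outDir = tempfile("adipodyn_run")) {
  cfg <- list(
    nGenes = nGenes, fractionDivergent = fractionDivergent,
    noiseSd = noiseSd, nReplicates = nReplicates,
    amplitudeRange = amplitudeRange,
    fractionExpressed = fractionExpressed, nExonsPerGene = nExonsPerGene,
    alpha = alpha, instabilityQuantile = instabilityQuantile,
    k = k, nRestarts = nRestarts, epsilon = epsilon,
    clusterGenes = match.arg(clusterGenes),
    cohortSize = cohortSize, targetRho = targetRho,
    ratioCutoff = ratioCutoff, leanBmiCutoff = leanBmiCutoff,
    seed = as.integer(seed), outDir = outDir
  )
  class(cfg) <- "pipelineConfig"
  cfg
}

.stageSeed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes all stages in order: simulate the time course, DABG table,
#' literature counts and cohort; filter expressed genes; compute the
#' four divergence scores, flags and consensus; select the stable
#' multi-score-significant candidates and the upper-quartile top set;
#' cluster slope vectors and classify congruent vs divergent dynamics;
#' and run the cohort association statistics for the top genes. Every
#' stage output is written to `config$outDir` as TSV; identical config
#' and seed give identical outputs.
#'
#' @param config a [pipelineConfig()] list.
#' @return a run report (list): per-stage gene `counts`, the `files`
#'   manifest, the Figure-style `trajectory` table (all vs selected
#'   genes), the candidate/top gene sets, the `config` echo and `seed`.
#' @examples
#' \donttest{
#' rep <- runPipeline(pipelineConfig(nGenes = 300, seed = 1))
#' rep$counts
#' }
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  manifest <- character()
  note <- character()

  # -- simulate ------------------------------------------------------
  sim <- simulateTimecourse(
    nGenes = config$nGenes, fractionDivergent = config$fractionDivergent,
    amplitudeRange = config$amplitudeRange, noiseSd = config$noiseSd,
    nReplicates = config$nReplicates, seed = .stageSeed(config$seed, 0L)
  )
  experiment <- sim$experiment
  truth <- sim$truth
  nExpr <- round(config$fractionExpressed * config$nGenes)
  expressedTruth <- withSeed(.stageSeed(config$seed, 1L), {
    sample(truth$gene, nExpr)
  })
  dabg <- simulateDabg(experiment, nExonsPerGene = config$nExonsPerGene,
                       expressedGenes = expressedTruth, alpha = config$alpha,
                       seed = .stageSeed(config$seed, 2L))
  lit <- simulateLiteratureCounts(truth$gene,
                                  associated = truth$gene[truth$divergent],
                                  seed = .stageSeed(config$seed, 3L))
  writeTimecourse(experiment, out("expression.tsv"), out("samples.tsv"))
  writeDabgTable(dabg, out("dabg.tsv"))
  writeLiteratureCounts(lit, out("literature_counts.tsv"))
  .writeTsv(truth, out("ground_truth.tsv"))
  manifest <- c(manifest, out(c("expression.tsv", "samples.tsv", "dabg.tsv",
                                "literature_counts.tsv", "ground_truth.tsv")))

  # -- filter --------------------------------------------------------
  expressed <- filterExpressedGenes(dabg, alpha = config$alpha)
  writeGeneList(expressed, out("expressed_genes.txt"))
  manifest <- c(manifest, out("expressed_genes.txt"))
  exprTce <- experiment[expressed, ]

  # -- score ---------------------------------------------------------
  scores <- scoreGenes(exprTce, litCounts = lit, alpha = config$alpha,
                       instabilityQuantile = config$instabilityQuantile)
  tab <- scoreTable(scores)
  .writeTsv(tab, out("score_table.tsv"))
  candidates <- selectCandidates(scores)
  writeGeneList(candidates, out("candidate_genes.txt"))
  if (length(candidates)) {
    topSet <- selectTopSet(stats::setNames(
      tab$consensus[match(candidates, tab$gene)], candidates))
  } else {
    topSet <- character()
    note <- c(note, "no candidate genes; downstream stages are empty")
  }
  writeGeneList(topSet, out("top_genes.txt"))
  manifest <- c(manifest, out(c("score_table.tsv", "candidate_genes.txt",
                                "top_genes.txt")))

  # -- trajectory summary (all vs selected) --------------------------
  curves <- conditionMeanCurves(exprTce)
  trajectory <- rbind(
    log2fcTrajectory(curves, label = "all", summary = "signed"),
    log2fcTrajectory(curves, label = "all", summary = "absolute"),
    if (length(candidates)) {
      rbind(
        log2fcTrajectory(curves, candidates, label = "selected", summary = "signed"),
        log2fcTrajectory(curves, candidates, label = "selected", summary = "absolute")
      )
    }
  )
  .writeTsv(trajectory, out("trajectory.tsv"))
  manifest <- c(manifest, out("trajectory.tsv"))

  # -- cluster -------------------------------------------------------
  clusterSet <- if (config$clusterGenes == "candidates") candidates else expressed
  congruence <- NULL
  model <- NULL
  if (length(clusterSet) >= max(1L, ceiling(config$k / 2))) {
    profiles <- slopeVectors(conditionMeanCurves(experiment[clusterSet, ]))
    model <- fitKmeans(profiles, k = config$k,
                       seed = .stageSeed(config$seed, 4L),
                       nRestarts = config$nRestarts,
                       epsilon = config$epsilon)
    congruence <- congruenceClassification(model)
    .writeTsv(congruenceRecords(congruence), out("congruence.tsv"))
    .writeTsv(congruence@combinations, out("cluster_combinations.tsv"))
    .writeTsv(data.frame(cluster = seq_len(model@k),
                         pattern = model@patterns,
                         unname(as.data.frame(model@centroids))),
              out("cluster_centroids.tsv"))
    .writeTsv(data.frame(gene = model@gene, condition = model@condition,
                         cluster = model@cluster),
              out("cluster_assignments.tsv"))
    manifest <- c(manifest, out(c("congruence.tsv", "cluster_combinations.tsv",
                                  "cluster_centroids.tsv", "cluster_assignments.tsv")))
  } else {
    note <- c(note, "too few genes to cluster; clustering stage skipped")
  }

  # -- cohort validation --------------------------------------------
  association <- NULL
  groupTests <- NULL
  if (length(topSet)) {
    targets <- data.frame(gene = topSet, depot = "sc", phenotype = "bmi",
                          rho = config$targetRho, stringsAsFactors = FALSE)
    cohortSim <- simulateCohort(nSubjects = config$cohortSize, genes = topSet,
                                targets = targets,
                                leanBmiCutoff = config$leanBmiCutoff,
                                seed = .stageSeed(config$seed, 5L))
    cohort <- cohortSim$cohort
    writeCohort(cohort, out("cohort.tsv"))
    association <- associationTable(cohort, topSet)
    .writeTsv(association, out("association.tsv"))
    groups <- assignGroups(cohort, config$ratioCutoff, config$leanBmiCutoff)
    groupTests <- groupComparisonTable(cohort, topSet, groups)
    .writeTsv(groupTests, out("group_tests.tsv"))
    manifest <- c(manifest, out(c("cohort.tsv", "association.tsv",
                                  "group_tests.tsv")))
  }

  counts <- list(
    simulated = config$nGenes,
    expressed = length(expressed),
    scored = nrow(tab),
    candidates = length(candidates),
    top_set = length(topSet),
    congruent = if (is.null(congruence)) 0L else sum(congruenceRecords(congruence)$congruent),
    divergent_dynamics = if (is.null(congruence)) 0L else sum(!congruenceRecords(congruence)$congruent)
  )
  stopifnot(all(topSet %in% candidates), all(candidates %in% expressed))

  report <- list(
    counts = counts,
    files = manifest,
    trajectory = trajectory,
    candidates = candidates,
    topSet = topSet,
    bssTss = if (is.null(model)) NA_real_ else model@bssTss,
    notes = note,
    config = unclass(config),
    seed = config$seed
  )
  class(report) <- "adipoDynReport"
  report
}

#' @export
print.adipoDynReport <- function(x, ...) {
  cat("adipoDyn pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  genes: %d simulated -> %d expressed -> %d candidates -> %d top\n",
              x$counts$simulated, x$counts$expressed,
              x$counts$candidates, x$counts$top_set))
  cat(sprintf("  dynamics: %d congruent, %d divergent (BSS/TSS %.3f)\n",
              x$counts$congruent, x$counts$divergent_dynamics, x$bssTss))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a pipeline run report
#'
#' Writes a human-readable summary (`run_summary.txt`), a
#' machine-readable JSON report (`run_report.json`) with the stage
#' counts, seed, config echo and file manifest, and the trajectory
#' table (`trajectory.tsv`). Warns (but succeeds) when the candidate
#' set was empty.
#'
#' @param report a report from [runPipeline()].
#' @param dir output directory (default: the run's output directory).
#' @return character vector of files written, invisibly.
#' @export
writeReport <- function(report, dir = report$config$outDir) {
  stopifnot(inherits(report, "adipoDynReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summaryPath <- file.path(dir, "run_summary.txt")
  jsonPath <- file.path(dir, "run_report.json")
  trajPath <- file.path(dir, "trajectory.tsv")

  lines <- c(
    sprintf("adipoDyn pipeline run (seed %d)", report$seed),
    sprintf("genes simulated:        %d", report$counts$simulated),
    sprintf("expressed (DABG):       %d", report$counts$expressed),
    sprintf("candidates (all-score): %d", report$counts$candidates),
    sprintf("top set (upper Q):      %d", report$counts$top_set),
    sprintf("congruent dynamics:     %d", report$counts$congruent),
    sprintf("divergent dynamics:     %d", report$counts$divergent_dynamics),
    if (length(report$notes)) paste("note:", report$notes) else character()
  )
  writeLines(lines, summaryPath)

  jsonlite::write_json(
    list(seed = report$seed, counts = report$counts,
         bss_tss = report$bssTss, notes = report$notes,
         files = report$files,
         config = report$config[setdiff(names(report$config), "outDir")]),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  .writeTsv(report$trajectory, trajPath)

  if (report$counts$candidates == 0L) {
    warning("pipeline produced no candidate genes; downstream stages are empty")
  }
  invisible(c(summaryPath, jsonPath, trajPath))
}
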