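#' Simulate a two-depot differentiation time course with known truth
#'
#' Generates a balanced two-condition (epi vs ing) time-course
#' experiment on a day grid. Each gene follows, per condition, one of
#' the eight schematic trajectory archetypes ([archetypeShapes()])
#' scaled by a gene-specific amplitude on top of a gene-specific
#' baseline; replicates add i.i.d. Gaussian noise on the log2 scale.
#' A configurable fraction of genes is made divergent: those genes
#' receive distinct archetypes (and independent amplitudes) in the two
#' conditions, with the maximal between-condition difference of their
#' noise-free mean curves enforced to be at least `minDivergentGap`
#' log2 units. All remaining genes share archetype, amplitude and
#' baseline across conditions, so their expected difference curve is
#' identically zero.
#'
#' @param nGenes number of genes (> 0).
#' @param fractionDivergent proportion of genes with divergent dynamics
#'   between conditions, in `[0, 1]`.
#' @param amplitudeRange range (log2 units) from which per-condition
#'   trajectory amplitudes are drawn uniformly.
#' @param noiseSd replicate noise standard deviation (log2 units, >= 0).
#' @param nReplicates replicates per (condition, day) cell (> 0).
#' @param days strictly increasing day grid.
#' @param baselineRange range of uniform per-gene baseline log2 levels.
#' @param baselineOffsetSd standard deviation of an optional
#'   condition-specific baseline offset (default 0: both conditions
#'   share the gene baseline).
#' @param minDivergentGap minimal max-over-days absolute difference
#'   (log2 units) between the two noise-free condition means of a
#'   divergent gene; amplitudes are scaled up jointly to enforce it.
#' @param amplitudeMargin amplitude-ratio band inside which two equal
#'   archetypes still count as non-divergent ground truth.
#' @param conditions the two condition labels.
#' @param seed integer RNG seed; identical configuration and seed give
#'   bit-identical output.
#' @return list with `experiment` (a [TimeCourseExperiment-class]) and
#'   `truth` (data.frame: gene, archetype/baseline/amplitude per
#'   condition, and the deterministic `divergent` flag).
#' @examples
#' sim <- simulateTimecourse(nGenes = 100, fractionDivergent = 0.1, seed = 1)
#' sum(sim$truth$divergent)
#' @export
simulateTimecourse <- function(nGenes,
                               fractionDivergent = 0.05,
                               amplitudeRange = c(2, 4),
                               noiseSd = 0.25,
                               nReplicates = 3,
                               days = c(-2, 0, 2, 4, 6, 8),
                               baselineRange = c(6, 12),
                               baselineOffsetSd = 0,
                               minDivergentGap = 2,
                               amplitudeMargin = c(0.8, 1.25),
                               conditions = c("epi", "ing"),
                               seed = 1) {
  if (!is.numeric(nGenes) || length(nGenes) != 1L || nGenes < 1) {
    stop("'nGenes' must be a positive count", call. = FALSE)
  }
  if (!is.numeric(nReplicates) || length(nReplicates) != 1L || nReplicates < 1) {
    stop("'nReplicates' must be a positive count", call. = FALSE)
  }
  assertScalarProb(fractionDivergent, "fractionDivergent",
                   openLeft = FALSE, openRight = FALSE)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("'days' must be strictly increasing", call. = FALSE)
  }
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    stop("'conditions' must be two distinct labels", call. = FALSE)
  }
  nGenes <- as.integer(nGenes)
  nReplicates <- as.integer(nReplicates)
  archNames <- names(.ARCHETYPES)
  templates <- vapply(archNames, archetypeTemplate, numeric(length(days)),
                      days = days)          # days x archetypes
  genes <- sprintf("gene%04d", seq_len(nGenes))

  withSeed(seed, {
    nDiv <- as.integer(round(fractionDivergent * nGenes))
    divergent <- logical(nGenes)
    divergent[sample.int(nGenes, nDiv)] <- TRUE

    archIng <- sample(archNames, nGenes, replace = TRUE)
    archEpi <- archIng
    if (nDiv > 0L) {
      archEpi[divergent] <- vapply(archIng[divergent], function(a) {
        sample(setdiff(archNames, a), 1L)
      }, character(1))
    }
    ampIng <- stats::runif(nGenes, amplitudeRange[1], amplitudeRange[2])
    ampEpi <- ampIng
    ampEpi[divergent] <- stats::runif(nDiv, amplitudeRange[1], amplitudeRange[2])
    baseline <- stats::runif(nGenes, baselineRange[1], baselineRange[2])
    offEpi <- if (baselineOffsetSd > 0) stats::rnorm(nGenes, 0, baselineOffsetSd) else numeric(nGenes)
    offIng <- if (baselineOffsetSd > 0) stats::rnorm(nGenes, 0, baselineOffsetSd) else numeric(nGenes)

    # Enforce the dynamic gap for divergent genes (joint scaling keeps
    # the amplitude ratio, hence the ground-truth flag, unchanged).
    if (nDiv > 0L && minDivergentGap > 0) {
      for (g in which(divergent)) {
        gap <- max(abs(ampEpi[g] * templates[, archEpi[g]] -
                         ampIng[g] * templates[, archIng[g]]))
        if (gap > 0 && gap < minDivergentGap) {
          s <- minDivergentGap / gap
          ampEpi[g] <- ampEpi[g] * s
          ampIng[g] <- ampIng[g] * s
        }
      }
    }

    meanEpi <- baseline + offEpi + ampEpi * t(templates[, archEpi, drop = FALSE])
    meanIng <- baseline + offIng + ampIng * t(templates[, archIng, drop = FALSE])

    grid <- expand.grid(replicate = seq_len(nReplicates), day = days,
                        condition = conditions, stringsAsFactors = FALSE)
    nSamp <- nrow(grid)
    values <- matrix(0, nGenes, nSamp)
    dayIdx <- match(grid$day, days)
    for (j in seq_len(nSamp)) {
      mu <- if (grid$condition[j] == conditions[1]) meanEpi[, dayIdx[j]] else meanIng[, dayIdx[j]]
      values[, j] <- mu + if (noiseSd > 0) stats::rnorm(nGenes, 0, noiseSd) else 0
    }
    rownames(values) <- genes
    sampleIds <- paste(grid$condition, grid$day, grid$replicate, sep = "_")

    truth <- data.frame(
      gene = genes,
      archetype_epi = archEpi,
      archetype_ing = archIng,
      baseline_epi = baseline + offEpi,
      baseline_ing = baseline + offIng,
      amplitude_epi = ampEpi,
      amplitude_ing = ampIng,
      stringsAsFactors = FALSE
    )
    truth$divergent <- isDivergent(truth, amplitudeMargin)
    stopifnot(identical(truth$divergent, divergent))

    experiment <- TimeCourseExperiment(values, grid$condition, grid$day,
                                       grid$replicate, sampleIds)
    list(experiment = experiment, truth = truth)
  })
}

#' Ground-truth divergence flag from generating parameters
#'
#' A gene is divergent iff its two conditions use different archetypes,
#' or the amplitude ratio falls outside the stated margin.
#'
#' @param truth data.frame with `archetype_epi`, `archetype_ing`,
#'   `amplitude_epi`, `amplitude_ing`.
#' @param amplitudeMargin length-2 ratio band treated as equal.
#' @return logical vector.
#' @export
isDivergent <- function(truth, amplitudeMargin = c(0.8, 1.25)) {
  ratio <- truth$amplitude_epi / truth$amplitude_ing
  truth$archetype_epi != truth$archetype_ing |
    ratio < amplitudeMargin[1] | ratio > amplitudeMargin[2]
}

#' Simulate a per-exon detection-above-background p-value table
#'
#' Emulates DABG (detection above background) testing: genes in
#' `expressedGenes` receive p < 0.05 for at least half of their exons
#' in one randomly chosen sample (uniform on `[0, alpha)` there), all
#' other (gene, exon, sample) cells draw p uniformly on `[alpha, 1]`.
#' By construction [filterExpressedGenes()] at the default thresholds
#' recovers exactly `expressedGenes`.
#'
#' @param experiment a [TimeCourseExperiment-class] (defines genes and
#'   samples).
#' @param nExonsPerGene exons per gene (>= 1).
#' @param expressedGenes character, subset of the experiment's genes to
#'   mark as expressed.
#' @param alpha detection threshold the table is constructed around.
#' @param seed integer RNG seed.
#' @return long data.frame (gene, exon, sample, p).
#' @export
simulateDabg <- function(experiment, nExonsPerGene = 4,
                         expressedGenes = geneIds(experiment),
                         alpha = 0.05, seed = 1) {
  if (nExonsPerGene < 1) stop("'nExonsPerGene' must be >= 1", call. = FALSE)
  genes <- geneIds(experiment)
  unknown <- setdiff(expressedGenes, genes)
  if (length(unknown)) {
    stop(sprintf("unknown gene(s) in 'expressedGenes': %s",
                 paste(utils::head(unknown, 3L), collapse = ", ")), call. = FALSE)
  }
  samples <- colnames(experiment)
  nExonsPerGene <- as.integer(nExonsPerGene)
  tab <- expand.grid(
    exon = seq_len(nExonsPerGene),
    gene = genes,
    sample = samples,
    stringsAsFactors = FALSE
  )[, c("gene", "exon", "sample")]
  tab$exon <- paste0("exon", tab$exon)
  withSeed(seed, {
    tab$p <- stats::runif(nrow(tab), alpha, 1)
    nHit <- as.integer(ceiling(nExonsPerGene / 2))
    for (g in expressedGenes) {
      s <- sample(samples, 1L)
      exons <- sample(nExonsPerGene, nHit)
      idx <- which(tab$gene == g & tab$sample == s &
                     tab$exon %in% paste0("exon", exons))
      tab$p[idx] <- stats::runif(length(idx), 0, alpha * 0.999)
    }
    tab
  })
}

#' Simulate informative literature counts for a stimulus term
#'
#' Emulates an offline gene-to-publication-count table for a query term
#' such as "fat distribution": associated genes (by default the
#' ground-truth divergent set of a simulated experiment) receive high
#' Poisson counts, background genes are mostly unpublished for the
#' term with occasional small counts.
#'
#' @param genes character, all gene ids.
#' @param associated character, genes with genuine literature support.
#' @param associatedMean Poisson mean of associated-gene counts (an
#'   offset of 3 guarantees a nonzero count).
#' @param backgroundRate probability a background gene has any count.
#' @param backgroundMean Poisson mean of nonzero background counts.
#' @param seed integer RNG seed.
#' @return data.frame (gene, count).
#' @export
simulateLiteratureCounts <- function(genes, associated = character(),
                                     associatedMean = 20,
                                     backgroundRate = 0.1,
                                     backgroundMean = 2,
                                     seed = 1) {
  unknown <- setdiff(associated, genes)
  if (length(unknown)) {
    stop("'associated' must be a subset of 'genes'", call. = FALSE)
  }
  withSeed(seed, {
    count <- ifelse(stats::runif(length(genes)) < backgroundRate,
                    stats::rpois(length(genes), backgroundMean), 0L)
    hit <- genes %in% associated
    count[hit] <- 3L + stats::rpois(sum(hit), associatedMean)
    data.frame(gene = genes, count = as.integer(count), stringsAsFactors = FALSE)
  })
}

#' Simulate a paired visceral/subcutaneous adipose cohort
#'
#' Generates one row per subject with age, sex, BMI, waist-to-hip ratio
#' (WHR), visceral-to-subcutaneous fat area ratio, and per-gene
#' expression in both depots. Subjects are constructed group-first
#' (lean / sc obese / vis obese) so that [assignGroups()] at the
#' default cutoffs recovers the configured group sizes exactly.
#' Expression is coupled to a phenotype through a shared latent
#' Gaussian whose Pearson correlation `r = 2*sin(pi*rho/6)` targets the
#' requested Spearman `rho`; a monotone transform to an expression-like
#' scale leaves rank correlations untouched, so the sample Spearman
#' correlation approaches the target as n grows and equals `+/-1`
#' exactly for `rho = +/-1`.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param groupSizes named counts for lean / sc_obese / vis_obese,
#'   summing to `nSubjects`.
#' @param ageMean,ageSd,ageRange truncated-normal age parameters (years).
#' @param pFemale proportion of female subjects.
#' @param bmiMean,bmiSd,bmiRange truncated-normal BMI parameters
#'   (kg/m^2); lean subjects are additionally truncated below
#'   `leanBmiCutoff`, obese subjects above it.
#' @param leanBmiCutoff BMI below which a subject is lean.
#' @param whrMean,whrSd,whrRange truncated-normal WHR parameters.
#' @param genes character, gene ids to simulate expression for.
#' @param targets optional data.frame (gene, depot in sc/vis, phenotype
#'   in bmi/whr, rho) of target Spearman correlations; unlisted
#'   gene-depot pairs are uncorrelated.
#' @param exprBase,exprScale location/scale of the expression transform.
#' @param missingRate per-cell probability of a missing expression value.
#' @param seed integer RNG seed.
#' @return list with `cohort` (data.frame; expression columns are named
#'   `<gene>_<depot>`) and `truth` (group labels and the target table).
#' @examples
#' cc <- simulateCohort(genes = "Alx1",
#'                      targets = data.frame(gene = "Alx1", depot = "sc",
#'                                           phenotype = "bmi", rho = -0.6),
#'                      seed = 1)
#' nrow(cc$cohort)
#' @export
simulateCohort <- function(nSubjects = 63,
                           groupSizes = c(lean = 25, sc_obese = 21, vis_obese = 17),
                           ageMean = 53, ageSd = 16, ageRange = c(18, 90),
                           pFemale = 47 / 63,
                           bmiMean = 36.1, bmiSd = 14, bmiRange = c(15, 70),
                           leanBmiCutoff = 30,
                           whrMean = 0.953, whrSd = 0.149, whrRange = c(0.5, 1.5),
                           genes = character(),
                           targets = NULL,
                           exprBase = 8, exprScale = 1.5,
                           missingRate = 0,
                           seed = 1) {
  if (nSubjects < 3) stop("'nSubjects' must be >= 3", call. = FALSE)
  if (!setequal(names(groupSizes), c("lean", "sc_obese", "vis_obese"))) {
    stop("'groupSizes' must be named lean, sc_obese, vis_obese", call. = FALSE)
  }
  if (sum(groupSizes) != nSubjects) {
    stop("'groupSizes' must sum to 'nSubjects'", call. = FALSE)
  }
  if (!is.null(targets)) {
    need <- c("gene", "depot", "phenotype", "rho")
    if (!all(need %in% colnames(targets))) {
      stop("'targets' needs columns gene, depot, phenotype, rho", call. = FALSE)
    }
    if (any(abs(targets$rho) > 1)) {
      stop("target |rho| must be <= 1", call. = FALSE)
    }
    if (!all(targets$depot %in% c("sc", "vis")) ||
        !all(targets$phenotype %in% c("bmi", "whr"))) {
      stop("'targets' depot must be sc/vis and phenotype bmi/whr", call. = FALSE)
    }
    if (!all(targets$gene %in% genes)) {
      stop("'targets' genes must appear in 'genes'", call. = FALSE)
    }
  }

  withSeed(seed, {
    group <- sample(rep(names(groupSizes), times = groupSizes))
    n <- nSubjects
    age <- rtruncnorm(n, ageMean, ageSd, ageRange[1], ageRange[2])
    sex <- ifelse(stats::runif(n) < pFemale, "female", "male")
    bmi <- numeric(n)
    lean <- group == "lean"
    bmi[lean] <- rtruncnorm(sum(lean), bmiMean, bmiSd, bmiRange[1], leanBmiCutoff)
    bmi[!lean] <- rtruncnorm(sum(!lean), bmiMean, bmiSd, leanBmiCutoff, bmiRange[2])
    whr <- rtruncnorm(n, whrMean, whrSd, whrRange[1], whrRange[2])
    ratio <- numeric(n)
    ratio[lean] <- stats::runif(sum(lean), 0.05, 1.3)
    ratio[group == "sc_obese"] <- stats::runif(sum(group == "sc_obese"), 0.05, 0.395)
    ratio[group == "vis_obese"] <- stats::runif(sum(group == "vis_obese"), 0.405, 1.3)

    cohort <- data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, whr = whr,
      vis_sc_ratio = ratio,
      stringsAsFactors = FALSE
    )

    pheno <- list(bmi = bmi, whr = whr)
    for (g in genes) {
      for (depot in c("sc", "vis")) {
        tgt <- NULL
        if (!is.null(targets)) {
          hit <- targets$gene == g & targets$depot == depot
          if (any(hit)) tgt <- targets[which(hit)[1L], ]
        }
        if (is.null(tgt)) {
          latent <- stats::rnorm(n)
        } else {
          # Normal scores of the phenotype ranks; bivariate-Gaussian
          # Pearson r targeting Spearman rho.
          z <- stats::qnorm((rank(pheno[[tgt$phenotype]], ties.method = "average") - 0.5) / n)
          r <- 2 * sin(pi * tgt$rho / 6)
          latent <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
        }
        expr <- 2^(exprBase + exprScale * latent / 4)  # monotone, expression-like
        if (missingRate > 0) {
          expr[stats::runif(n) < missingRate] <- NA_real_
        }
        cohort[[paste(g, depot, sep = "_")]] <- expr
      }
    }
    list(cohort = cohort,
         truth = list(group = stats::setNames(group, cohort$subject),
                      targets = targets))
  })
}
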