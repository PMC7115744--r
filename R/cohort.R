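# Paired-cohort validation statistics: obesity-group assignment,
# Spearman expression-phenotype correlation, Mann-Whitney group
# comparisons, covariate-adjusted regression.

#' Assign obesity groups from BMI and the vis/sc fat area ratio
#'
#' Subjects with BMI below `leanBmiCutoff` are lean; obese subjects are
#' split by the visceral-to-subcutaneous fat area ratio at
#' `ratioCutoff` into subcutaneously obese (ratio below the cutoff) and
#' viscerally obese (at or above it; the boundary value itself is
#' assigned visceral).
#'
#' @param cohort data.frame with columns `bmi` and `vis_sc_ratio`.
#' @param ratioCutoff vis/sc ratio cutoff (default 0.4).
#' @param leanBmiCutoff BMI cutoff defining lean (default 30).
#' @return factor with levels `lean`, `sc_obese`, `vis_obese`.
#' @export
assignGroups <- function(cohort, ratioCutoff = 0.4, leanBmiCutoff = 30) {
  stopifnot(all(c("bmi", "vis_sc_ratio") %in% colnames(cohort)))
  if (any(cohort$vis_sc_ratio < 0, na.rm = TRUE)) {
    stop("'vis_sc_ratio' must be >= 0", call. = FALSE)
  }
  if (any(cohort$bmi <= 0, na.rm = TRUE)) {
    stop("'bmi' must be positive", call. = FALSE)
  }
  g <- ifelse(cohort$bmi < leanBmiCutoff, "lean",
              ifelse(cohort$vis_sc_ratio < ratioCutoff, "sc_obese", "vis_obese"))
  factor(g, levels = c("lean", "sc_obese", "vis_obese"))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average-rank Spearman correlation on pairwise-complete observations;
#' the two-sided p-value uses the t approximation with n - 2 degrees of
#' freedom (|rho| = 1 gives p = 0). Zero variance in either ranked
#' vector yields a flagged, undefined result.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with `rho`, `p`, `n`, and logical `degenerate`.
#' @export
spearmanAssoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-15) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Mann-Whitney U test between two groups
#'
#' U statistic with tie correction; the two-sided p-value uses exact
#' enumeration when `n_a + n_b <= 12` and the data carry no ties, and
#' the normal approximation with continuity (and tie) correction
#' otherwise. Two groups sharing a single common value are flagged
#' all-ties and return `U = n_a * n_b / 2`, `p = 1`.
#'
#' @param a,b numeric vectors, both nonempty.
#' @return list with `U`, `p`, logical `exact` and `allTies`.
#' @examples
#' mannWhitneyTest(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitneyTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty", call. = FALSE)
  pooled <- c(a, b)
  if (anyNA(pooled)) stop("missing values are not supported", call. = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1,
                exact = FALSE, allTies = TRUE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       exact = exact, allTies = FALSE)
}

#' Age- and sex-adjusted linear regression of expression on a phenotype
#'
#' Ordinary least squares of expression on the phenotype plus age and a
#' sex indicator (female = 0, male = 1); reports the coefficient,
#' standard error and two-sided p-value per term. A rank-deficient
#' design aborts with the names of the collinear columns.
#'
#' @param expression numeric response.
#' @param phenotype numeric covariate of interest (e.g. BMI or WHR).
#' @param age numeric, years.
#' @param sex character/factor with levels female/male.
#' @return data.frame (term, beta, se, p).
#' @export
adjustedRegression <- function(expression, phenotype, age, sex) {
  df <- data.frame(
    expression = expression,
    phenotype = phenotype,
    age = age,
    sex_male = as.integer(factor(sex, levels = c("female", "male"))) - 1L
  )
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) <= 4L) {
    stop("more observations than covariates + 1 are required", call. = FALSE)
  }
  X <- stats::model.matrix(~ phenotype + age + sex_male, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("collinear design; dependent column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(expression ~ phenotype + age + sex_male, data = df)
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), beta = cf[, 1L], se = cf[, 2L],
             p = cf[, 4L], row.names = NULL, stringsAsFactors = FALSE)
}

#' Depot-wise Spearman association table
#'
#' For every gene, depot (sc/vis) and phenotype (BMI/WHR), the
#' pairwise-complete Spearman correlation between depot expression and
#' the phenotype: the standard gene x depot x phenotype correlation
#' layout of a paired-cohort analysis.
#'
#' @param cohort cohort data.frame with expression columns named
#'   `<gene>_<depot>`.
#' @param genes character, genes to test.
#' @param phenotypes subset of `c("bmi", "whr")`.
#' @param depots subset of `c("sc", "vis")`.
#' @return data.frame (gene, depot, phenotype, n, rho, p).
#' @export
associationTable <- function(cohort, genes,
                             phenotypes = c("bmi", "whr"),
                             depots = c("sc", "vis")) {
  rows <- list()
  for (g in genes) {
    for (depot in depots) {
      col <- paste(g, depot, sep = "_")
      if (!col %in% colnames(cohort)) {
        stop(sprintf("missing expression column '%s'", col), call. = FALSE)
      }
      for (ph in phenotypes) {
        res <- spearmanAssoc(cohort[[col]], cohort[[ph]])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, depot = depot, phenotype = ph,
          n = res$n, rho = res$rho, p = res$p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Mann-Whitney comparisons of expression between obesity groups
#'
#' For every gene and depot, pairwise Mann-Whitney tests of expression
#' between the obesity groups of [assignGroups()].
#'
#' @param cohort cohort data.frame.
#' @param genes character, genes to test.
#' @param groups optional precomputed group factor (default:
#'   [assignGroups()] at the standard cutoffs).
#' @param depots subset of `c("sc", "vis")`.
#' @return data.frame (gene, depot, group_a, group_b, U, p).
#' @export
groupComparisonTable <- function(cohort, genes, groups = assignGroups(cohort),
                                 depots = c("sc", "vis")) {
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  rows <- list()
  for (g in genes) {
    for (depot in depots) {
      col <- paste(g, depot, sep = "_")
      expr <- cohort[[col]]
      for (j in seq_len(ncol(pairs))) {
        ga <- expr[groups == pairs[1L, j] & !is.na(expr)]
        gb <- expr[groups == pairs[2L, j] & !is.na(expr)]
        if (!length(ga) || !length(gb)) next
        res <- mannWhitneyTest(ga, gb)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, depot = depot,
          group_a = pairs[1L, j], group_b = pairs[2L, j],
          U = res$U, p = res$p, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
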