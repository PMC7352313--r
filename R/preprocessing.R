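#' Natural-log transform of all marker concentrations
#'
#' Replaces every marker value by its natural logarithm, the standard
#' pre-treatment for right-skewed serum concentrations: it limits the
#' influence of extreme values while leaving within-marker ranks -- and
#' hence rank-sum p-values and AUCs of monotone scores -- unchanged.
#' Covariates, labels and stages are untouched.
#'
#' @param cohort A \linkS4class{MarkerCohort} on the raw concentration
#'   scale.
#' @return The cohort with the assay on the natural-log scale and
#'   \code{isLogTransformed()} set.
#' @examples
#' ch <- generateCohort(cohortConfig(nCase = 3, nControl = 3))
#' lg <- logTransformMarkers(ch)
#' all.equal(assay(lg), log(assay(ch)))
#' @export
logTransformMarkers <- function(cohort) {
  stopifnot(is(cohort, "MarkerCohort"))
  if (isLogTransformed(cohort)) {
    stop("cohort is already log-transformed")
  }
  a <- assay(cohort)
  if (any(a <= 0)) {
    bad <- which(a <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "cannot log-transform: non-positive value for marker '%s', subject '%s'",
      rownames(cohort)[bad[1L]], colnames(cohort)[bad[2L]]))
  }
  assay(cohort) <- log(a)
  metadata(cohort)$logTransformed <- TRUE
  cohort
}

#' Age bins used to categorize the age covariate
#'
#' Decade bins with left-closed boundaries: \code{<40}, \code{40-49},
#' \code{50-59}, \code{60-69}, \code{>=70} under the default breaks.
#'
#' @param breaks Increasing interior break points (years); an age equal to
#'   a break falls in the bin to its right.
#' @return Character vector of bin labels, in order.
#' @examples
#' ageBinLevels()
#' @export
ageBinLevels <- function(breaks = c(40, 50, 60, 70)) {
  stopifnot(length(breaks) >= 1L, !is.unsorted(breaks, strictly = TRUE))
  k <- length(breaks)
  c(paste0("<", breaks[1L]),
    if (k > 1L) paste0(breaks[-k], "-", breaks[-1L] - 1L),
    paste0(">=", breaks[k]))
}

#' Categorize age into decade bins
#'
#' Converts numeric age to the categorical covariate used in the feature
#' matrices (the age distribution differs between cases and controls, so
#' age enters the classifiers as bins rather than as a raw number).
#' Intervals are left-closed: age 40 falls in \code{40-49}.
#'
#' @param age Numeric ages in years (non-negative).
#' @param breaks Interior break points, see [ageBinLevels()].
#' @return Factor with levels \code{ageBinLevels(breaks)}.
#' @examples
#' categorizeAge(c(39.99, 40, 64, 81))
#' @export
categorizeAge <- function(age, breaks = c(40, 50, 60, 70)) {
  age <- as.numeric(age)
  if (any(is.na(age)) || any(age < 0)) {
    stop("age must be non-negative and non-missing")
  }
  lev <- ageBinLevels(breaks)
  cut(age, breaks = c(-Inf, breaks, Inf), labels = lev, right = FALSE)
}

#' Label-stratified random train/validation split
#'
#' Randomly assigns each subject to the training or validation set,
#' stratified by case/control label: within each label stratum the number
#' of training subjects is exactly \code{round(trainFraction * n)}
#' (half-up rounding), so only the membership -- never the counts -- is
#' random. With the study's 180 cases / 573 controls and the default 2:1
#' fraction this yields 120/382 training and 60/191 validation subjects.
#'
#' @param cohort A \linkS4class{MarkerCohort}.
#' @param trainFraction Fraction assigned to training, in (0, 1);
#'   default 2/3.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Named factor (levels \code{train}, \code{validation}), one
#'   element per subject, named by subject id, in cohort order.
#' @examples
#' ch <- generateCohort(cohortConfig(nCase = 6, nControl = 9))
#' table(splitCohort(ch, seed = 1), cohortLabels(ch))
#' @export
splitCohort <- function(cohort, trainFraction = 2 / 3, seed = 1L) {
  stopifnot(is(cohort, "MarkerCohort"))
  if (length(trainFraction) != 1L || is.na(trainFraction) ||
      trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must be in (0, 1)")
  }
  labels <- cohortLabels(cohort)
  ids <- colnames(cohort)
  out <- rep("validation", ncol(cohort))
  # membership is drawn over id-sorted strata, so each subject's
  # assignment depends only on its id, never on table row order
  withSeed(seed, {
    for (lab in c("case", "control")) {
      sids <- sort(ids[labels == lab], method = "radix")
      nTrain <- floor(trainFraction * length(sids) + 0.5)  # round half-up
      if (nTrain > 0L) {
        chosen <- sids[sample.int(length(sids), nTrain)]
        out[ids %in% chosen] <- "train"
      }
    }
  })
  out <- factor(out, levels = c("train", "validation"))
  names(out) <- colnames(cohort)
  out
}

#' Marker-wise Mann-Whitney/Wilcoxon rank-sum pre-screen
#'
#' Tests each marker for a case-versus-control distributional difference
#' with the two-sided Mann-Whitney U test (identically, the Wilcoxon
#' rank-sum test). The null distribution is exact (full enumeration) when
#' the smaller group has at most 8 subjects and there are no ties;
#' otherwise the normal approximation with tie and continuity correction
#' is used. A marker constant across all subjects gets p = 1.
#'
#' The screen is descriptive by default: it reports which markers differ
#' at \code{alpha} but does not remove any marker from the combination
#' search, mirroring a workflow in which all candidates are enumerated
#' regardless (an exclusionary mode is available in [runPipeline()]).
#' Because the test is rank-based, results are identical on raw and
#' log-transformed concentrations.
#'
#' @param cohort A \linkS4class{MarkerCohort} containing at least one case
#'   and one control.
#' @param alpha Significance level (default 0.01).
#' @return A data.frame with one row per marker: \code{marker}, \code{U}
#'   (the Mann-Whitney U statistic for cases versus controls),
#'   \code{p_value} and \code{significant} (\code{p_value < alpha}).
#' @examples
#' ch <- generateCohort(cohortConfig(nCase = 30, nControl = 30, seed = 2))
#' rankSumScreen(ch)
#' @export
rankSumScreen <- function(cohort, alpha = 0.01) {
  stopifnot(is(cohort, "MarkerCohort"))
  labels <- cohortLabels(cohort)
  if (!any(labels == "case") || !any(labels == "control")) {
    stop("rank-sum screen needs at least one case and one control")
  }
  a <- assay(cohort)
  isCase <- labels == "case"
  res <- lapply(rownames(cohort), function(m) {
    x <- a[m, isCase]
    y <- a[m, !isCase]
    if (length(unique(c(x, y))) == 1L) {
      # degenerate constant marker: no information, U at its null mean
      return(data.frame(marker = m, U = length(x) * length(y) / 2,
                        p_value = 1, significant = FALSE))
    }
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && min(length(x), length(y)) <= 8L
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    data.frame(marker = m, U = unname(wt$statistic),
               p_value = min(wt$p.value, 1), significant = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant <- res$p_value < alpha
  rownames(res) <- NULL
  res
}
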