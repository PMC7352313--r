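#' Canonical panel identifier
#'
#' A panel (an unordered non-empty set of marker names) is serialized as
#' its members sorted byte-wise and joined with \code{"+"}, e.g.
#' \code{"ApoA1+ApoA2+CA125+CA19-9+CEA+TTR"}. The canonical id is unique
#' per set and is used throughout ledgers and performance tables.
#'
#' @param panel Character vector of marker names.
#' @return Single canonical id string.
#' @examples
#' panelId(c("CEA", "CA19-9"))
#' @export
panelId <- function(panel) {
  stopifnot(length(panel) >= 1L, !anyDuplicated(panel))
  paste(sortMarkers(as.character(panel)), collapse = "+")
}

#' Members of a canonical panel id
#'
#' @param id Canonical panel id produced by [panelId()].
#' @return Character vector of marker names.
#' @examples
#' panelMembers("CA19-9+CEA")
#' @export
panelMembers <- function(id) {
  stopifnot(length(id) == 1L, nzchar(id))
  strsplit(id, "+", fixed = TRUE)[[1L]]
}

#' Enumerate all non-empty marker subsets
#'
#' Produces every non-empty subset of the candidate markers -- the
#' exhaustive combination search space: \eqn{2^n - 1} panels, e.g. 2047
#' for the 11 candidate markers. The order is deterministic: by size, then
#' lexicographically (byte-wise) within size, so downstream rank ties
#' break reproducibly.
#'
#' @param markers Unique candidate marker names.
#' @param maxMarkers Safety cap on \code{length(markers)} (enumeration is
#'   exponential); default 16.
#' @return List of character vectors (panels), each in canonical sorted
#'   order.
#' @examples
#' length(enumeratePanels(c("A", "B", "C")))  # 7
#' @export
enumeratePanels <- function(markers, maxMarkers = 16L) {
  markers <- as.character(markers)
  if (!length(markers)) stop("markers must be non-empty")
  if (anyDuplicated(markers)) stop("duplicate marker names")
  if (length(markers) > maxMarkers) {
    stop(sprintf("%d markers exceed maxMarkers = %d (2^n - 1 subsets)",
                 length(markers), maxMarkers))
  }
  markers <- sortMarkers(markers)
  n <- length(markers)
  out <- vector("list", 2L^n - 1L)
  k <- 0L
  for (size in seq_len(n)) {
    comb <- utils::combn(markers, size, simplify = FALSE)
    out[k + seq_along(comb)] <- comb
    k <- k + length(comb)
  }
  out
}

#' Assemble a per-panel feature matrix with covariates
#'
#' Builds the classifier input for one panel: the log-scale values of the
#' panel's markers (columns in canonical order), optionally followed by
#' the encoded covariates -- the age bins as one-hot indicators with the
#' youngest bin as reference, and sex as a single male indicator. Feature
#' column order is deterministic, and the age-bin columns are always the
#' full set of non-reference bins (whether or not a bin is occupied), so
#' matrices built on different subject subsets are schema-compatible.
#'
#' @param cohort A log-transformed \linkS4class{MarkerCohort}.
#' @param panel Character vector of marker names (subset of
#'   \code{markerNames(cohort)}).
#' @param covariates Include encoded age and sex columns? Default
#'   \code{TRUE}.
#' @param ageBreaks Age bin breaks, see [categorizeAge()].
#' @return List with \code{features} (numeric subjects x features matrix,
#'   rows named by subject id), \code{labels} (factor with levels
#'   \code{control}, \code{case}) and \code{stages} (integer, \code{NA}
#'   for controls).
#' @examples
#' ch <- logTransformMarkers(generateCohort(cohortConfig(5, 8)))
#' fm <- buildFeatureMatrix(ch, c("CEA", "CA19-9"))
#' colnames(fm$features)
#' @export
buildFeatureMatrix <- function(cohort, panel, covariates = TRUE,
                               ageBreaks = c(40, 50, 60, 70)) {
  stopifnot(is(cohort, "MarkerCohort"))
  if (!isLogTransformed(cohort)) {
    stop("cohort must be log-transformed before building feature matrices")
  }
  panel <- sortMarkers(as.character(panel))
  unknown <- setdiff(panel, rownames(cohort))
  if (length(unknown)) {
    stop("unknown marker(s) in panel: ", paste(unknown, collapse = ", "))
  }
  x <- t(assay(cohort)[panel, , drop = FALSE])
  if (covariates) {
    bins <- categorizeAge(colData(cohort)$age, ageBreaks)
    lev <- levels(bins)
    oneHot <- vapply(lev[-1L], function(l) as.numeric(bins == l),
                     numeric(ncol(cohort)))
    colnames(oneHot) <- paste0("age", lev[-1L])
    sexM <- as.numeric(colData(cohort)$sex == "M")
    x <- cbind(x, oneHot, sexM = sexM)
  }
  rownames(x) <- colnames(cohort)
  list(features = x,
       labels = factor(cohortLabels(cohort), levels = c("control", "case")),
       stages = cohortStages(cohort))
}
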