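#' Rank panels by mean cross-validated training AUC
#'
#' Orders all candidate panels by the mean of their training
#' cross-validated AUCs across the five classification algorithms,
#' descending -- panels that perform well for every algorithm rise to the
#' top. Ties break toward fewer markers, then by canonical panel id, so
#' the ranking is fully deterministic.
#'
#' @param records Long-format performance data.frame with columns
#'   \code{panel}, \code{algorithm}, \code{split}, \code{auc} containing a
#'   \code{train_cv} row for every (panel, algorithm) pair.
#' @param algorithms Algorithms that must be present for every panel
#'   (default all five).
#' @return data.frame with columns \code{panel}, \code{meanTrainCvAuc},
#'   \code{nMarkers}, ordered best-first.
#' @export
rankPanels <- function(records, algorithms = panelAlgorithms()) {
  cv <- records[records$split == "train_cv" &
                  records$algorithm %in% algorithms, , drop = FALSE]
  counts <- table(cv$panel)
  if (length(counts) == 0L) stop("no train_cv records found")
  if (any(counts != length(algorithms))) {
    bad <- names(counts)[counts != length(algorithms)]
    stop("missing algorithm records for panel(s): ",
         paste(head(bad, 3L), collapse = "; "))
  }
  meanAuc <- tapply(cv$auc, cv$panel, mean)
  panels <- names(meanAuc)
  nMarkers <- lengths(strsplit(panels, "+", fixed = TRUE))
  ord <- order(-meanAuc, nMarkers, panels, method = "radix")
  data.frame(panel = panels[ord],
             meanTrainCvAuc = as.numeric(meanAuc)[ord],
             nMarkers = nMarkers[ord], row.names = NULL)
}

#' Keep the top-ranked fraction of panels
#'
#' Retains the first \eqn{\lceil fraction \cdot N \rceil} entries of a
#' ranked panel list (so the top 10\% of 2047 panels is 205).
#'
#' @param ranked Ranked panels: the data.frame from [rankPanels()] or a
#'   character vector of panel ids, best first.
#' @param fraction Fraction to keep, in (0, 1].
#' @return Object of the same shape as \code{ranked}, truncated.
#' @examples
#' filterTopFraction(letters[1:10], 0.1)
#' @export
filterTopFraction <- function(ranked, fraction) {
  if (length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  n <- NROW(ranked)
  keep <- as.integer(ceiling(fraction * n - 1e-9))
  head(ranked, keep)
}

#' Keep panels containing all mandatory markers
#'
#' Retains the panels that are supersets of \code{required}, preserving
#' order. In the pancreatic cancer application the mandatory pair is
#' CEA and CA19-9, the tumor markers already used clinically.
#'
#' @param panels Character vector of canonical panel ids.
#' @param required Character vector of mandatory marker names (empty
#'   vector keeps everything).
#' @return Character vector of surviving panel ids.
#' @examples
#' filterMandatory(c("CA19-9", "CA19-9+CEA"), c("CEA", "CA19-9"))
#' @export
filterMandatory <- function(panels, required) {
  required <- as.character(required)
  if (!length(required)) return(panels)
  keep <- vapply(panels, function(id) {
    all(required %in% panelMembers(id))
  }, logical(1))
  panels[keep]
}

#' Filter panels by train/validation AUC stability
#'
#' Keeps the panels whose absolute gap between the training
#' cross-validated AUC and the validation AUC is at most \code{maxGap}
#' for \emph{every} algorithm -- the first half of the stability
#' criterion: a selected panel should generalize, not merely fit the
#' training set.
#'
#' @param panels Character vector of candidate panel ids (order
#'   preserved).
#' @param records Long-format performance data.frame with \code{train_cv}
#'   and \code{validation} rows for every (panel, algorithm).
#' @param maxGap Maximum tolerated |train CV AUC - validation AUC|
#'   (default 0.02).
#' @param algorithms Algorithms the bound must hold for (default all
#'   five).
#' @return Character vector of surviving panel ids.
#' @export
stabilityFilter <- function(panels, records, maxGap = 0.02,
                            algorithms = panelAlgorithms()) {
  stopifnot(maxGap >= 0)
  keep <- vapply(panels, function(id) {
    r <- records[records$panel == id & records$algorithm %in% algorithms, ]
    gaps <- vapply(algorithms, function(a) {
      tr <- r$auc[r$algorithm == a & r$split == "train_cv"]
      va <- r$auc[r$algorithm == a & r$split == "validation"]
      if (length(tr) != 1L || length(va) != 1L) {
        stop("missing train_cv/validation record for panel ", id,
             ", algorithm ", a)
      }
      abs(tr - va)
    }, numeric(1))
    all(gaps <= maxGap)
  }, logical(1))
  panels[keep]
}

#' Select the final panel by cross-algorithm worst-case validation AUC
#'
#' Operationalizes \dQuote{excellent performance independent of the
#' linear and non-linear methods}: among the surviving candidates, pick
#' the panel maximizing the \emph{minimum} validation AUC across the five
#' algorithms. Ties break by the smallest standard deviation of the five
#' validation AUCs (most algorithm-consistent), then fewest markers, then
#' canonical id.
#'
#' @param candidates Non-empty character vector of candidate panel ids.
#' @param records Long-format performance data.frame with a
#'   \code{validation} row per (panel, algorithm).
#' @param algorithms Algorithms considered (default all five).
#' @return List with \code{panel} (marker vector), \code{panelId},
#'   \code{minValidationAuc}, \code{sdValidationAuc} and
#'   \code{validationAuc} (named per algorithm).
#' @export
selectFinal <- function(candidates, records,
                        algorithms = panelAlgorithms()) {
  if (!length(candidates)) {
    stop("no candidate panels survive the cascade; ",
         "relax maxGap or increase topFraction")
  }
  stats <- lapply(candidates, function(id) {
    va <- vapply(algorithms, function(a) {
      v <- records$auc[records$panel == id & records$algorithm == a &
                         records$split == "validation"]
      if (length(v) != 1L) {
        stop("missing validation record for panel ", id, ", algorithm ", a)
      }
      v
    }, numeric(1))
    list(id = id, min = min(va), sd = sd(va), va = va)
  })
  minAuc <- vapply(stats, `[[`, numeric(1), "min")
  sdAuc <- vapply(stats, `[[`, numeric(1), "sd")
  nMarkers <- lengths(strsplit(candidates, "+", fixed = TRUE))
  ord <- order(-minAuc, sdAuc, nMarkers, candidates, method = "radix")
  best <- stats[[ord[1L]]]
  list(panel = panelMembers(best$id), panelId = best$id,
       minValidationAuc = best$min, sdValidationAuc = best$sd,
       validationAuc = best$va)
}
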