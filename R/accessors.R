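#' Accessors for MarkerCohort and SelectionLedger
#'
#' \code{markerNames} returns the marker identifiers (assay rows);
#' \code{subjectIds} the subject identifiers; \code{cohortLabels} the
#' case/control labels; \code{cohortStages} the tumor stages (\code{NA}
#' for controls); \code{isLogTransformed} whether the assay is on the
#' natural-log scale. On a \linkS4class{SelectionLedger},
#' \code{finalPanel} returns the selected panel's markers,
#' \code{cascadeCounts} the number of surviving panels at each stage, and
#' \code{performanceRecords} the long-format performance table.
#'
#' @param x A \linkS4class{MarkerCohort} or \linkS4class{SelectionLedger}.
#' @return See details above.
#' @examples
#' cfg <- cohortConfig(nCase = 4, nControl = 6)
#' ch <- generateCohort(cfg)
#' markerNames(ch)
#' table(cohortLabels(ch))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setMethod("markerNames", "MarkerCohort", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setMethod("subjectIds", "MarkerCohort", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setMethod("cohortLabels", "MarkerCohort", function(x) colData(x)$label)

#' @rdname accessors
#' @export
setGeneric("cohortStages", function(x) standardGeneric("cohortStages"))
#' @rdname accessors
#' @export
setMethod("cohortStages", "MarkerCohort", function(x) colData(x)$stage)

#' @rdname accessors
#' @export
setGeneric("isLogTransformed", function(x) standardGeneric("isLogTransformed"))
#' @rdname accessors
#' @export
setMethod("isLogTransformed", "MarkerCohort",
          function(x) isTRUE(metadata(x)$logTransformed))

#' @rdname accessors
#' @export
setGeneric("finalPanel", function(x) standardGeneric("finalPanel"))
#' @rdname accessors
#' @export
setMethod("finalPanel", "SelectionLedger", function(x) x@finalPanel)

#' @rdname accessors
#' @export
setGeneric("cascadeCounts", function(x) standardGeneric("cascadeCounts"))
#' @rdname accessors
#' @export
setMethod("cascadeCounts", "SelectionLedger",
          function(x) vapply(x@stagePanels, length, integer(1)))

#' @rdname accessors
#' @export
setGeneric("performanceRecords",
           function(x) standardGeneric("performanceRecords"))
#' @rdname accessors
#' @export
setMethod("performanceRecords", "SelectionLedger", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("screenResults", function(x) standardGeneric("screenResults"))
#' @rdname accessors
#' @export
setMethod("screenResults", "SelectionLedger", function(x) x@screen)

#' @rdname accessors
#' @export
setGeneric("splitAssignment", function(x) standardGeneric("splitAssignment"))
#' @rdname accessors
#' @export
setMethod("splitAssignment", "SelectionLedger", function(x) x@split)

setMethod("show", "MarkerCohort", function(object) {
  lab <- cohortLabels(object)
  cat(sprintf(
    "MarkerCohort: %d markers x %d subjects (%d cases / %d controls)\n",
    nrow(object), ncol(object), sum(lab == "case"), sum(lab == "control")))
  cat("  markers:", paste(rownames(object), collapse = ", "), "\n")
  cat("  scale:", if (isLogTransformed(object)) "natural-log" else "raw",
      "concentrations\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d cases / %d controls, %d markers (seed %d)\n",
              object@nCase, object@nControl, length(object@markerNames),
              object@seed))
  null <- names(which(object@effectShift == 0))
  cat("  shifted markers:", sum(object@effectShift != 0),
      if (length(null)) paste0("; null: ", paste(null, collapse = ", "))
      else "", "\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
  hp <- object@hyperparameters
  cat(sprintf("ModelSpec: %s (seed %d)\n", object@algorithm, object@seed))
  if (length(hp)) {
    cat("  ", paste(names(hp), vapply(hp, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = "=", collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "PanelScorer", function(object) {
  cat(sprintf("PanelScorer: %s over %d features\n",
              object@spec@algorithm, length(object@schema)))
})

setMethod("show", "SelectionLedger", function(object) {
  n <- cascadeCounts(object)
  cat("SelectionLedger\n")
  cat(sprintf("  stage0 (all panels):        %d\n", n[["stage0"]]))
  cat(sprintf("  stage1 (top fraction):      %d\n", n[["stage1"]]))
  cat(sprintf("  stage2 (mandatory markers): %d\n", n[["stage2"]]))
  cat(sprintf("  stage3 (stability filter):  %d\n", n[["stage3"]]))
  cat("  final panel:", if (length(object@finalPanel))
    panelId(object@finalPanel) else "<none>", "\n")
})
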