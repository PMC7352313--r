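#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Candidate serum markers of the pancreatic cancer screening panel
#'
#' The eleven serum proteins measured by the pan-cancer assay platform that
#' the pipeline searches over: the classical tumor antigens CA19-9, CEA and
#' CA125, the apolipoproteins ApoA1/ApoA2, transthyretin (TTR), beta-2
#' microglobulin (B2M), C-reactive protein (CRP), CYFRA21.1, D-Dimer and
#' LRG1.
#'
#' @return Character vector of the 11 marker names.
#' @examples
#' defaultMarkerNames()
#' @export
defaultMarkerNames <- function() {
  c("ApoA1", "CA125", "CA19-9", "CRP", "CYFRA21.1", "CEA",
    "ApoA2", "TTR", "B2M", "D-Dimer", "LRG1")
}

validMarkerNames <- function(markers) {
  if (!length(markers)) return("marker names must be non-empty")
  if (anyDuplicated(markers)) return("marker names must be unique")
  if (any(is.na(markers) | markers == "")) return("marker names must be non-missing")
  if (any(grepl("[+,]", markers))) {
    return("marker names must not contain '+' or ',' (reserved for panel ids)")
  }
  NULL
}

#' CohortConfig: generative model of a synthetic case-control serum cohort
#'
#' Parameters of the synthetic cohort generator. Marker concentrations are
#' log-normal: controls have log-mean \code{controlLogMean} and log-sd
#' \code{logSd} per marker; cases shift the log-mean by
#' \code{effectShift * stageEffectScale[stage]}. A marker with zero shift is
#' a null marker. Ages are normal (truncated at 18), sex is Bernoulli, and
#' tumor stage is multinomial over \code{stageProbs}.
#'
#' @slot nCase,nControl Non-negative subject counts.
#' @slot markerNames Character vector of marker identifiers.
#' @slot controlLogMean,logSd,effectShift Named numeric vectors, one value
#'   per marker (log-concentration units; \code{logSd > 0}).
#' @slot stageProbs Probabilities of stages 1-4 among cases (sum to 1).
#' @slot stageEffectScale Nondecreasing multipliers applied to
#'   \code{effectShift} by stage.
#' @slot ageCaseMean,ageCaseSd,ageControlMean,ageControlSd Age model (years).
#' @slot maleFracCase,maleFracControl Probability of male sex.
#' @slot seed Integer seed; identical configs give bit-identical cohorts.
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nCase = "integer", nControl = "integer",
    markerNames = "character",
    controlLogMean = "numeric", logSd = "numeric", effectShift = "numeric",
    stageProbs = "numeric", stageEffectScale = "numeric",
    ageCaseMean = "numeric", ageCaseSd = "numeric",
    ageControlMean = "numeric", ageControlSd = "numeric",
    maleFracCase = "numeric", maleFracControl = "numeric",
    seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  m <- validMarkerNames(object@markerNames)
  if (!is.null(m)) msg <- c(msg, m)
  if (object@nCase < 0L || object@nControl < 0L) {
    msg <- c(msg, "nCase and nControl must be non-negative")
  }
  p <- length(object@markerNames)
  for (s in c("controlLogMean", "logSd", "effectShift")) {
    v <- slot(object, s)
    if (length(v) != p || !identical(names(v), object@markerNames)) {
      msg <- c(msg, sprintf("%s must be named per marker, in marker order", s))
    }
  }
  if (any(object@logSd <= 0)) msg <- c(msg, "logSd must be > 0 for every marker")
  if (length(object@stageProbs) != 4L ||
      any(object@stageProbs < 0 | object@stageProbs > 1)) {
    msg <- c(msg, "stageProbs must be 4 probabilities in [0, 1]")
  } else if (abs(sum(object@stageProbs) - 1) > 1e-9) {
    msg <- c(msg, "stageProbs must sum to 1 (within 1e-9)")
  }
  if (length(object@stageEffectScale) != 4L ||
      is.unsorted(object@stageEffectScale)) {
    msg <- c(msg, "stageEffectScale must be 4 nondecreasing multipliers")
  }
  for (s in c("maleFracCase", "maleFracControl")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", s))
  }
  if (object@ageCaseSd <= 0 || object@ageControlSd <= 0) {
    msg <- c(msg, "age standard deviations must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' MarkerCohort: a case-control serum-marker cohort
#'
#' Container for a subject-level cohort, extending
#' \linkS4class{SummarizedExperiment}: the assay is a markers x subjects
#' matrix of serum concentrations (strictly positive on the raw scale),
#' and \code{colData} holds age (years), sex (M/F), label (case/control)
#' and, for cases only, AJCC tumor stage 1-4.
#'
#' After [logTransformMarkers()] the assay holds natural-log concentrations
#' and \code{isLogTransformed()} is \code{TRUE}.
#'
#' @seealso [MarkerCohort()], [generateCohort()], [readCohort()]
#' @export
setClass("MarkerCohort", contains = "SummarizedExperiment")

setValidity("MarkerCohort", function(object) {
  msg <- character(0)
  cd <- colData(object)
  need <- c("age", "sex", "label", "stage")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    return(paste("colData is missing columns:", paste(miss, collapse = ", ")))
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "subject ids (colnames) must be present and unique")
  }
  m <- validMarkerNames(rownames(object))
  if (!is.null(m)) msg <- c(msg, m)
  if (ncol(object)) {
    if (!all(cd$label %in% c("case", "control"))) {
      msg <- c(msg, "label must be 'case' or 'control'")
    }
    if (!all(cd$sex %in% c("M", "F"))) msg <- c(msg, "sex must be 'M' or 'F'")
    if (any(is.na(cd$age)) || any(cd$age < 0)) {
      msg <- c(msg, "age must be non-negative and non-missing")
    }
    isCase <- cd$label == "case"
    if (any(is.na(cd$stage[isCase]))) {
      msg <- c(msg, "every case must have a stage")
    }
    if (any(!is.na(cd$stage[!isCase]))) {
      msg <- c(msg, "controls must not have a stage")
    }
    st <- cd$stage[isCase]
    if (length(st) && !all(st %in% 1:4)) {
      msg <- c(msg, "stage must be in 1..4")
    }
    a <- assay(object)
    if (any(!is.finite(a))) {
      msg <- c(msg, "marker values must be finite")
    } else if (!isTRUE(metadata(object)$logTransformed) && any(a <= 0)) {
      bad <- which(a <= 0, arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf(
        "marker values must be strictly positive (marker '%s', subject '%s')",
        rownames(object)[bad[1L]], colnames(object)[bad[2L]]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerCohort
#'
#' @param concentrations Numeric markers x subjects matrix with marker row
#'   names and unique subject column names.
#' @param age Numeric vector of ages (years), one per subject.
#' @param sex Character vector, \code{"M"} or \code{"F"}.
#' @param label Character vector, \code{"case"} or \code{"control"}.
#' @param stage Integer tumor stage 1-4 for cases, \code{NA} for controls.
#' @param logTransformed Set \code{TRUE} if \code{concentrations} are
#'   already on the natural-log scale.
#' @return A \linkS4class{MarkerCohort}.
#' @examples
#' x <- matrix(rexp(6) + 0.1, nrow = 2,
#'             dimnames = list(c("CEA", "CA19-9"), paste0("s", 1:3)))
#' MarkerCohort(x, age = c(60, 55, 70), sex = c("M", "F", "M"),
#'              label = c("case", "control", "control"),
#'              stage = c(2L, NA, NA))
#' @export
MarkerCohort <- function(concentrations, age, sex, label, stage = NA,
                         logTransformed = FALSE) {
  concentrations <- as.matrix(concentrations)
  n <- ncol(concentrations)
  stage <- suppressWarnings(as.integer(rep_len(stage, n)))
  cd <- DataFrame(age = as.numeric(age), sex = as.character(sex),
                  label = as.character(label), stage = stage,
                  row.names = colnames(concentrations))
  se <- SummarizedExperiment(
    assays = list(concentration = concentrations), colData = cd)
  out <- new("MarkerCohort", se)
  metadata(out)$logTransformed <- isTRUE(logTransformed)
  validObject(out)
  out
}

#' ModelSpec: one of the five classification algorithms
#'
#' Identifies a classification algorithm of the suite -- \code{"GLM"}
#' (unpenalized logistic regression), \code{"RIDGE"} (L2-penalized
#' logistic regression), \code{"SVM"} (radial-kernel support vector
#' machine with a sigmoid margin-to-probability map), \code{"RF"}
#' (random forest, vote fraction) or \code{"GLM_RF"} (unweighted mean of
#' the GLM and RF probability scores) -- together with its hyperparameters
#' and a seed making the fit deterministic.
#'
#' @slot algorithm One of \code{GLM, RIDGE, SVM, RF, GLM_RF}.
#' @slot hyperparameters Named list, validated per algorithm; see
#'   [modelSpec()].
#' @slot seed Integer seed for any randomness in fitting.
#' @seealso [modelSpec()], [fitClassifier()]
#' @export
setClass("ModelSpec",
  representation(algorithm = "character", hyperparameters = "list",
                 seed = "integer"))

panelAlgorithms <- function() c("GLM", "RIDGE", "SVM", "RF", "GLM_RF")

hyperparameterNames <- list(
  GLM = c("maxit", "maxFeatures"),
  RIDGE = c("lambda", "internalFolds", "nlambda", "maxFeatures"),
  SVM = c("cost", "gamma", "kernel", "maxFeatures"),
  RF = c("numTrees", "mtry", "maxFeatures"),
  GLM_RF = c("maxit", "numTrees", "mtry", "maxFeatures"))

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (length(object@algorithm) != 1L ||
      !object@algorithm %in% panelAlgorithms()) {
    msg <- c(msg, paste("algorithm must be one of",
                        paste(panelAlgorithms(), collapse = ", ")))
  } else {
    bad <- setdiff(names(object@hyperparameters),
                   hyperparameterNames[[object@algorithm]])
    if (length(bad)) {
      msg <- c(msg, sprintf("unknown hyperparameters for %s: %s",
                            object@algorithm, paste(bad, collapse = ", ")))
    }
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "seed must be a single integer")
  }
  if (length(msg)) msg else TRUE
})

#' PanelScorer: a fitted classifier with its feature schema
#'
#' Returned by [fitClassifier()]; score new subjects with [scoreSamples()].
#' The fitted model(s) and the exact training feature columns are stored so
#' scoring can verify the schema.
#'
#' @slot spec The \linkS4class{ModelSpec} used for the fit.
#' @slot fits List of underlying fitted models (two for \code{GLM_RF}).
#' @slot schema Character vector of feature column names, in order.
#' @export
setClass("PanelScorer",
  representation(spec = "ModelSpec", fits = "list", schema = "character"))

#' SelectionLedger: audit trail of the panel-selection cascade
#'
#' Records every stage of the selection cascade run by [runCascade()] /
#' [runPipeline()]: all enumerated panels with per-algorithm performance
#' (stage 0), the top-ranked fraction (stage 1), the mandatory-marker
#' survivors (stage 2), the train/validation stability survivors (stage 3),
#' and the final panel, together with every parameter in force.
#'
#' @slot records Long-format data.frame of performance records: one row per
#'   (panel, algorithm, split) with AUC, threshold, sensitivity,
#'   specificity, accuracy and per-stage sensitivities.
#' @slot screen Marker-wise rank-sum screen table (may have zero rows when
#'   the screen was not run).
#' @slot split Named character vector: subject id -> \code{train} or
#'   \code{validation}.
#' @slot stagePanels List of four character vectors of canonical panel ids:
#'   \code{stage0} (all), \code{stage1} (top fraction), \code{stage2}
#'   (mandatory markers), \code{stage3} (stability).
#' @slot finalPanel Character vector of the selected panel's markers.
#' @slot parameters Named list of all thresholds, seeds and decisions in
#'   force for the run.
#' @seealso [finalPanel()], [cascadeCounts()], [performanceRecords()],
#'   [writeLedger()]
#' @export
setClass("SelectionLedger",
  representation(records = "data.frame", screen = "data.frame",
                 split = "character", stagePanels = "list",
                 finalPanel = "character", parameters = "list"))

setValidity("SelectionLedger", function(object) {
  msg <- character(0)
  if (!identical(names(object@stagePanels),
                 c("stage0", "stage1", "stage2", "stage3"))) {
    msg <- c(msg, "stagePanels must be named stage0..stage3")
  } else {
    sp <- object@stagePanels
    for (i in 2:4) {
      if (!all(sp[[i]] %in% sp[[i - 1L]])) {
        msg <- c(msg, sprintf("%s must be a subset of %s",
                              names(sp)[i], names(sp)[i - 1L]))
      }
    }
    if (length(object@finalPanel) &&
        !panelId(object@finalPanel) %in% sp$stage3) {
      msg <- c(msg, "final panel must be a stage3 survivor")
    }
  }
  if (length(msg)) msg else TRUE
})
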