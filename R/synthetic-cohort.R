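#' Configure the synthetic case-control cohort generator
#'
#' Builds a \linkS4class{CohortConfig} describing a case-control serum
#' cohort with planted marker effects. The defaults emulate the pancreatic
#' ductal adenocarcinoma screening study the pipeline is modelled on:
#' 180 cases and 573 healthy controls; case age 64.4 (9.8) years versus
#' control 56.9 (8.8); 65.0\% versus 58.3\% male; AJCC stage mix
#' 29.4/41.1/16.7/12.8\%; right-skewed (log-normal) marker concentrations
#' with a location shift in 10 of the 11 markers and one null marker (the
#' B2M analog); and stage-dependent effect strength (multipliers
#' 0.8/0.9/1.1/1.2 on the log-scale shift for stages 1-4).
#'
#' Because every downstream step first log-transforms the markers and
#' either ranks them or standardizes them, absolute assay units are
#' irrelevant; the default control log-mean is 0 and log-sd 1 for every
#' marker, so \code{effectShift} is expressed in log-sd units.
#'
#' @param nCase,nControl Subject counts (defaults 180 / 573).
#' @param markerNames Candidate marker identifiers (default the 11 of
#'   [defaultMarkerNames()]).
#' @param controlLogMean,logSd Per-marker log-normal parameters for
#'   controls; scalars are recycled and named.
#' @param effectShift Per-marker additive shift of the case log-mean, in
#'   the same units as \code{logSd}; 0 marks a null marker. The default
#'   (defined for the 11 default markers) shifts every marker except B2M
#'   by 1.0-1.6 log-sd, strongest for CA19-9.
#' @param stageProbs Stage 1-4 probabilities among cases.
#' @param stageEffectScale Nondecreasing stage multipliers on
#'   \code{effectShift}.
#' @param ageCaseMean,ageCaseSd,ageControlMean,ageControlSd Age model
#'   (normal, truncated at 18 years).
#' @param maleFracCase,maleFracControl Probability of male sex.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config including this seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @examples
#' cohortConfig()
#' cohortConfig(nCase = 10, nControl = 20, markerNames = c("CEA", "CA19-9"),
#'              effectShift = c(1.5, 0))
#' @export
cohortConfig <- function(nCase = 180L, nControl = 573L,
                         markerNames = defaultMarkerNames(),
                         controlLogMean = 0, logSd = 1,
                         effectShift = NULL,
                         stageProbs = c(0.294, 0.411, 0.167, 0.128),
                         stageEffectScale = c(0.8, 0.9, 1.1, 1.2),
                         ageCaseMean = 64.4, ageCaseSd = 9.8,
                         ageControlMean = 56.9, ageControlSd = 8.8,
                         maleFracCase = 0.650, maleFracControl = 0.583,
                         seed = 1L) {
  if (length(nCase) != 1L || length(nControl) != 1L ||
      is.na(nCase) || is.na(nControl) || nCase < 0 || nControl < 0) {
    stop("nCase and nControl must be single non-negative counts")
  }
  perMarker <- function(v, what) {
    if (is.null(names(v))) {
      v <- rep_len(v, length(markerNames))
      names(v) <- markerNames
    } else {
      miss <- setdiff(markerNames, names(v))
      if (length(miss)) {
        stop(what, " is missing values for: ", paste(miss, collapse = ", "))
      }
      v <- v[markerNames]
    }
    v
  }
  if (is.null(effectShift)) {
    effectShift <- defaultEffectShift(markerNames)
  }
  new("CohortConfig",
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      markerNames = as.character(markerNames),
      controlLogMean = perMarker(as.numeric(controlLogMean), "controlLogMean"),
      logSd = perMarker(as.numeric(logSd), "logSd"),
      effectShift = perMarker(as.numeric(effectShift), "effectShift"),
      stageProbs = as.numeric(stageProbs),
      stageEffectScale = as.numeric(stageEffectScale),
      ageCaseMean = ageCaseMean, ageCaseSd = ageCaseSd,
      ageControlMean = ageControlMean, ageControlSd = ageControlSd,
      maleFracCase = maleFracCase, maleFracControl = maleFracControl,
      seed = as.integer(seed))
}

# Default planted shifts, log-sd units: every marker except the B2M analog
# is informative; tumor antigens get the strongest shifts.
defaultEffectShift <- function(markerNames) {
  shifts <- c(ApoA1 = 1.0, CA125 = 1.2, "CA19-9" = 1.6, CRP = 1.1,
              CYFRA21.1 = 1.0, CEA = 1.0, ApoA2 = 1.1, TTR = 1.0,
              B2M = 0, "D-Dimer" = 1.2, LRG1 = 1.3)
  miss <- setdiff(markerNames, names(shifts))
  if (length(miss)) {
    stop("no default effect shift for marker(s): ",
         paste(miss, collapse = ", "),
         "; supply effectShift explicitly")
  }
  shifts[markerNames]
}

#' Generate a synthetic case-control cohort
#'
#' Draws a cohort from the generative model in a \linkS4class{CohortConfig}.
#' All randomness comes from the config's seed, consumed in a fixed order
#' (case stages, case ages, control ages, case sex, control sex, then per
#' marker the case and control log-concentrations), so an identical config
#' yields a bit-identical cohort.
#'
#' Marker concentrations are log-normal: for control subjects marker
#' \eqn{j} has log-mean \eqn{\mu_j}; for a case of stage \eqn{s} the
#' log-mean is \eqn{\mu_j + \delta_j \cdot c_s} with \eqn{\delta_j} the
#' effect shift and \eqn{c_s} the stage multiplier. Ages are normal,
#' truncated at 18 years.
#'
#' @param config A \linkS4class{CohortConfig}.
#' @return A \linkS4class{MarkerCohort} with \code{nCase + nControl}
#'   subjects (cases first).
#' @examples
#' ch <- generateCohort(cohortConfig(nCase = 5, nControl = 8, seed = 7))
#' dim(ch)
#' table(cohortLabels(ch))
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  nca <- config@nCase
  nco <- config@nControl
  n <- nca + nco
  markers <- config@markerNames
  withSeed(config@seed, {
    stage <- if (nca > 0L) {
      sample.int(4L, nca, replace = TRUE, prob = config@stageProbs)
    } else integer(0)
    ageCase <- rnormTrunc(nca, config@ageCaseMean, config@ageCaseSd, 18)
    ageControl <- rnormTrunc(nco, config@ageControlMean,
                             config@ageControlSd, 18)
    sexCase <- ifelse(rbinom(nca, 1L, config@maleFracCase) == 1L, "M", "F")
    sexControl <- ifelse(rbinom(nco, 1L, config@maleFracControl) == 1L,
                         "M", "F")
    conc <- matrix(NA_real_, nrow = length(markers), ncol = n,
                   dimnames = list(markers, NULL))
    scale <- config@stageEffectScale
    for (j in seq_along(markers)) {
      mu <- config@controlLogMean[j]
      caseMean <- mu + config@effectShift[j] * scale[stage]
      conc[j, ] <- exp(c(rnorm(nca, caseMean, config@logSd[j]),
                         rnorm(nco, mu, config@logSd[j])))
    }
  })
  ids <- c(sprintf("case_%03d", seq_len(nca)),
           sprintf("ctrl_%03d", seq_len(nco)))
  colnames(conc) <- ids
  MarkerCohort(conc,
               age = c(ageCase, ageControl),
               sex = c(sexCase, sexControl),
               label = rep(c("case", "control"), c(nca, nco)),
               stage = c(stage, rep(NA_integer_, nco)))
}

#' Ground-truth informative marker set of a synthetic cohort
#'
#' Returns the planted panel -- the markers whose effect shift is nonzero
#' in the generator config -- which is the recovery target for the
#' selection cascade on synthetic data.
#'
#' @param config A \linkS4class{CohortConfig}.
#' @return Character vector of informative marker names (possibly empty),
#'   in canonical sorted order.
#' @examples
#' plantedTruth(cohortConfig())   # the 10 non-B2M markers
#' @export
plantedTruth <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  sortMarkers(names(config@effectShift)[config@effectShift != 0])
}
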