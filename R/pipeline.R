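#' Run the selection cascade over precomputed performance records
#'
#' Applies the four-stage cascade to a long-format performance table:
#' (1) rank all panels by mean cross-validated training AUC over the five
#' algorithms and keep the top \code{topFraction}; (2) keep panels
#' containing all \code{mandatory} markers; (3) keep panels whose
#' train/validation AUC gap is at most \code{maxGap} for every algorithm;
#' (4) pick the panel with the best worst-case validation AUC across
#' algorithms.
#'
#' @param records Long-format performance data.frame (see
#'   [performanceRecords()]) with \code{train_cv} and \code{validation}
#'   rows for every (panel, algorithm).
#' @param mandatory Marker names every surviving panel must contain.
#' @param topFraction Fraction of ranked panels kept at stage 1.
#' @param maxGap Stability bound on |train CV AUC - validation AUC|.
#' @param algorithms Algorithms considered (default all five).
#' @return List with \code{stagePanels} (list \code{stage0..stage3} of
#'   panel-id vectors), \code{final} (the [selectFinal()] result) and
#'   \code{ranking} (the [rankPanels()] table).
#' @seealso [runPipeline()] for the end-to-end entry point.
#' @export
runCascade <- function(records, mandatory = c("CA19-9", "CEA"),
                       topFraction = 0.10, maxGap = 0.02,
                       algorithms = panelAlgorithms()) {
  ranking <- rankPanels(records, algorithms)
  stage0 <- ranking$panel
  stage1 <- filterTopFraction(ranking, topFraction)$panel
  stage2 <- filterMandatory(stage1, mandatory)
  stage3 <- stabilityFilter(stage2, records, maxGap, algorithms)
  final <- selectFinal(stage3, records, algorithms)
  list(stagePanels = list(stage0 = stage0, stage1 = stage1,
                          stage2 = stage2, stage3 = stage3),
       final = final, ranking = ranking)
}

resolveHyperparameters <- function(hyperparameters) {
  hp <- defaultHyperparameters()
  bad <- setdiff(names(hyperparameters), names(hp))
  if (length(bad)) {
    stop("hyperparameters must be named by algorithm; unknown: ",
         paste(bad, collapse = ", "))
  }
  for (a in names(hyperparameters)) {
    hp[[a]] <- modifyList(hp[[a]], hyperparameters[[a]], keep.null = TRUE)
  }
  hp
}

# Performance records for one panel: shares the GLM and RF fits with
# GLM_RF (whose score is their mean), so the five algorithms cost four
# fits per fold.
panelRecords <- function(pid, cols, xTrain, yTrain, stTrain, xVal, yVal,
                         stVal, folds, algorithms, hp, targetSpecificity,
                         seed) {
  k <- max(folds)
  baseAlgos <- setdiff(algorithms, "GLM_RF")
  if ("GLM_RF" %in% algorithms) {
    baseAlgos <- union(baseAlgos, c("GLM", "RF"))
  }
  xt <- xTrain[, cols, drop = FALSE]
  xv <- xVal[, cols, drop = FALSE]
  oof <- resub <- val <- list()
  for (a in baseAlgos) {
    o <- numeric(length(yTrain))
    for (f in seq_len(k)) {
      hold <- folds == f
      sp <- new("ModelSpec", algorithm = a, hyperparameters = hp[[a]],
                seed = deriveSeed(seed, pid, a, f))
      sc <- fitClassifier(sp, xt[!hold, , drop = FALSE], yTrain[!hold])
      o[hold] <- scoreSamples(sc, xt[hold, , drop = FALSE])
    }
    oof[[a]] <- o
    spFull <- new("ModelSpec", algorithm = a, hyperparameters = hp[[a]],
                  seed = deriveSeed(seed, pid, a, "full"))
    scFull <- fitClassifier(spFull, xt, yTrain)
    resub[[a]] <- scoreSamples(scFull, xt)
    val[[a]] <- scoreSamples(scFull, xv)
  }
  if ("GLM_RF" %in% algorithms) {
    oof$GLM_RF <- combineGlmRf(oof$GLM, oof$RF)
    resub$GLM_RF <- combineGlmRf(resub$GLM, resub$RF)
    val$GLM_RF <- combineGlmRf(val$GLM, val$RF)
  }
  rows <- lapply(algorithms, function(a) {
    ctrlTrain <- yTrain == "control"
    tCv <- thresholdAtSpecificity(oof[[a]][ctrlTrain], targetSpecificity)
    tTrain <- thresholdAtSpecificity(resub[[a]][ctrlTrain],
                                     targetSpecificity)
    mk <- function(split, scores, y, st, thr) {
      ev <- evaluateAtThreshold(scores, as.character(y), thr, st)
      ps <- ev$perStageSensitivity
      data.frame(panel = pid, algorithm = a, split = split,
                 auc = computeAUC(scores, as.character(y)),
                 threshold = thr, sensitivity = ev$sensitivity,
                 specificity = ev$specificity, accuracy = ev$accuracy,
                 sens_stage1 = ps[["1"]], sens_stage2 = ps[["2"]],
                 sens_stage3 = ps[["3"]], sens_stage4 = ps[["4"]])
    }
    rbind(mk("train_cv", oof[[a]], yTrain, stTrain, tCv),
          mk("train_resub", resub[[a]], yTrain, stTrain, tTrain),
          # threshold transport: validation is judged at the
          # training-derived operating point, never re-fit
          mk("validation", val[[a]], yVal, stVal, tTrain))
  })
  do.call(rbind, rows)
}

#' End-to-end multi-marker panel discovery pipeline
#'
#' Runs the whole discovery procedure on a cohort: natural-log transform,
#' marker-wise rank-sum screen (reported, and optionally exclusionary),
#' label-stratified 2:1 train/validation split, exhaustive enumeration of
#' all non-empty marker subsets, cross-validated fitting of the five
#' classification algorithms on every panel (with age-bin and sex
#' covariates), evaluation at the fixed-specificity operating point with
#' threshold transport to the validation set, and the four-stage
#' stability cascade picking the final panel. Every random step is seeded
#' from \code{seed} via per-task derived seeds, so identical inputs give
#' identical ledgers regardless of execution order.
#'
#' @param cohort A \linkS4class{MarkerCohort} (raw or already
#'   log-transformed).
#' @param markers Candidate markers (default: all markers in the cohort).
#' @param mandatory Markers every selected panel must contain (default
#'   CA19-9 and CEA, the clinically established pancreatic tumor
#'   markers).
#' @param trainFraction Training fraction of the label-stratified split
#'   (default 2/3).
#' @param targetSpecificity Training specificity fixing the operating
#'   point (default 0.95).
#' @param topFraction Fraction of ranked panels kept by the cascade
#'   (default 0.10).
#' @param maxGap Stability bound on the train/validation AUC gap
#'   (default 0.02).
#' @param cvFolds Cross-validation folds (default 10).
#' @param algorithms Algorithms to run (default all five).
#' @param hyperparameters Named-by-algorithm list of overrides, see
#'   [defaultHyperparameters()].
#' @param covariates Include encoded age/sex columns (default
#'   \code{TRUE}).
#' @param ageBreaks Age bin breaks, see [categorizeAge()].
#' @param alpha Screen significance level (default 0.01).
#' @param screenExclude If \code{TRUE}, markers not significant in the
#'   screen are removed from the candidate list before enumeration
#'   (default \code{FALSE}: the screen is descriptive only).
#' @param seed Global integer seed.
#' @param outputDir If given, the ledger and its CSV side-tables are
#'   written there via [writeLedger()].
#' @param verbose Log per-stage progress and the resolved value of every
#'   tuning knob (default \code{FALSE}).
#' @return A \linkS4class{SelectionLedger}.
#' @examples
#' cfg <- cohortConfig(nCase = 24, nControl = 36,
#'                     markerNames = c("CA19-9", "CEA", "TTR"),
#'                     effectShift = c(1.5, 1.2, 0), seed = 5)
#' led <- runPipeline(generateCohort(cfg), cvFolds = 3,
#'                    hyperparameters = list(RF = list(numTrees = 50L),
#'                                           RIDGE = list(lambda = 0.1)),
#'                    maxGap = 1, seed = 5)
#' finalPanel(led)
#' @export
runPipeline <- function(cohort, markers = NULL,
                        mandatory = c("CA19-9", "CEA"),
                        trainFraction = 2 / 3, targetSpecificity = 0.95,
                        topFraction = 0.10, maxGap = 0.02, cvFolds = 10L,
                        algorithms = panelAlgorithms(),
                        hyperparameters = list(), covariates = TRUE,
                        ageBreaks = c(40, 50, 60, 70), alpha = 0.01,
                        screenExclude = FALSE, seed = 1L,
                        outputDir = NULL, verbose = FALSE) {
  stopifnot(is(cohort, "MarkerCohort"))
  if (is.null(markers)) markers <- markerNames(cohort)
  unknown <- setdiff(c(markers, mandatory), markerNames(cohort))
  if (length(unknown)) {
    stop("marker(s) not in cohort: ", paste(unknown, collapse = ", "))
  }
  if (!all(mandatory %in% markers)) {
    stop("mandatory markers must be among the candidate markers")
  }
  stopifnot(cvFolds >= 2L, topFraction > 0, topFraction <= 1)
  algorithms <- match.arg(algorithms, panelAlgorithms(),
                          several.ok = TRUE)
  hp <- resolveHyperparameters(hyperparameters)
  say <- function(...) if (verbose) message(sprintf(...))
  say("pipeline: seed=%d trainFraction=%.4f targetSpecificity=%.2f %s",
      seed, trainFraction, targetSpecificity,
      sprintf("topFraction=%.2f maxGap=%.3f cvFolds=%d covariates=%s",
              topFraction, maxGap, cvFolds, covariates))

  if (!isLogTransformed(cohort)) cohort <- logTransformMarkers(cohort)
  screen <- rankSumScreen(cohort, alpha)
  say("screen: %d of %d markers significant at alpha=%.3g",
      sum(screen$significant), nrow(screen), alpha)
  if (screenExclude) {
    markers <- intersect(markers,
                         screen$marker[screen$significant])
    if (!all(mandatory %in% markers)) {
      stop("screen excluded a mandatory marker; ",
           "disable screenExclude or drop it from mandatory")
    }
    say("screen-exclude: %d candidate markers remain", length(markers))
  }

  split <- splitCohort(cohort, trainFraction, deriveSeed(seed, "split"))
  fm <- buildFeatureMatrix(cohort, markers, covariates, ageBreaks)
  covCols <- setdiff(colnames(fm$features), markers)
  isTrain <- split == "train"
  xTrain <- fm$features[isTrain, , drop = FALSE]
  yTrain <- fm$labels[isTrain]
  stTrain <- fm$stages[isTrain]
  xVal <- fm$features[!isTrain, , drop = FALSE]
  yVal <- fm$labels[!isTrain]
  stVal <- fm$stages[!isTrain]
  say("split: %d train (%d cases) / %d validation (%d cases)",
      sum(isTrain), sum(yTrain == "case"), sum(!isTrain),
      sum(yVal == "case"))

  panels <- enumeratePanels(markers)
  say("enumeration: %d candidate panels", length(panels))
  folds <- withSeed(deriveSeed(seed, "folds", cvFolds),
                    stratifiedFolds(yTrain, cvFolds, rownames(xTrain)))
  recs <- vector("list", length(panels))
  for (i in seq_along(panels)) {
    pid <- panelId(panels[[i]])
    recs[[i]] <- panelRecords(pid, c(panels[[i]], covCols), xTrain,
                              yTrain, stTrain, xVal, yVal, stVal, folds,
                              algorithms, hp, targetSpecificity, seed)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  say("evaluation: %d performance records", nrow(records))

  cascade <- runCascade(records, mandatory, topFraction, maxGap,
                        algorithms)
  counts <- lengths(cascade$stagePanels)
  say("cascade: %d -> %d -> %d -> %d; final panel %s",
      counts[[1]], counts[[2]], counts[[3]], counts[[4]],
      cascade$final$panelId)

  parameters <- list(
    markers = sortMarkers(markers), mandatory = sortMarkers(mandatory),
    trainFraction = trainFraction,
    targetSpecificity = targetSpecificity, topFraction = topFraction,
    maxGap = maxGap, cvFolds = as.integer(cvFolds),
    algorithms = algorithms, covariates = covariates,
    ageBreaks = ageBreaks, alpha = alpha, screenExclude = screenExclude,
    cvPooling = "pooled", seed = as.integer(seed),
    hyperparameters = hp[algorithms],
    final = cascade$final[c("panelId", "minValidationAuc",
                            "sdValidationAuc")])
  ledger <- new("SelectionLedger", records = records, screen = screen,
                split = stats::setNames(as.character(split), names(split)),
                stagePanels = cascade$stagePanels,
                finalPanel = cascade$final$panel, parameters = parameters)
  validObject(ledger)
  if (!is.null(outputDir)) writeLedger(ledger, outputDir)
  ledger
}
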