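# build a long-format records table from a named list:
# panels -> algorithm -> c(train_cv, validation)
makeRecords <- function(spec) {
  rows <- list()
  for (pid in names(spec)) {
    for (a in names(spec[[pid]])) {
      v <- spec[[pid]][[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        panel = pid, algorithm = a,
        split = c("train_cv", "validation"), auc = v)
    }
  }
  do.call(rbind, rows)
}

fiveAlgos <- c("GLM", "RIDGE", "SVM", "RF", "GLM_RF")
flat <- function(cv, val) {
  stats::setNames(rep(list(c(cv, val)), 5), fiveAlgos)
}

test_that("panels rank by mean CV AUC with size and id tie-breaks", {
  recs <- makeRecords(list(
    "A+B" = flat(0.9, 0.9),
    "C" = flat(0.8, 0.8)))
  r <- rankPanels(recs)
  expect_identical(r$panel, c("A+B", "C"))
  expect_equal(r$meanTrainCvAuc, c(0.9, 0.8))

  tie <- makeRecords(list(
    "A+B+C+D+E" = flat(0.9, 0.9),
    "A+B+C" = flat(0.9, 0.9),
    "A+B+D" = flat(0.9, 0.9)))
  expect_identical(rankPanels(tie)$panel,
                   c("A+B+C", "A+B+D", "A+B+C+D+E"))

  missing <- makeRecords(list("A" = flat(0.9, 0.9)))
  missing <- missing[missing$algorithm != "RF", ]
  expect_error(rankPanels(missing), "missing algorithm")
})

test_that("top-fraction filter keeps the ceiling of fraction*N", {
  expect_identical(filterTopFraction(letters[1:10], 0.1), "a")
  expect_length(filterTopFraction(sprintf("p%04d", 1:2047), 0.1), 205L)
  expect_identical(filterTopFraction(letters[1:4], 1), letters[1:4])
  expect_error(filterTopFraction(letters, 0), "fraction")
})

test_that("mandatory-marker filter keeps supersets only, in order", {
  panels <- c("CA19-9", "CA19-9+CEA", "ApoA1+CA19-9+CEA", "ApoA1+CEA")
  expect_identical(filterMandatory(panels, c("CEA", "CA19-9")),
                   c("CA19-9+CEA", "ApoA1+CA19-9+CEA"))
  expect_identical(filterMandatory(panels, character(0)), panels)
})

test_that("stability filter bounds the train/validation gap per algorithm", {
  recs <- makeRecords(list(
    "A+B" = flat(0.9, 0.9),
    "A+C" = modifyList(flat(0.9, 0.9), list(SVM = c(0.9, 0.4))),
    "A+D" = flat(0.95, 0.935)))
  expect_identical(stabilityFilter(c("A+B", "A+C", "A+D"), recs,
                                   maxGap = 0.02),
                   c("A+B", "A+D"))
  expect_identical(stabilityFilter(c("A+B", "A+C"), recs, maxGap = 1),
                   c("A+B", "A+C"))
  expect_identical(stabilityFilter(c("A+C"), recs, maxGap = 0.02),
                   character(0))
})

test_that("final pick maximizes worst-case validation AUC with tie-breaks", {
  recs <- makeRecords(list(
    "A+B" = modifyList(flat(0.99, 0.95), list(RF = c(0.99, 0.90))),
    "A+C" = flat(0.99, 0.94)))
  pick <- selectFinal(c("A+B", "A+C"), recs)
  expect_identical(pick$panelId, "A+C")     # min 0.94 beats min 0.90
  expect_equal(pick$minValidationAuc, 0.94)

  single <- selectFinal("A+B", recs)
  expect_identical(single$panelId, "A+B")

  # sd tie-break: equal min, prefer the algorithm-consistent panel
  tie <- makeRecords(list(
    "A+B" = modifyList(flat(0.99, 0.95), list(RF = c(0.99, 0.99))),
    "A+C" = flat(0.99, 0.95)))
  expect_identical(selectFinal(c("A+B", "A+C"), tie)$panelId, "A+C")

  expect_error(selectFinal(character(0), recs), "relax")
})

test_that("the cascade ledger is monotone and contains the mandatory pair", {
  cfg <- cohortConfig(nCase = 30, nControl = 45,
                      markerNames = c("CA19-9", "CEA", "TTR", "B2M"),
                      effectShift = c(1.5, 1.5, 1.5, 0),
                      stageEffectScale = c(1, 1, 1, 1), seed = 31)
  led <- runPipeline(generateCohort(cfg), cvFolds = 3,
                     hyperparameters = fastHyper, maxGap = 1,
                     topFraction = 0.5, seed = 31)
  n <- cascadeCounts(led)
  expect_equal(n[["stage0"]], 15L)
  expect_true(all(diff(n) <= 0))
  expect_gte(n[["stage3"]], 1L)
  expect_true(all(c("CA19-9", "CEA") %in% finalPanel(led)))
  expect_true(panelId(finalPanel(led)) %in% led@stagePanels$stage3)
  # every (panel, algorithm) has the three splits recorded
  recs <- performanceRecords(led)
  expect_equal(nrow(recs), 15L * 5L * 3L)
  expect_setequal(unique(recs$split),
                  c("train_cv", "train_resub", "validation"))
  # threshold transport: validation rows reuse the train_resub threshold
  for (a in fiveAlgos) {
    r <- recs[recs$panel == panelId(finalPanel(led)) &
                recs$algorithm == a, ]
    expect_equal(r$threshold[r$split == "validation"],
                 r$threshold[r$split == "train_resub"])
  }
})
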