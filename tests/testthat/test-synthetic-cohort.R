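test_that("generated cohorts have the configured composition", {
  ch <- generateCohort(cohortConfig(nCase = 0, nControl = 5))
  expect_equal(ncol(ch), 5L)
  expect_true(all(cohortLabels(ch) == "control"))
  expect_true(all(is.na(cohortStages(ch))))

  ch <- generateCohort(cohortConfig(seed = 3))
  expect_equal(dim(ch), c(11L, 753L))
  expect_equal(sum(cohortLabels(ch) == "case"), 180L)
  expect_equal(sum(cohortLabels(ch) == "control"), 573L)
  expect_setequal(markerNames(ch), defaultMarkerNames())
  expect_true(all(assay(ch) > 0))
  expect_true(all(colData(ch)$age >= 18))
  isCase <- cohortLabels(ch) == "case"
  expect_true(all(cohortStages(ch)[isCase] %in% 1:4))
  expect_true(all(is.na(cohortStages(ch)[!isCase])))
})

test_that("identical configs give bit-identical cohorts", {
  a <- generateCohort(cohortConfig(nCase = 30, nControl = 40, seed = 9))
  b <- generateCohort(cohortConfig(nCase = 30, nControl = 40, seed = 9))
  expect_identical(assay(a), assay(b))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  c <- generateCohort(cohortConfig(nCase = 30, nControl = 40, seed = 10))
  expect_false(identical(assay(a), assay(c)))
})

test_that("plantedTruth reads the nonzero-shift markers from the config", {
  expect_identical(plantedTruth(cohortConfig()),
                   sort(setdiff(defaultMarkerNames(), "B2M"),
                        method = "radix"))
  nullCfg <- cohortConfig(markerNames = c("CEA", "CA19-9"),
                          effectShift = c(0, 0))
  expect_identical(plantedTruth(nullCfg), character(0))
  two <- cohortConfig(markerNames = c("CEA", "CA19-9", "TTR"),
                      effectShift = c(1, 2, 0))
  expect_identical(plantedTruth(two), c("CA19-9", "CEA"))
})

test_that("default config plants exactly one null marker (the B2M analog)", {
  cfg <- cohortConfig()
  expect_identical(names(which(cfg@effectShift == 0)), "B2M")
  expect_true(all(cfg@effectShift[setdiff(defaultMarkerNames(), "B2M")] >= 1))
  expect_equal(sum(cfg@stageProbs), 1)
})

test_that("null generator yields single-marker AUCs near 0.5", {
  cfg <- cohortConfig(nCase = 2000, nControl = 2000, effectShift = 0,
                      seed = 21)
  ch <- generateCohort(cfg)
  labels <- cohortLabels(ch)
  for (m in markerNames(ch)) {
    expect_lt(abs(computeAUC(assay(ch)[m, ], labels) - 0.5), 0.03)
  }
})

test_that("control log-concentration means match the config", {
  cfg <- cohortConfig(nCase = 0, nControl = 6000,
                      markerNames = c("CEA", "CA19-9"),
                      controlLogMean = c(1.5, -2), logSd = c(0.5, 2),
                      effectShift = c(0, 0), seed = 4)
  ch <- generateCohort(cfg)
  lm <- rowMeans(log(assay(ch)))
  expect_lt(abs(lm[["CEA"]] - 1.5), 3 * 0.5 / sqrt(6000))
  expect_lt(abs(lm[["CA19-9"]] + 2), 3 * 2 / sqrt(6000))
})

test_that("larger effect shifts do not decrease single-marker AUC", {
  meanAuc <- vapply(c(0, 0.75, 1.5), function(shift) {
    aucs <- vapply(1:10, function(s) {
      cfg <- cohortConfig(nCase = 150, nControl = 150,
                          markerNames = c("CEA", "CA19-9"),
                          effectShift = c(shift, 0),
                          stageEffectScale = c(1, 1, 1, 1), seed = s)
      ch <- generateCohort(cfg)
      computeAUC(assay(ch)["CEA", ], cohortLabels(ch))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(meanAuc) > -0.01))
  expect_gt(meanAuc[3], meanAuc[1] + 0.2)
})

test_that("invalid configs are rejected", {
  expect_error(cohortConfig(nCase = -1), "non-negative")
  expect_error(cohortConfig(stageProbs = c(0.5, 0.5, 0.2, 0)), "sum to 1")
  expect_error(cohortConfig(logSd = 0), "logSd")
  expect_error(cohortConfig(stageEffectScale = c(1.2, 1, 1, 1)),
               "nondecreasing")
  expect_error(cohortConfig(markerNames = c("A", "A"),
                            effectShift = c(1, 1)), "unique")
})
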