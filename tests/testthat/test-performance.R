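test_that("computeAUC equals exhaustive pairwise concordance", {
  expect_equal(computeAUC(c(0.9, 0.1), c("case", "control")), 1)
  expect_equal(computeAUC(c(0.5, 0.5), c("case", "control")), 0.5)
  expect_error(computeAUC(c(1, 2), c("case", "case")), "control")

  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- c("case", "control",
                sample(c("case", "control"), n - 2, replace = TRUE))
    scores <- if (i %% 2) runif(n) else sample(1:5, n, replace = TRUE) / 5
    expect_equal(computeAUC(scores, labels), aucBrute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("computeAUC equals the trapezoidal ROC area when tie-free", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    labels <- c("case", "control",
                sample(c("case", "control"), n - 2, replace = TRUE))
    scores <- sample(seq_len(1000), n) / 1000
    expect_equal(computeAUC(scores, labels),
                 aucTrapezoid(scores, labels), tolerance = 1e-12)
    # complement identity and monotone invariance
    expect_equal(computeAUC(scores, labels) +
                   computeAUC(-scores, labels), 1, tolerance = 1e-12)
    expect_equal(computeAUC(scores, labels),
                 computeAUC(qlogis(scores / 2 + 0.25), labels),
                 tolerance = 1e-12)
  }
})

test_that("computeAUC agrees with an established ROC implementation", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    labels <- c("case", "control",
                sample(c("case", "control"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # include ties
    ref <- as.numeric(pROC::auc(pROC::roc(
      labels, scores, levels = c("control", "case"),
      direction = "<", quiet = TRUE)))
    expect_equal(computeAUC(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("the specificity threshold is the minimal adequate order statistic", {
  s <- (1:20) / 20
  expect_equal(thresholdAtSpecificity(s, 0.95), 19 / 20)
  expect_equal(mean(s <= thresholdAtSpecificity(s, 0.95)), 0.95)
  expect_equal(thresholdAtSpecificity(rep(0.3, 7), 0.95), 0.3)

  set.seed(5)
  for (i in 1:40) {
    controls <- if (i %% 2) runif(sample(5:60, 1))
                else sample(1:8, sample(5:60, 1), replace = TRUE) / 8
    target <- sample(c(0.5, 0.8, 0.9, 0.95, 1), 1)
    t <- thresholdAtSpecificity(controls, target)
    expect_gte(mean(controls <= t), target)
    expect_equal(t, thresholdScan(controls, target))
  }
  expect_error(thresholdAtSpecificity(numeric(0), 0.95), "non-empty")
  expect_error(thresholdAtSpecificity(1:3, 0), "target")
})

test_that("threshold metrics match a hand-counted confusion matrix", {
  scores <- c(0.95, 0.9, 0.6, 0.4, 0.85, 0.7, 0.5, 0.3, 0.2, 0.1)
  labels <- rep(c("case", "control"), c(4, 6))
  ev <- evaluateAtThreshold(scores, labels, 0.55)
  expect_equal(ev$sensitivity, 3 / 4)   # cases 0.95, 0.9, 0.6 above
  expect_equal(ev$specificity, 4 / 6)   # controls 0.85, 0.7 above
  expect_equal(ev$accuracy, 7 / 10)     # 3 TP + 4 TN

  hi <- evaluateAtThreshold(scores, labels, 2)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)

  sep <- evaluateAtThreshold(c(1, 1, 0, 0), rep(c("case", "control"),
                                                each = 2), 0.5)
  expect_equal(c(sep$sensitivity, sep$specificity, sep$accuracy),
               c(1, 1, 1))
  # ties at the threshold are called control (strict >)
  tie <- evaluateAtThreshold(c(0.5, 0.4), c("case", "control"), 0.5)
  expect_equal(tie$sensitivity, 0)
})

test_that("stage-stratified sensitivity is computed within stage", {
  s <- stageSensitivity(c(0.9, 0.2, 0.8, 0.1),
                        c("case", "case", "case", "case"),
                        c(1, 2, 3, 4), 0.5)
  expect_equal(unname(s), c(1, 0, 1, 0))
  miss <- stageSensitivity(c(0.9, 0.1), c("case", "control"),
                           c(4L, NA), 0.5)
  expect_equal(miss[["4"]], 1)
  expect_true(is.na(miss[["1"]]))
  expect_error(stageSensitivity(c(0.9), "case", NA_integer_, 0.5),
               "stage")
})

test_that("stage-scaled effects yield stage-ordered sensitivity on average", {
  perStage <- matrix(NA_real_, 50, 4)
  for (s in 1:50) {
    cfg <- cohortConfig(nCase = 60, nControl = 120,
                        markerNames = c("CEA", "CA19-9"),
                        effectShift = c(1.2, 1.2),
                        stageEffectScale = c(0.5, 0.8, 1.3, 1.8),
                        seed = s)
    ch <- logTransformMarkers(generateCohort(cfg))
    fm <- buildFeatureMatrix(ch, c("CEA", "CA19-9"), covariates = FALSE)
    sc <- fitClassifier(modelSpec("GLM"), fm$features, fm$labels)
    scores <- scoreSamples(sc, fm$features)
    t <- thresholdAtSpecificity(scores[fm$labels == "control"], 0.9)
    perStage[s, ] <- stageSensitivity(scores, as.character(fm$labels),
                                      fm$stages, t)
  }
  avg <- colMeans(perStage, na.rm = TRUE)
  expect_true(all(diff(avg) > -0.03))
  expect_gt(avg[4], avg[1])
})

test_that("cross-validated AUC is deterministic and fold-sane", {
  toy <- makeSeparated(30L)
  auc <- crossValidatedAUC(modelSpec("GLM"), toy$features, toy$labels,
                           k = 10, seed = 2)
  expect_equal(auc, 1)
  expect_identical(auc, crossValidatedAUC(modelSpec("GLM"), toy$features,
                                          toy$labels, k = 10, seed = 2))
  avg <- crossValidatedAUC(modelSpec("GLM"), toy$features, toy$labels,
                           k = 5, seed = 2, pooling = "average")
  expect_equal(avg, 1)
  expect_error(crossValidatedAUC(modelSpec("GLM"), toy$features,
                                 toy$labels, k = 40, seed = 1),
               "lower k")
})

test_that("fold membership depends on subject ids, not row order", {
  set.seed(3)
  n <- 40L
  ids <- paste0("s", seq_len(n))
  labels <- rep(c("case", "control"), n / 2)
  f1 <- withr::with_seed(11, stratifiedFolds(labels, 4, ids))
  perm <- sample(n)
  f2 <- withr::with_seed(11, stratifiedFolds(labels[perm], 4, ids[perm]))
  expect_identical(f2[match(ids, ids[perm])], f1)
})
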