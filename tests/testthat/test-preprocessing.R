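test_that("log transform takes natural logs and touches nothing else", {
  vals <- rbind(CEA = c(1, exp(1), exp(2)), TTR = c(2, 4, 8))
  ch <- makeCohort(vals)
  lg <- logTransformMarkers(ch)
  expect_equal(unname(assay(lg)["CEA", ]), c(0, 1, 2))
  expect_equal(dim(lg), dim(ch))
  expect_identical(as.data.frame(colData(lg)), as.data.frame(colData(ch)))
  expect_true(isLogTransformed(lg))
  expect_error(logTransformMarkers(lg), "already")
})

test_that("screen p-values are invariant under the log transform", {
  ch <- generateCohort(cohortConfig(nCase = 40, nControl = 60, seed = 8))
  expect_equal(rankSumScreen(ch)$p_value,
               rankSumScreen(logTransformMarkers(ch))$p_value,
               tolerance = 1e-12)
})

test_that("age categorization uses left-closed decade bins", {
  expect_equal(as.character(categorizeAge(c(64, 40, 39.99, 0, 70, 99))),
               c("60-69", "40-49", "<40", "<40", ">=70", ">=70"))
  expect_equal(levels(categorizeAge(50)),
               c("<40", "40-49", "50-59", "60-69", ">=70"))
  expect_error(categorizeAge(-1), "non-negative")
})

test_that("2:1 label-stratified split reproduces the study counts", {
  ch <- generateCohort(cohortConfig(seed = 1))
  sp <- splitCohort(ch, seed = 1)
  tab <- table(sp, cohortLabels(ch))
  expect_equal(tab["train", "case"], 120L, ignore_attr = TRUE)
  expect_equal(tab["train", "control"], 382L, ignore_attr = TRUE)
  expect_equal(tab["validation", "case"], 60L, ignore_attr = TRUE)
  expect_equal(tab["validation", "control"], 191L, ignore_attr = TRUE)
})

test_that("split is an exact seeded partition with half-up rounding", {
  ch <- generateCohort(cohortConfig(nCase = 3, nControl = 4, seed = 2))
  sp <- splitCohort(ch, seed = 7)
  expect_equal(sum(sp[cohortLabels(ch) == "case"] == "train"), 2L)
  expect_setequal(names(sp), subjectIds(ch))
  expect_identical(sp, splitCohort(ch, seed = 7))
  expect_false(identical(sp, splitCohort(ch, seed = 8)))
  expect_error(splitCohort(ch, trainFraction = 1.2), "trainFraction")
  # per-subject assignment does not depend on table row order
  perm <- sample(ncol(ch))
  sp2 <- splitCohort(ch[, perm], seed = 7)
  expect_identical(sp2[names(sp)], sp[names(sp)], ignore_attr = TRUE)
  expect_equal(as.character(sp2[names(sp)]), as.character(sp))
})

test_that("rank-sum screen matches the exact-enumeration oracle", {
  # the canonical extreme arrangement: exact two-sided p = 2/20
  ch <- makeCohort(rbind(CEA = c(1, 2, 3, 4, 5, 6)),
                   label = rep(c("case", "control"), each = 3))
  res <- rankSumScreen(ch, alpha = 0.01)
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_false(res$significant)

  set.seed(31)
  for (i in 1:25) {
    m <- sample(3:8, 1)
    n <- sample(3:8, 1)
    vals <- sample(seq_len(40), m + n)  # tie-free
    ch <- makeCohort(rbind(CEA = vals),
                     label = rep(c("case", "control"), c(m, n)))
    res <- rankSumScreen(ch)
    expect_equal(res$p_value, enumWilcoxP(vals[1:m], vals[-(1:m)]),
                 tolerance = 1e-12)
    expect_lte(res$U, m * n)
  }
})

test_that("degenerate screens behave sensibly", {
  ch <- makeCohort(rbind(CEA = c(1, 2, 3, 1, 2, 3)),
                   label = rep(c("case", "control"), each = 3))
  expect_equal(rankSumScreen(ch)$p_value, 1, tolerance = 1e-9)

  const <- makeCohort(rbind(CEA = rep(5, 6)),
                      label = rep(c("case", "control"), each = 3))
  res <- rankSumScreen(const)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  onlyCases <- makeCohort(rbind(CEA = 1:4), label = rep("case", 4))
  expect_error(rankSumScreen(onlyCases), "at least one")
})
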