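# Expected scores at covariate extremes and the score-range coverage screen.

test_that("a zero-correlation covariate leaves the expected score at its marginal", {
  model <- reduced2dModel()
  jm <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "null", corr = c(0, 0)),
    list(name = "x", corr = c(0.7, 0.3))))
  e1 <- expectedScoreGiven(jm, model, "fibrosis", "null", -5, nMC = 5000L, seed = 9L)
  e2 <- expectedScoreGiven(jm, model, "fibrosis", "null", 5, nMC = 5000L, seed = 9L)
  expect_equal(e1, e2, tolerance = 1e-12)   # common random numbers: exact
  marg <- ghExpected2d(modelItems(model)$fibrosis, c(0, 0),
                       latentCorrelation(model))
  expect_lt(abs(e1 - marg), 0.03)
})

test_that("Monte Carlo expected scores match 2-D quadrature", {
  model <- reduced2dModel()
  jm <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "x", corr = c(0.6, 0.4))))
  for (v in c(-1.96, 0, 1.96)) {
    cond <- conditionalLatent(jm, "x", v)
    for (tg in c("steatosis", "ballooning", "fibrosis")) {
      mc <- expectedScoreGiven(jm, model, tg, "x", v, nMC = 1e5L, seed = 11L)
      qd <- ghExpected2d(modelItems(model)[[tg]], cond$mean, cond$cov)
      expect_lt(abs(mc - qd), 0.02)
    }
  }
})

test_that("the NAS expectation is the sum of its components on shared draws", {
  model <- reduced2dModel()
  jm <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "x", corr = c(0.6, 0.4))))
  nas <- expectedScoreGiven(jm, model, "NAS", "x", 1, nMC = 2e4L, seed = 13L)
  comp <- vapply(c("steatosis", "lobular_inflammation", "ballooning"),
                 function(tg) expectedScoreGiven(jm, model, tg, "x", 1,
                                                 nMC = 2e4L, seed = 13L), 0)
  expect_equal(nas, sum(comp), tolerance = 1e-12)
  expect_lte(nas, 8); expect_gte(nas, 0)
})

test_that("flipping the covariate correlation swaps the extreme expected scores", {
  model <- reduced2dModel()
  jp <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "x", corr = c(0.2, 0.6))))
  jn <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "x", corr = c(-0.2, -0.6))))
  cp <- scoreCoverage(jp, model, "fibrosis", "x", nMC = 2e4L, seed = 15L)
  cn <- scoreCoverage(jn, model, "fibrosis", "x", nMC = 2e4L, seed = 15L)
  expect_equal(cp$scoreLow, cn$scoreHigh, tolerance = 1e-9)
  expect_equal(cp$scoreHigh, cn$scoreLow, tolerance = 1e-9)
  expect_equal(cp$coverage, cn$coverage, tolerance = 1e-9)
})

test_that("coverage is monotone in the generating correlation and flags at 0.25", {
  model <- reduced2dModel()
  # correlation vector proportional to Sigma[, 2]: a covariate proportional
  # to the second facet plus noise, feasible for any r < 1
  covFor <- function(r) {
    jm <- syntheticJointModel(latentCorrelation(model), list(
      list(name = "x", corr = r * c(0.5, 1))))
    scoreCoverage(jm, model, "fibrosis", "x", nMC = 2e4L, seed = 17L)$coverage
  }
  cv <- vapply(c(0, 0.3, 0.6, 0.9), covFor, 0)
  expect_true(all(diff(cv) > 0))
  expect_lt(cv[1], 0.02)
  # strong correlation: flagged, and consistent with the quadrature oracle
  jm <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "x", corr = 0.9 * c(0.5, 1))))
  res <- scoreCoverage(jm, model, "fibrosis", "x", nMC = 2e4L, seed = 17L)
  expect_true(res$influential)
  lo <- ghExpected2d(modelItems(model)$fibrosis,
                     conditionalLatent(jm, "x", -1.96)$mean,
                     conditionalLatent(jm, "x", -1.96)$cov)
  hi <- ghExpected2d(modelItems(model)$fibrosis,
                     conditionalLatent(jm, "x", 1.96)$mean,
                     conditionalLatent(jm, "x", 1.96)$cov)
  expect_lt(abs(res$coverage - (hi - lo) / 4), 0.01)
  expect_gte((hi - lo) / 4, 0.25)
})

test_that("binary covariates condition on their levels", {
  model <- reduced2dModel()
  jm <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "diabetes", kind = "binary", corr = c(0.1, 0.35),
         prevalence = 0.381)))
  res <- scoreCoverage(jm, model, "fibrosis", "diabetes", nMC = 2e4L, seed = 19L)
  expect_identical(res$valueLow, "0")
  expect_identical(res$valueHigh, "1")
  expect_gt(res$scoreHigh, res$scoreLow)
  # mean expected score is the prevalence-weighted level mean
  e0 <- expectedScoreGiven(jm, model, "fibrosis", "diabetes", 0, nMC = 2e4L, seed = 19L)
  e1 <- expectedScoreGiven(jm, model, "fibrosis", "diabetes", 1, nMC = 2e4L, seed = 19L)
  expect_equal(res$meanScore, 0.619 * e0 + 0.381 * e1, tolerance = 1e-9)
})

test_that("the screen enumerates every target-covariate pair in order", {
  model <- reduced2dModel()
  jm <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "x", corr = c(0.6, 0.2)),
    list(name = "y", corr = c(0, 0.5)),
    list(name = "null", corr = c(0, 0))))
  scr <- coverageScreen(jm, model, nMC = 4000L, seed = 21L)
  # 4 items + NAS, 3 covariates
  expect_identical(nrow(scr), 15L)
  expect_identical(anyDuplicated(paste(scr$target, scr$covariate)), 0L)
  # within a target, coverage is non-increasing
  for (tg in unique(scr$target))
    expect_true(all(diff(scr$coverage[scr$target == tg]) <= 1e-12))
  # expected scores bounded by the score range
  rng <- c(steatosis = 3, lobular_inflammation = 3, ballooning = 2,
           fibrosis = 4, NAS = 8)
  expect_true(all(scr$scoreLow >= 0 & scr$scoreHigh <= rng[scr$target]))
  # all-null joint model: no flags
  j0 <- syntheticJointModel(latentCorrelation(model), list(
    list(name = "a", corr = c(0, 0)), list(name = "b", corr = c(0, 0))))
  s0 <- coverageScreen(j0, model, nMC = 4000L, seed = 23L)
  expect_identical(sum(s0$influential), 0L)
})
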