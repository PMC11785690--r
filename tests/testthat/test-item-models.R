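# Item response functions: closed-form values, normalization, monotonicity,
# the 2PL/graded-response equivalence at two categories, and simulation
# consistency.

test_that("cumulative and category probabilities match closed-form logistic values", {
  it <- itemParameters("x", "ordered", 3L, 1L, c(1, 0, 0, 0, 0), c(1, -1))
  expect_equal(grmCumulative(it, rep(0, 5)),
               c(1 / (1 + exp(-1)), 1 / (1 + exp(1))), tolerance = 1e-12)
  expect_equal(categoryProbs(it, rep(0, 5)),
               c(1 - plogis(1), plogis(1) - plogis(-1), plogis(-1)),
               tolerance = 1e-12)
  # no loading: theta irrelevant
  it0 <- itemParameters("null", "ordered", 3L, 1L, rep(0, 5), c(1, -1))
  for (th in list(rep(0, 5), c(3, -2, 1, 0.5, -4)))
    expect_equal(grmCumulative(it0, th), c(plogis(1), plogis(-1)),
                 tolerance = 1e-12)
  # binary at zero logit
  bi <- itemParameters("b", "binary", 2L, 1L, c(2, 0, 0, 0, 0), 0)
  expect_equal(categoryProbs(bi, rep(0, 5)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("random cases agree with independent high-precision evaluation", {
  set.seed(14)
  for (r in 1:200) {
    K <- sample(2:5, 1)
    a <- rnorm(5) * rbinom(5, 1, 0.7)
    pat <- which(a != 0)
    if (!length(pat)) { pat <- 1L; a[1] <- 0 }
    d <- sort(rnorm(K - 1, sd = 2), decreasing = TRUE)
    if (K > 2) d <- d - cumsum(c(0, rep(1e-3, K - 2)))
    it <- itemParameters("r", if (K == 2) "binary" else "ordered", K, pat, a, d)
    th <- rnorm(5)
    eta <- sum(a * th)
    expect_equal(grmCumulative(it, th), 1 / (1 + exp(-(eta + d))),
                 tolerance = 1e-12)
    p <- categoryProbs(it, th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(expectedItemScore(it, th), sum(seq_len(K - 1) * p[-1]),
                 tolerance = 1e-12)
  }
})

test_that("normalization holds over 1000 random parameter/theta draws", {
  set.seed(77)
  err <- replicate(1000, {
    K <- sample(2:5, 1)
    a <- rnorm(5, sd = 1.5)
    d <- sort(rnorm(K - 1, sd = 3), decreasing = TRUE) - seq_len(K - 1) * 1e-6
    it <- itemParameters("r", if (K == 2) "binary" else "ordered", K, 1:5, a, d)
    abs(sum(categoryProbs(it, rnorm(5, sd = 2))) - 1)
  })
  expect_lt(max(err), 1e-12)
})

test_that("cumulative probability is strictly increasing in the linear predictor", {
  it <- itemParameters("x", "ordered", 4L, 1L, c(1.3, 0, 0, 0, 0), c(2, 0, -2))
  th <- seq(-4, 4, length.out = 81)
  cum <- grmCumulative(it, cbind(th, 0, 0, 0, 0))
  expect_true(all(diff(cum[, 1]) > 0))
  expect_true(all(diff(cum[, 2]) > 0))
  expect_true(all(diff(cum[, 3]) > 0))
  # and decreasing across thresholds at fixed theta
  expect_true(all(cum[, 1] > cum[, 2] & cum[, 2] > cum[, 3]))
})

test_that("a two-category graded item is exactly the 2PL", {
  a <- c(1.7, -0.4, 0, 0.9, 0)
  d <- 0.3
  grm <- itemParameters("g", "ordered", 2L, c(1, 2, 4), a, d)
  pl2 <- itemParameters("p", "binary", 2L, c(1, 2, 4), a, d)
  th <- cbind(seq(-5, 5, length.out = 100), 0.3, 0, -0.2, 0)
  expect_equal(categoryProbs(grm, th), categoryProbs(pl2, th), tolerance = 1e-12)
})

test_that("expected score is bounded and monotone; NAS components stay in 0-8", {
  it <- itemParameters("f", "ordered", 5L, 4L, c(0, 0, 0, 1.8, 0),
                       c(1.5, 0, -1.5, -3))
  th <- cbind(0, 0, 0, seq(-5, 5, length.out = 50), 0)
  es <- expectedItemScore(it, th)
  expect_true(all(es >= 0 & es <= 4))
  expect_true(all(diff(es) > 0))
  # NAS = steatosis + inflammation + ballooning expected scores, range 0-8
  cfg <- defaultTruth(10L)
  nas <- vapply(c("steatosis", "lobular_inflammation", "ballooning"),
                function(nm) {
                  it <- cfg@items[[match(nm, vapply(cfg@items, itemName, ""))]]
                  expectedItemScore(it, rep(8, 5)) # extreme disease
                }, 0)
  expect_lte(sum(nas), 8)
  expect_gte(sum(nas), 0)
})

test_that("simulated responses reproduce the category distribution", {
  it <- itemParameters("x", "ordered", 4L, 1L, c(1.2, 0, 0, 0, 0), c(1.5, 0, -1.5))
  th <- matrix(rep(c(0.7, 0, 0, 0, 0), each = 1e5), 1e5)
  y <- simulateResponse(it, th, seed = 5)
  p <- categoryProbs(it, c(0.7, 0, 0, 0, 0))
  emp <- as.numeric(table(factor(y, levels = 0:3))) / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(emp - p) < 3 * se + 1e-9))
  # degenerate: certain success
  sure <- itemParameters("s", "binary", 2L, 1L, c(0, 0, 0, 0, 0), 20)
  expect_true(all(simulateResponse(sure, matrix(0, 50, 5), seed = 1) == 1L))
  # seed reproducibility
  expect_identical(simulateResponse(it, th[1:100, ], seed = 9),
                   simulateResponse(it, th[1:100, ], seed = 9))
})

test_that("subject log-likelihood sums per-item log probabilities and skips missing", {
  items <- toy1dItems()
  items5 <- lapply(items, function(it)
    itemParameters(itemName(it), itemKind(it), nCategories(it), 1L,
                   c(slopes(it), 0, 0, 0, 0), intercepts(it)))
  th <- c(0.5, 0, 0, 0, 0)
  y <- c(1L, 0L, 2L)
  manual <- sum(vapply(1:3, function(j)
    log(categoryProbs(items5[[j]], th)[y[j] + 1L]), 0))
  expect_equal(subjectLoglik(items5, y, th), manual, tolerance = 1e-12)
  expect_identical(subjectLoglik(items5, c(NA, NA, NA), th), 0)
  half <- subjectLoglik(items5, c(1L, NA, NA), th)
  expect_equal(half, log(categoryProbs(items5[[1]], th)[2]), tolerance = 1e-12)
  # single binary item with p = 0.5
  b <- itemParameters("b", "binary", 2L, 1L, rep(0, 5), 0)
  expect_equal(subjectLoglik(list(b), 1L, th), log(0.5), tolerance = 1e-12)
})

test_that("construction rejects invalid parameters", {
  expect_error(itemParameters("x", "ordered", 3L, 1L, c(1, 0, 0, 0, 0), c(-1, 1)),
               "decreasing")
  expect_error(itemParameters("x", "binary", 3L, 1L, c(1, 0, 0, 0, 0), c(1, -1)),
               "2 categories")
  expect_error(itemParameters("x", "ordered", 3L, 2L, c(1, 0, 0, 0, 0), c(1, -1)),
               "outside its loading pattern")
  expect_error(itemParameters("x", "ordered", 3L, integer(0), rep(0, 5), c(1, -1)))
})

test_that("model JSON serialization round-trips", {
  cfg <- defaultTruth(10L)
  model <- latentModel(cfg@items, cfg@Sigma)
  path <- withr::local_tempfile(fileext = ".json")
  modelToJson(model, path)
  back <- modelFromJson(path)
  expect_equal(latentCorrelation(back), latentCorrelation(model),
               tolerance = 1e-12)
  for (nm in itemNames(model)) {
    expect_equal(slopes(modelItems(back)[[nm]]), slopes(modelItems(model)[[nm]]))
    expect_equal(intercepts(modelItems(back)[[nm]]),
                 intercepts(modelItems(model)[[nm]]))
  }
  # fixed field names in the document
  doc <- jsonlite::fromJSON(path)
  expect_true(all(c("name", "kind", "n_categories", "loading_pattern",
                    "slopes", "intercepts") %in% names(doc$items)))
})
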