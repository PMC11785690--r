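# Covariate classification, the missing-data EM, the joint latent-covariate
# model and closed-form conditioning.

test_that("covariate columns are classified by type, with log for skewed positives", {
  set.seed(50)
  df <- data.frame(
    platelets = exp(rnorm(400, log(239000), 0.9)),   # strongly right-skewed
    symm = rnorm(400, 100, 10),
    sex = rbinom(400, 1, 0.36),
    smoking = sample(c("never", "former", "current"), 400, TRUE,
                     prob = c(0.5, 0.3, 0.2)))
  sp <- specTable(buildCovariateSpecs(df))
  expect_identical(sp$kind, c("continuous", "continuous", "binary", "categorical"))
  expect_identical(sp$transform[1], "log")
  expect_identical(sp$transform[2], "none")
  expect_identical(sp$reference[4], "never")   # most frequent level
  # one indicator per non-reference level
  des <- hepirt:::covariateDesign(df, buildCovariateSpecs(df))
  expect_setequal(des$columns$smoking, c("smoking=current", "smoking=former"))
  # overrides are honored
  sp2 <- specTable(buildCovariateSpecs(df, overrides = list(
    platelets = list(transform = "none"))))
  expect_identical(sp2$transform[1], "none")
})

test_that("EM on missing-at-random data matches the complete-data estimate", {
  set.seed(51)
  n <- 5000
  S <- matrix(c(1, 0.6, 0.3, 0.6, 1, 0.5, 0.3, 0.5, 1), 3)
  X <- matrix(rnorm(n * 3), n, 3) %*% chol(S)
  full <- mvnEM(X)
  expect_lt(max(abs(full$cov - cov(X) * (n - 1) / n)), 1e-3)
  Xm <- X
  Xm[runif(n) < 0.3, 2] <- NA
  Xm[runif(n) < 0.3, 3] <- NA
  em <- mvnEM(Xm)
  expect_true(em$converged)
  expect_lt(max(abs(em$cov - full$cov)), 0.05)
  expect_lt(max(abs(em$mean - full$mean)), 0.05)
  # degenerate inputs
  expect_error(mvnEM(cbind(X[, 1], NA)), "missing")
})

test_that("joint model errors name the offending covariate", {
  sim <- simulateToy1d(80, seed = 52)
  model <- latentModel(sim$items, matrix(1, 1, 1))
  sc <- eapScores(model, sim$responses, nDraws = 50L, seed = 1L)
  covs <- data.frame(ok = rnorm(80), allmiss = NA_real_)
  expect_error(fitJointModel(sc, covs, nImputations = 2L), "allmiss")
  covs2 <- data.frame(ok = rnorm(80), flat = 1)
  expect_error(fitJointModel(sc, covs2, nImputations = 2L), "flat")
})

test_that("a covariate independent of the latent vector shows near-zero correlation", {
  cfg <- defaultTruth(800L)
  model <- latentModel(cfg@items, cfg@Sigma)
  pop <- generatePopulation(cfg, seed = 53)
  sc <- eapScores(model, pop$responses, nDraws = 120L, seed = 2L)
  set.seed(54)
  covs <- data.frame(noise = rnorm(800), temp = pop$covariates$temperature)
  jm <- fitJointModel(sc, covs, nImputations = 5L)
  r <- covariateLatentCorrelations(jm)
  expect_lt(max(abs(r["noise", ])), 3.5 / sqrt(800) * 2)
})

test_that("conditional distribution matches closed-form MVN conditioning and sampling", {
  S <- defaultLatentCorrelation()
  jm <- syntheticJointModel(S, list(
    list(name = "age", corr = c(0, 0, 0.15, 0.45, 0), mean = 50, sd = 12),
    list(name = "null", corr = rep(0, 5))))
  cl <- conditionalLatent(jm, "age", 74)     # +2 sd
  # manual closed form
  cross <- 12 * c(0, 0, 0.15, 0.45, 0)
  muMan <- cross / 144 * (74 - 50)
  SgMan <- S - tcrossprod(cross) / 144
  expect_equal(unname(cl$mean), muMan, tolerance = 1e-10)
  expect_equal(cl$cov, SgMan, tolerance = 1e-10, ignore_attr = TRUE)
  # zero-correlation covariate leaves the prior untouched
  cl0 <- conditionalLatent(jm, "null", 3)
  expect_equal(unname(cl0$mean), rep(0, 5), tolerance = 1e-12)
  expect_equal(cl0$cov, S, tolerance = 1e-12, ignore_attr = TRUE)
  # sampling oracle: condition by rejection-free regression of joint draws
  set.seed(55)
  n <- 1e6
  z <- matrix(rnorm(n * 6), n, 6)
  draws <- z %*% chol(jm@cov[c(1:5, 6), c(1:5, 6)])
  sel <- abs(draws[, 6] - (74 - 50)) < 1.2
  empMean <- colMeans(draws[sel, 1:5])
  expect_lt(max(abs(empMean - muMan)), 0.02)
  empCov <- cov(draws[sel, 1:5])
  expect_lt(max(abs(empCov - SgMan)), 0.03)
  # conditional covariance never exceeds the marginal (Loewner order)
  ev <- eigen(S - cl$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

pop2000 <- function() fixture("pop2000", function()
  generatePopulation(defaultTruth(2000L), seed = 56))

scores2000 <- function() fixture("scores2000", function() {
  cfg <- defaultTruth(2000L)
  eapScores(latentModel(cfg@items, cfg@Sigma), pop2000()$responses,
            nDraws = 200L, seed = 3L)
})

test_that("joint model recovers a strong negative platelet-type correlation", {
  # dedicated scenario: one log-normal covariate with latent correlation -0.5
  cfg <- defaultTruth(2000L)
  pop <- pop2000()
  sc <- scores2000()
  Si <- solve(cfg@Sigma)
  cc <- c(0, 0, 0, -0.5, 0)
  b <- drop(Si %*% cc)
  set.seed(57)
  u <- drop(pop$theta %*% b) + sqrt(1 - sum(cc * b)) * rnorm(2000)
  covs <- data.frame(platelet_like = exp(log(239000) + 0.45 * u))
  jm <- fitJointModel(sc, covs, nImputations = 8L)
  est <- covariateLatentCorrelations(jm)["platelet_like", 4]
  expect_lt(abs(est - (-0.5)), 0.08)
})

test_that("imputation count hardly changes the estimates", {
  pop <- pop2000()
  sc <- scores2000()
  covs <- pop$covariates[, c("age", "alt", "platelet_count", "diabetes")]
  j5 <- fitJointModel(sc, covs, nImputations = 5L)
  j20 <- fitJointModel(sc, covs, nImputations = 20L)
  expect_lt(max(abs(covariateLatentCorrelations(j5) -
                    covariateLatentCorrelations(j20))), 0.02)
  # theta block equals the reference latent correlation used for correction
  expect_equal(jointCorrelation(j5)[1:5, 1:5],
               jointCorrelation(j20)[1:5, 1:5], tolerance = 0.02)
})
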