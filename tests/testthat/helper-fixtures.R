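# Shared fixtures, generated in code. Heavy objects (fitted models) are
# cached so several test files can reuse them within one run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, fun(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a small 1-LV toy: two binary + one 4-category item
toy1dItems <- function() list(
  itemParameters("b1", "binary", 2L, 1L, 1.2, 0.5),
  itemParameters("b2", "binary", 2L, 1L, 0.8, -0.7),
  itemParameters("o1", "ordered", 4L, 1L, 1.5, c(1.5, 0, -1.5)))

toy1dMap <- function() new("LoadingMap",
                           items = list(b1 = 1L, b2 = 1L, o1 = 1L),
                           nLatent = 1L)

simulateToy1d <- function(N, seed) {
  items <- toy1dItems()
  set.seed(seed)
  theta <- matrix(rnorm(N), N, 1)
  resp <- vapply(items, function(it) simulateResponse(it, theta), integer(N))
  colnames(resp) <- vapply(items, itemName, "")
  list(responses = resp, theta = theta, items = items)
}

# construct a JointModel directly from a latent correlation matrix and a list
# of continuous/binary covariates with chosen latent correlations; mutual
# covariate correlations are induced through the latent vector (Gaussian
# copula convention, matching the synthetic generator)
syntheticJointModel <- function(Sigma, covs) {
  L <- nrow(Sigma)
  Si <- solve(Sigma)
  m <- length(covs)
  nms <- vapply(covs, `[[`, "", "name")
  sds <- vapply(covs, function(cv) if (is.null(cv$sd)) 1 else cv$sd, 0)
  mns <- vapply(covs, function(cv) if (is.null(cv$mean)) 0 else cv$mean, 0)
  C <- t(vapply(covs, `[[`, numeric(L), "corr"))      # m x L correlations
  xx <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    xx[i, j] <- if (i == j) 1 else drop(C[i, ] %*% Si %*% C[j, ])
  cov <- matrix(0, L + m, L + m)
  cov[seq_len(L), seq_len(L)] <- Sigma
  cov[seq_len(L), L + seq_len(m)] <- t(C * sds)
  cov[L + seq_len(m), seq_len(L)] <- C * sds
  cov[L + seq_len(m), L + seq_len(m)] <- xx * tcrossprod(sds)
  latentNames <- paste0("LV", seq_len(L))
  colnames(cov) <- rownames(cov) <- c(latentNames, nms)
  tab <- do.call(rbind, lapply(covs, function(cv) data.frame(
    name = cv$name, kind = if (is.null(cv$kind)) "continuous" else cv$kind,
    transform = if (is.null(cv$transform)) "none" else cv$transform,
    reference = "0", units = "", stringsAsFactors = FALSE)))
  lvls <- list()
  marg <- list()
  for (cv in covs) {
    if (!is.null(cv$kind) && cv$kind == "binary") {
      lvls[[cv$name]] <- c(0, 1)
      marg[[cv$name]] <- list(kind = "binary", levels = c("0", "1"),
                              probs = c(1 - cv$prevalence, cv$prevalence),
                              reference = "0")
    } else {
      mn <- if (is.null(cv$mean)) 0 else cv$mean
      sd <- if (is.null(cv$sd)) 1 else cv$sd
      marg[[cv$name]] <- list(kind = "continuous", median = mn,
                              p2.5 = mn - 1.96 * sd, p97.5 = mn + 1.96 * sd)
    }
  }
  specs <- new("CovariateSpecs", table = tab, levels = lvls)
  cols <- as.list(nms)
  names(cols) <- nms
  new("JointModel", mean = stats::setNames(c(rep(0, L), mns), colnames(cov)),
      cov = cov, corr = stats::cov2cor(cov), latentNames = latentNames,
      columns = cols, marginals = marg, specs = specs,
      nImputations = 1L, nSubjects = 0L)
}

# a 2-LV reduced model used by expected-score oracle checks
reduced2dModel <- function() {
  items <- list(
    itemParameters("steatosis", "ordered", 4L, 1L, c(1.8, 0), c(2, 0, -2)),
    itemParameters("lobular_inflammation", "ordered", 4L, 1L, c(1.4, 0),
                   c(3, 0.6, -2)),
    itemParameters("ballooning", "ordered", 3L, 2L, c(0, 2.4), c(1, -1)),
    itemParameters("fibrosis", "ordered", 5L, 2L, c(0, 1.8),
                   c(1.5, 0, -1.5, -3)))
  latentModel(items, matrix(c(1, 0.5, 0.5, 1), 2))
}
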