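# Expected a posteriori (EAP) scoring of subjects on the latent disease
# facets, by Metropolis-Hastings sampling of theta | responses under the
# fitted model. Posterior draws are retained for the covariate stage, which
# treats them as multiple imputations of the latent vector.

#' Score subjects on the latent disease facets
#'
#' Samples each subject's posterior `theta | responses` under the fitted item
#' parameters and latent correlation matrix with a random-walk
#' Metropolis-Hastings chain (vectorized over subjects), and returns posterior
#' means, covariances and retained draws. Subjects with all items missing get
#' the prior exactly: mean zero, covariance equal to the latent correlation
#' matrix.
#'
#' @param model a [LatentModel-class] or [FittedModel-class].
#' @param responses integer matrix/data frame of 0-based item categories,
#'   columns matching the model's items; `NA` allowed.
#' @param nDraws number of retained posterior draws per subject.
#' @param seed integer seed; scoring is deterministic given the seed.
#' @param burn number of burn-in iterations. Generous burn-in and thinning
#'   matter beyond Monte Carlo error: the covariate stage corrects for
#'   posterior shrinkage using the average posterior covariance, which an
#'   under-mixed chain underestimates.
#' @param thin thinning interval between retained draws.
#' @return A [SubjectScores-class] object.
#' @export
eapScores <- function(model, responses, nDraws = 200L, seed = 1L,
                      burn = 300L, thin = 3L) {
  stopifnot(is(model, "LatentModel"), isCount(nDraws), isCount(thin))
  items <- modelItems(model)
  nms <- itemNames(model)
  resp <- as.matrix(as.data.frame(responses)[, nms, drop = FALSE])
  storage.mode(resp) <- "integer"
  N <- nrow(resp)
  L <- nLatent(model)
  Sigma <- latentCorrelation(model)
  ids <- rownames(resp)
  if (is.null(ids)) ids <- as.character(seq_len(N))

  A <- do.call(rbind, lapply(items, slopes))
  dList <- lapply(items, intercepts)
  K <- vapply(items, nCategories, 0L)
  obsList <- lapply(seq_along(items), function(j) which(!is.na(resp[, j])))

  draws <- array(0, dim = c(N, L, nDraws))
  withSeed(seed, {
    Theta <- matrix(0, N, L)
    U <- Theta %*% t(A)
    cholS <- chol(Sigma)
    llCur <- respLoglik(U, resp, obsList, dList, K) + dmvnLog(Theta, Sigma, cholS)
    scale <- 0.6
    kept <- 0L
    total <- burn + nDraws * thin
    for (iter in seq_len(total)) {
      Prop <- Theta + matrix(stats::rnorm(N * L, sd = scale), N, L)
      Up <- Prop %*% t(A)
      llProp <- respLoglik(Up, resp, obsList, dList, K) +
        dmvnLog(Prop, Sigma, cholS)
      acc <- log(stats::runif(N)) < llProp - llCur
      if (any(acc)) {
        Theta[acc, ] <- Prop[acc, ]
        llCur[acc] <- llProp[acc]
      }
      if (iter <= burn) {
        scale <- min(2, max(0.05, scale * exp(0.1 * (mean(acc) - 0.35))))
      } else if ((iter - burn) %% thin == 0L) {
        kept <- kept + 1L
        draws[, , kept] <- Theta
      }
    }
  })

  mean <- apply(draws, c(1L, 2L), mean)
  covs <- array(0, dim = c(L, L, N))
  for (i in seq_len(N)) {
    di <- t(draws[i, , , drop = TRUE])
    if (L == 1L) di <- matrix(draws[i, 1L, ], ncol = 1L)
    covs[, , i] <- stats::cov(di) * (nDraws - 1L) / nDraws
  }
  allMissing <- rowSums(!is.na(resp)) == 0L
  if (any(allMissing)) {
    idx <- which(allMissing)
    mean[idx, ] <- 0
    for (i in idx) covs[, , i] <- Sigma
    # prior draws for all-missing subjects, deterministic given the same seed
    pri <- withSeed(subSeed(seed, 1L),
                    rmvn(length(idx) * nDraws, rep(0, L), Sigma))
    k <- 0L
    for (i in idx) for (m in seq_len(nDraws)) {
      k <- k + 1L
      draws[i, , m] <- pri[k, ]
    }
  }
  new("SubjectScores", ids = ids, mean = mean, cov = covs, draws = draws,
      nDraws = as.integer(nDraws), prior = Sigma)
}
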