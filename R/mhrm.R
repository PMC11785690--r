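# Marginal maximum likelihood for the multidimensional item response model by
# Metropolis-Hastings Robbins-Monro (MHRM) stochastic approximation.
#
# Each cycle alternates (i) a Metropolis-Hastings sweep updating every
# subject's latent vector given the current parameters with (ii) gain-weighted
# Fisher-scoring updates of the item parameters and a gain-weighted update of
# the latent correlation matrix from the sampled latent vectors. During
# burn-in the gain is 1 (stochastic EM); afterwards it decays as 1/k^alpha so
# the parameter sequence averages out the Monte Carlo noise.

#' Options controlling the MHRM fit
#'
#' @param burnIn number of constant-gain (stochastic EM) cycles.
#' @param maxCycles maximum number of decaying-gain Robbins-Monro cycles.
#' @param gainExponent alpha in the Robbins-Monro gain `1 / k^alpha`;
#'   must lie in (0.5, 1].
#' @param mhSweeps Metropolis-Hastings sweeps per subject per cycle.
#' @param proposalSd initial random-walk proposal standard deviation; adapted
#'   during burn-in toward the target acceptance rate, then frozen.
#' @param targetAcceptance acceptance rate targeted by the adaptation.
#' @param convergenceTol parameter-update tolerance declaring convergence.
#' @param convergenceWindow cycles per convergence window.
#' @param convergenceWindows number of consecutive windows in which every
#'   update must stay below `convergenceTol`.
#' @param stepCap largest parameter change allowed in a single cycle.
#' @param minGain floor on the Robbins-Monro gain. With a floor the late
#'   cycles form a constant-gain stochastic-approximation phase whose
#'   iterates orbit the maximum likelihood estimate; the tail average then
#'   centers on it. Weakly identified directions (cross-loadings of rare
#'   binary lesions on correlated facets) would otherwise freeze wherever
#'   the decaying gain leaves them.
#' @param averageTail fraction of the Robbins-Monro phase (from the end) over
#'   which parameter iterates are averaged into the reported estimate
#'   (Polyak-Ruppert averaging); set 0 to report the final iterate.
#' @param seed integer seed; the fit is deterministic given options and seed.
#' @param verbose print cycle diagnostics every 50 cycles.
#' @return A list of validated options for [fitIRT()].
#' @export
fitOptions <- function(burnIn = 200L, maxCycles = 400L, gainExponent = 0.75,
                       mhSweeps = 1L, proposalSd = 0.6,
                       targetAcceptance = 0.35, convergenceTol = 1e-3,
                       convergenceWindow = 10L, convergenceWindows = 3L,
                       stepCap = 0.5, minGain = 0.1, averageTail = 0.7,
                       seed = 1L, verbose = FALSE) {
  stopifnot(isCount(burnIn), isCount(maxCycles),
            gainExponent > 0.5, gainExponent <= 1,
            isCount(mhSweeps), proposalSd > 0,
            targetAcceptance > 0, targetAcceptance < 1,
            convergenceTol > 0, isCount(convergenceWindow),
            isCount(convergenceWindows), stepCap > 0,
            minGain >= 0, minGain <= 1,
            averageTail >= 0, averageTail <= 1)
  list(burnIn = as.integer(burnIn), maxCycles = as.integer(maxCycles),
       gainExponent = gainExponent, mhSweeps = as.integer(mhSweeps),
       proposalSd = proposalSd, targetAcceptance = targetAcceptance,
       convergenceTol = convergenceTol,
       convergenceWindow = as.integer(convergenceWindow),
       convergenceWindows = as.integer(convergenceWindows),
       stepCap = stepCap, minGain = minGain, averageTail = averageTail,
       seed = as.integer(seed), verbose = isTRUE(verbose))
}

# total complete-data log-likelihood contributions per subject, given the
# linear-predictor matrix U = Theta %*% t(A)
respLoglik <- function(U, resp, obsList, dList, K) {
  ll <- numeric(nrow(U))
  for (j in seq_along(dList)) {
    obs <- obsList[[j]]
    if (!length(obs)) next
    y <- resp[obs, j]
    e <- U[obs, j]
    d <- dList[[j]]
    Kj <- K[j]
    lo <- rep(1, length(obs))
    hasLo <- y >= 1L
    lo[hasLo] <- stats::plogis(e[hasLo] + d[y[hasLo]])
    hi <- rep(0, length(obs))
    hasHi <- y < Kj - 1L
    hi[hasHi] <- stats::plogis(e[hasHi] + d[y[hasHi] + 1L])
    ll[obs] <- ll[obs] + log(pmax(lo - hi, 1e-300))
  }
  ll
}

# gradient and expected information for one item's free parameters,
# ordered (d_1..d_{K-1}, a_free)
itemGradInfo <- function(y, Th, a, d, freeLV) {
  K <- length(d) + 1L
  n <- length(y)
  e <- drop(Th %*% a)
  P <- stats::plogis(outer(e, d, "+"))          # n x (K-1) cumulative probs
  if (!is.matrix(P)) P <- matrix(P, nrow = n)
  W <- P * (1 - P)
  pcat <- cbind(1, P) - cbind(P, 0)             # n x K category probs
  pcat <- pmax(pcat, 1e-12)
  pobs <- pcat[cbind(seq_len(n), y + 1L)]
  # per-subject gradient: two nonzero cumulative components, k = y and k = y+1
  d1 <- ifelse(y >= 1L, W[cbind(seq_len(n), pmax(y, 1L))] / pobs, 0)
  d2 <- ifelse(y < K - 1L, -W[cbind(seq_len(n), pmin(y + 1L, K - 1L))] / pobs, 0)
  s <- d1 + d2
  gd <- numeric(K - 1L)
  for (k in seq_len(K - 1L))
    gd[k] <- sum(d1[y == k]) + sum(d2[y + 1L == k])
  ThF <- Th[, freeLV, drop = FALSE]
  ga <- drop(crossprod(ThF, s))
  # expected information given theta: s_c and category probabilities
  Smat <- matrix(0, n, K)                       # s_c for each category c
  for (cc in 0:(K - 1L)) {
    v <- numeric(n)
    if (cc >= 1L) v <- v + W[, cc]
    if (cc <= K - 2L) v <- v - W[, cc + 1L]
    Smat[, cc + 1L] <- v / pcat[, cc + 1L]
  }
  # B block (intercepts): tridiagonal
  Bd <- numeric(K - 1L); Bo <- numeric(max(K - 2L, 0L))
  for (k in seq_len(K - 1L)) {
    Bd[k] <- sum(W[, k]^2 * (1 / pcat[, k + 1L] + 1 / pcat[, k]))
    if (k <= K - 2L)
      Bo[k] <- -sum(W[, k] * W[, k + 1L] / pcat[, k + 1L])
  }
  # b block (intercept x slope): w_k (s_k - s_{k-1}) per subject
  bs <- matrix(0, K - 1L, length(freeLV))
  for (k in seq_len(K - 1L)) {
    wk <- W[, k] * (Smat[, k + 1L] - Smat[, k])
    bs[k, ] <- colSums(ThF * wk)
  }
  vq <- rowSums(pcat * Smat^2)
  Ablk <- crossprod(ThF, ThF * vq)
  p <- K - 1L + length(freeLV)
  I <- matrix(0, p, p)
  diag(I)[seq_len(K - 1L)] <- Bd
  if (K > 2L) for (k in seq_len(K - 2L)) {
    I[k, k + 1L] <- I[k + 1L, k] <- Bo[k]
  }
  I[seq_len(K - 1L), K:p] <- bs
  I[K:p, seq_len(K - 1L)] <- t(bs)
  I[K:p, K:p] <- Ablk
  list(g = c(gd, ga), I = I)
}

resolveAnchors <- function(map, anchor) {
  L <- map@nLatent
  pats <- map@items
  exclusive <- lapply(seq_len(L), function(l)
    names(pats)[vapply(pats, function(p) identical(p, l), TRUE)])
  needs <- which(!vapply(exclusive, function(x) length(x) > 0L, TRUE))
  out <- list()
  if (is.null(anchor) || !length(needs)) return(out)
  if (identical(anchor, "auto")) {
    for (l in needs) {
      cand <- names(pats)[vapply(pats, function(p) l %in% p, TRUE)]
      pick <- if ("portal_inflammation" %in% cand) "portal_inflammation"
              else cand[1L]
      out[[as.character(l)]] <- pick
    }
  } else {
    if (is.null(names(anchor)))
      stop("'anchor' must be \"auto\", NULL, or a character vector named by LV index")
    for (l in needs) {
      nm <- anchor[[as.character(l)]]
      if (!is.null(nm)) out[[as.character(l)]] <- nm
    }
  }
  out
}

#' Fit the histological liver score model by MHRM
#'
#' Marginal maximum likelihood estimation of all item slopes and intercepts
#' together with the latent correlation matrix, for binary (2PL) and ordered
#' (graded-response) items over correlated standard-normal latent variables.
#'
#' Latent scale is identified by fixing all latent variances to one (the
#' latent covariance is a correlation matrix). Sign is identified by
#' constraining each latent variable's orientation item (its exclusive loader,
#' or the anchor item) to a positive slope; orientation is applied by sign
#' flipping after the run. A latent variable without an exclusive loading item
#' (LV5 in the default map) is additionally rotationally unidentified; for
#' such variables the designated anchor item is constrained to load on that
#' variable only (see the package vignette).
#'
#' @param responses integer matrix or data frame, one column per item, 0-based
#'   categories, `NA` allowed. Column names must match the loading map.
#' @param map a [LoadingMap-class].
#' @param options list from [fitOptions()].
#' @param nCat optional named integer vector of category counts; inferred from
#'   the data when `NULL`.
#' @param anchor `"auto"` (default), `NULL`, or a character vector named by
#'   latent-variable index giving the anchor item for each latent variable
#'   that lacks an exclusive loading item.
#' @param nStarts number of independent MHRM chains. With more than one, the
#'   chains run from distinct sub-seeds and the reported parameters are their
#'   average: the stochastic-approximation noise of a single chain (sizable
#'   for weakly identified cross-loadings at moderate N) averages out, while
#'   every chain targets the same maximum likelihood estimate.
#' @return A [FittedModel-class].
#' @export
fitIRT <- function(responses, map, options = fitOptions(), nCat = NULL,
                   anchor = "auto", nStarts = 1L) {
  stopifnot(isCount(nStarts))
  if (nStarts > 1L) {
    fits <- lapply(seq_len(nStarts), function(k) {
      op <- options
      op$seed <- subSeed(options$seed, k)
      fitIRT(responses, map, op, nCat = nCat, anchor = anchor, nStarts = 1L)
    })
    base <- fits[[1L]]
    L <- nLatent(base)
    Sigma <- nearestPDCorr(Reduce(`+`, lapply(fits, latentCorrelation)) / nStarts,
                           minEig = 1e-6)
    items <- lapply(itemNames(base), function(nm) {
      sl <- Reduce(`+`, lapply(fits, function(f) slopes(modelItems(f)[[nm]]))) / nStarts
      dd <- Reduce(`+`, lapply(fits, function(f) intercepts(modelItems(f)[[nm]]))) / nStarts
      it <- modelItems(base)[[nm]]
      itemParameters(nm, itemKind(it), nCategories(it), loadingPattern(it),
                     sl, dd)
    })
    return(new("FittedModel",
               items = stats::setNames(items, itemNames(base)),
               Sigma = Sigma,
               converged = all(vapply(fits, converged, TRUE)),
               standardErrors = standardErrors(base),
               trajectory = trajectory(base), options = options))
  }
  stopifnot(is(map, "LoadingMap"))
  resp <- as.matrix(as.data.frame(responses)[, names(map@items), drop = FALSE])
  storage.mode(resp) <- "integer"
  N <- nrow(resp)
  J <- ncol(resp)
  L <- map@nLatent
  if (N < 50L)
    warning("fewer than 50 subjects; estimates will be unstable")
  itemNms <- colnames(resp)
  K <- integer(J)
  for (j in seq_len(J)) {
    obsVals <- resp[!is.na(resp[, j]), j]
    if (!length(obsVals) || length(unique(obsVals)) < 2L)
      stop(sprintf("item '%s' has fewer than two observed categories",
                   itemNms[j]))
    K[j] <- if (!is.null(nCat)) as.integer(nCat[[itemNms[j]]])
            else max(obsVals) + 1L
    if (any(obsVals < 0L | obsVals > K[j] - 1L))
      stop(sprintf("item '%s': responses outside 0..%d", itemNms[j], K[j] - 1L))
  }

  freeMask <- matrix(FALSE, J, L, dimnames = list(itemNms, NULL))
  for (j in seq_len(J)) freeMask[j, map@items[[itemNms[j]]]] <- TRUE
  anchors <- resolveAnchors(map, anchor)
  for (l in names(anchors)) {
    aj <- match(anchors[[l]], itemNms)
    if (is.na(aj)) stop(sprintf("anchor item '%s' not found", anchors[[l]]))
    keep <- as.integer(l)
    freeMask[aj, setdiff(seq_len(L), keep)] <- FALSE
    if (!freeMask[aj, keep])
      stop(sprintf("anchor item '%s' does not load on LV%s", anchors[[l]], l))
  }

  # starting values: marginal cumulative logits, unit slopes, identity Sigma
  A <- matrix(0, J, L, dimnames = list(itemNms, NULL))
  A[freeMask] <- 1
  dList <- vector("list", J)
  for (j in seq_len(J)) {
    y <- resp[!is.na(resp[, j]), j]
    pg <- vapply(seq_len(K[j] - 1L), function(k) mean(y >= k), 0)
    pg <- pmin(pmax(pg, 1e-3), 1 - 1e-3)
    d0 <- stats::qlogis(pg)
    for (k in seq_along(d0)[-1]) d0[k] <- min(d0[k], d0[k - 1L] - 0.01)
    dList[[j]] <- d0
  }
  Sigma <- diag(L)
  obsList <- lapply(seq_len(J), function(j) which(!is.na(resp[, j])))

  op <- options
  totalCycles <- op$burnIn + op$maxCycles
  traj <- data.frame(cycle = integer(totalCycles), phase = character(totalCycles),
                     gain = numeric(totalCycles), acceptance = numeric(totalCycles),
                     loglik = numeric(totalCycles), maxUpdate = numeric(totalCycles),
                     stringsAsFactors = FALSE)

  result <- withSeed(op$seed, {
    Theta <- matrix(0, N, L)
    U <- Theta %*% t(A)
    cholS <- chol(Sigma)
    llCur <- respLoglik(U, resp, obsList, dList, K) + dmvnLog(Theta, Sigma, cholS)
    scale <- op$proposalSd
    Hbar <- vector("list", J)
    Sbar <- diag(L)
    belowCount <- 0L
    convergedFlag <- FALSE
    usedCycles <- 0L
    avgStart <- op$burnIn + ceiling((1 - op$averageTail) * op$maxCycles)
    avgN <- 0L
    avgA <- A * 0
    avgD <- lapply(dList, function(d) d * 0)
    avgS <- Sigma * 0

    for (cycle in seq_len(totalCycles)) {
      rmPhase <- cycle > op$burnIn
      gain <- if (rmPhase)
        max(op$minGain, 1 / (cycle - op$burnIn)^op$gainExponent) else 1

      accN <- 0L
      for (sw in seq_len(op$mhSweeps)) {
        Prop <- Theta + matrix(stats::rnorm(N * L, sd = scale), N, L)
        Up <- Prop %*% t(A)
        llProp <- respLoglik(Up, resp, obsList, dList, K) +
          dmvnLog(Prop, Sigma, cholS)
        acc <- log(stats::runif(N)) < llProp - llCur
        if (any(acc)) {
          Theta[acc, ] <- Prop[acc, ]
          U[acc, ] <- Up[acc, ]
          llCur[acc] <- llProp[acc]
        }
        accN <- accN + sum(acc)
      }
      accRate <- accN / (N * op$mhSweeps)
      if (!rmPhase)
        scale <- min(2, max(0.05, scale * exp(0.1 * (accRate - op$targetAcceptance))))

      maxUpd <- 0
      # item parameter updates: gain-weighted Fisher scoring
      for (j in seq_len(J)) {
        obs <- obsList[[j]]
        freeLV <- which(freeMask[j, ])
        gi <- itemGradInfo(resp[obs, j], Theta[obs, , drop = FALSE],
                           A[j, ], dList[[j]], freeLV)
        if (!all(is.finite(gi$g)) || !all(is.finite(gi$I)))
          stop(sprintf("non-finite likelihood quantities at cycle %d (item '%s')",
                       cycle, itemNms[j]))
        Hbar[[j]] <- if (is.null(Hbar[[j]])) gi$I
                     else Hbar[[j]] + gain * (gi$I - Hbar[[j]])
        p <- length(gi$g)
        step <- tryCatch(solve(Hbar[[j]] + diag(1e-4, p), gi$g),
                         error = function(e) gi$g / (diag(gi$I) + 1))
        step <- gain * pmin(pmax(step, -op$stepCap), op$stepCap)
        nd <- K[j] - 1L
        newD <- dList[[j]] + step[seq_len(nd)]
        halvings <- 0L
        while (nd > 1L && any(diff(newD) >= -1e-6) && halvings < 30L) {
          step <- step / 2
          newD <- dList[[j]] + step[seq_len(nd)]
          halvings <- halvings + 1L
        }
        if (nd > 1L && any(diff(newD) >= -1e-6)) next  # skip update, keep valid d
        newA <- A[j, freeLV] + step[nd + seq_along(freeLV)]
        maxUpd <- max(maxUpd, max(abs(c(newD - dList[[j]], newA - A[j, freeLV]))))
        dList[[j]] <- newD
        A[j, freeLV] <- newA
      }
      U <- Theta %*% t(A)

      # latent correlation update from the sampled latent vectors
      if (L > 1L) {
        Ssamp <- crossprod(Theta) / N
        Sbar <- Sbar + gain * (Ssamp - Sbar)
        newSigma <- nearestPDCorr(stats::cov2cor(Sbar), minEig = 1e-6)
        maxUpd <- max(maxUpd, max(abs(newSigma - Sigma)))
        Sigma <- newSigma
        cholS <- chol(Sigma)
      }
      llCur <- respLoglik(U, resp, obsList, dList, K) + dmvnLog(Theta, Sigma, cholS)
      if (!all(is.finite(llCur)))
        stop(sprintf("non-finite likelihood at cycle %d", cycle))

      traj$cycle[cycle] <- cycle
      traj$phase[cycle] <- if (rmPhase) "rm" else "burnin"
      traj$gain[cycle] <- gain
      traj$acceptance[cycle] <- accRate
      traj$loglik[cycle] <- sum(llCur)
      traj$maxUpdate[cycle] <- maxUpd
      usedCycles <- cycle
      if (op$verbose && cycle %% 50L == 0L)
        message(sprintf("cycle %d (%s): loglik %.1f, max update %.2e, acc %.2f",
                        cycle, traj$phase[cycle], sum(llCur), maxUpd, accRate))

      if (rmPhase && op$averageTail > 0 && cycle >= avgStart) {
        avgN <- avgN + 1L
        avgA <- avgA + (A - avgA) / avgN
        for (j in seq_len(J)) avgD[[j]] <- avgD[[j]] + (dList[[j]] - avgD[[j]]) / avgN
        avgS <- avgS + (Sigma - avgS) / avgN
      }
      if (rmPhase) {
        belowCount <- if (maxUpd < op$convergenceTol) belowCount + 1L else 0L
        if (belowCount >= op$convergenceWindow * op$convergenceWindows) {
          convergedFlag <- TRUE
          break
        }
      }
    }
    if (avgN > 0L) {
      A <- avgA
      dList <- avgD
      Sigma <- nearestPDCorr(stats::cov2cor(avgS), minEig = 1e-6)
    }
    list(A = A, dList = dList, Sigma = Sigma, Hbar = Hbar,
         converged = convergedFlag, usedCycles = usedCycles)
  })

  A <- result$A; dList <- result$dList; Sigma <- result$Sigma

  # orientation: positive slope on each LV's orientation item
  catal <- map@items
  for (l in seq_len(L)) {
    excl <- which(vapply(catal, function(p) identical(p, l), TRUE))
    ori <- if (length(excl)) match(names(catal)[excl[1L]], itemNms)
           else if (!is.null(anchors[[as.character(l)]]))
             match(anchors[[as.character(l)]], itemNms)
           else which.max(abs(A[, l]))
    if (A[ori, l] < 0) {
      A[, l] <- -A[, l]
      Sigma[l, -l] <- -Sigma[l, -l]
      Sigma[-l, l] <- -Sigma[-l, l]
    }
  }

  ses <- vector("list", J)
  names(ses) <- itemNms
  items <- vector("list", J)
  for (j in seq_len(J)) {
    freeLV <- which(freeMask[j, ])
    se <- rep(NA_real_, K[j] - 1L + length(freeLV))
    invH <- tryCatch(solve(result$Hbar[[j]]), error = function(e) NULL)
    if (!is.null(invH)) se <- sqrt(pmax(diag(invH), 0))
    ses[[j]] <- list(intercepts = se[seq_len(K[j] - 1L)],
                     slopes = se[K[j] - 1L + seq_along(freeLV)],
                     loadedLV = freeLV)
    sl <- numeric(L); sl[freeLV] <- A[j, freeLV]
    items[[j]] <- itemParameters(itemNms[j],
                                 if (K[j] == 2L) "binary" else "ordered",
                                 K[j],
                                 map@items[[itemNms[j]]], sl, dList[[j]])
  }
  new("FittedModel", items = stats::setNames(items, itemNms),
      Sigma = symmetrize(Sigma), converged = result$converged,
      standardErrors = ses,
      trajectory = utils::head(data.frame(
        cycle = traj$cycle, phase = traj$phase, gain = traj$gain,
        acceptance = traj$acceptance, loglik = traj$loglik,
        maxUpdate = traj$maxUpdate), result$usedCycles),
      options = op)
}
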