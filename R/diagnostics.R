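# Simulation-based model evaluation: replicate datasets simulated under the
# fitted model, observed versus simulated item-pair correlations (posterior
# predictive check of the dependence structure), and mirror frequency
# comparisons of the per-item category distributions.

#' Simulate replicate datasets under a latent model
#'
#' Each dataset draws a fresh latent vector per subject from
#' `MVN(0, Sigma)` and simulates all item responses from the item models.
#'
#' @param model a [LatentModel-class].
#' @param nSim number of replicate datasets (500 by default, matching the
#'   evaluation design).
#' @param N subjects per dataset.
#' @param seed integer seed.
#' @return List of `nSim` integer response matrices (`N x J`, 0-based).
#' @export
simulateDatasets <- function(model, nSim = 500L, N, seed = 1L) {
  stopifnot(is(model, "LatentModel"), isCount(nSim), isCount(N))
  items <- modelItems(model)
  L <- nLatent(model)
  Sigma <- latentCorrelation(model)
  withSeed(seed, {
    lapply(seq_len(nSim), function(s) {
      theta <- rmvn(N, rep(0, L), Sigma)
      out <- vapply(items, function(it) simulateResponse(it, theta),
                    integer(N))
      colnames(out) <- itemNames(model)
      out
    })
  })
}

#' Item-pair correlation matrix
#'
#' Pearson correlations of the raw integer scores, pairwise-complete over
#' missing values.
#'
#' @param responses integer response matrix (subjects x items).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
itemPairCorrelations <- function(responses) {
  r <- stats::cor(as.matrix(responses), use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Posterior predictive check result
#'
#' @slot pairs data.frame per item pair: observed correlation, central-interval
#'   bounds of the simulated correlations, inside/outside flag.
#' @slot simCorrelations nSim x nPairs matrix of simulated correlations.
#' @slot frequencies per-item observed and mean simulated category frequencies.
#' @slot nSim number of simulations.
#' @export
setClass("PPCResult",
  representation(pairs = "data.frame", simCorrelations = "matrix",
                 frequencies = "list", nSim = "integer"))

setMethod("show", "PPCResult", function(object) {
  cat(sprintf("PPCResult: %d item pairs, %d simulations, %d pairs outside the 95%% band\n",
              nrow(object@pairs), object@nSim, sum(!object@pairs$inside)))
})

#' @rdname correlationPPC
#' @param object a `PPCResult`.
#' @export
setGeneric("ppcPairs", function(object) standardGeneric("ppcPairs"))
#' @export
setMethod("ppcPairs", "PPCResult", function(object) object@pairs)

#' Posterior predictive check of item-pair correlations
#'
#' Simulates `nSim` replicate datasets under the model, computes the item-pair
#' correlation matrix of each, and compares the observed correlations against
#' the equal-tailed central 95% interval of the simulated ones. Close
#' agreement (observed inside the band for about 95% of pairs) indicates good
#' predictive performance of the dependence structure.
#'
#' @param observed observed response matrix.
#' @param model a [LatentModel-class].
#' @param nSim number of simulations.
#' @param seed integer seed.
#' @param level central interval probability.
#' @return A [PPCResult-class] object.
#' @export
correlationPPC <- function(observed, model, nSim = 500L, seed = 1L,
                           level = 0.95) {
  observed <- as.matrix(as.data.frame(observed)[, itemNames(model), drop = FALSE])
  N <- nrow(observed)
  obsCor <- itemPairCorrelations(observed)
  sims <- simulateDatasets(model, nSim = nSim, N = N, seed = seed)
  J <- ncol(observed)
  ut <- which(upper.tri(obsCor), arr.ind = TRUE)
  pairNames <- paste(colnames(observed)[ut[, 1L]],
                     colnames(observed)[ut[, 2L]], sep = ":")
  simCor <- t(vapply(sims, function(d) itemPairCorrelations(d)[upper.tri(obsCor)],
                     numeric(nrow(ut))))
  colnames(simCor) <- pairNames
  alpha <- (1 - level) / 2
  ci <- apply(simCor, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  obs <- obsCor[upper.tri(obsCor)]
  pairs <- data.frame(item1 = colnames(observed)[ut[, 1L]],
                      item2 = colnames(observed)[ut[, 2L]],
                      observed = obs, lower = ci[1L, ], upper = ci[2L, ],
                      inside = obs >= ci[1L, ] & obs <= ci[2L, ],
                      stringsAsFactors = FALSE)
  new("PPCResult", pairs = pairs, simCorrelations = simCor,
      frequencies = mirrorFrequencies(observed, sims, itemsOf(model)),
      nSim = as.integer(nSim))
}

itemsOf <- function(model) modelItems(model)

#' Observed versus simulated category frequencies (mirror comparison)
#'
#' Per-item observed category proportions next to the mean simulated
#' proportions, the numerical content of a back-to-back mirror plot.
#'
#' @param observed observed response matrix.
#' @param simulated list of simulated response matrices.
#' @param items optional list of [ItemParameters-class] fixing the category
#'   counts; inferred from the pooled data when `NULL`.
#' @return Named list, one data.frame per item with columns `category`,
#'   `observed`, `simulated` (each frequency column sums to one).
#' @export
mirrorFrequencies <- function(observed, simulated, items = NULL) {
  observed <- as.matrix(observed)
  out <- list()
  for (j in seq_len(ncol(observed))) {
    nm <- colnames(observed)[j]
    if (is.null(nm)) nm <- paste0("item", j)
    K <- if (!is.null(items)) nCategories(items[[j]])
         else max(c(observed[, j], vapply(simulated, function(s) max(s[, j], na.rm = TRUE), 0L)),
                  na.rm = TRUE) + 1L
    lev <- 0:(K - 1L)
    obsP <- as.numeric(table(factor(observed[, j], levels = lev)))
    obsP <- obsP / sum(obsP)
    simP <- rowMeans(vapply(simulated, function(s) {
      p <- as.numeric(table(factor(s[, j], levels = lev)))
      p / sum(p)
    }, numeric(K)))
    out[[nm]] <- data.frame(category = lev, observed = obsP, simulated = simP)
  }
  out
}

#' Mirror plot of observed versus simulated frequencies
#'
#' Back-to-back bars: observed category proportions upward, mean simulated
#' proportions downward, one panel per item.
#'
#' @param frequencies list from [mirrorFrequencies()] (or the `frequencies`
#'   slot of a [PPCResult-class]).
#' @param items subset of item names to plot.
#' @return A ggplot object.
#' @export
plotMirror <- function(frequencies, items = names(frequencies)) {
  dfs <- lapply(items, function(nm) {
    f <- frequencies[[nm]]
    rbind(data.frame(item = nm, category = f$category, source = "observed",
                     proportion = f$observed),
          data.frame(item = nm, category = f$category, source = "simulated",
                     proportion = -f$simulated))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(category),
                                   y = proportion, fill = source)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~item, scales = "free_x") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "score category", y = "proportion (simulated mirrored)") +
    ggplot2::theme_minimal()
}
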