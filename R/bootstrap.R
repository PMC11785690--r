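# Nonparametric bootstrap for the imprecision of the covariate-latent
# correlations (and any derived quantity of the joint model). Subjects are
# resampled with replacement and the stage-2 joint model is refit per
# replicate; the stage-1 item response model is held fixed (conditional
# bootstrap: item-parameter uncertainty is not propagated, understating the
# total uncertainty somewhat).

#' Bootstrap result
#'
#' @slot nBoot number of replicates attempted.
#' @slot estimates data.frame with `quantity`, `point`, `lower`, `upper`,
#'   `violation` (point outside its own interval, flagged not hidden).
#' @slot replicates matrix of per-replicate quantities (replicates x quantities).
#' @slot seed master seed.
#' @slot failures indices of failed replicates (logged and skipped).
#' @slot log per-replicate messages for failed replicates.
#' @export
setClass("BootstrapResult",
  representation(nBoot = "integer", estimates = "data.frame",
                 replicates = "matrix", seed = "integer",
                 failures = "integer", log = "character"))

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d replicates (%d failed), %d quantities\n",
              object@nBoot, length(object@failures), nrow(object@estimates)))
  print(utils::head(object@estimates, 8L))
})

#' @rdname bootstrapJoint
#' @param object a `BootstrapResult`.
#' @export
setGeneric("bootstrapEstimates", function(object) standardGeneric("bootstrapEstimates"))
#' @export
setMethod("bootstrapEstimates", "BootstrapResult", function(object) object@estimates)

#' Nonparametric bootstrap of the joint latent-covariate model
#'
#' Resamples subjects with replacement (`n = N` per replicate), refits the
#' stage-2 joint model on each replicate (posterior draws of the resampled
#' subjects are reused; the item response model is fixed), and summarizes the
#' covariate-latent correlations by 2.5/97.5 percentile intervals around the
#' full-data point estimate. Replicate sub-seeds derive from the master seed
#' by a counter scheme, so results are deterministic given `seed`.
#'
#' @param scores a [SubjectScores-class].
#' @param covariates covariate data frame aligned with the scores.
#' @param specs a [CovariateSpecs-class]; built from the data when `NULL`.
#' @param nBoot number of bootstrap replicates (must be at least 2).
#' @param seed master seed.
#' @param nImputations posterior draws used per replicate fit.
#' @param maxFailFraction error out when more than this fraction of
#'   replicates fails.
#' @return A [BootstrapResult-class] object.
#' @export
bootstrapJoint <- function(scores, covariates, specs = NULL, nBoot = 200L,
                           seed = 1L, nImputations = 5L,
                           maxFailFraction = 0.1) {
  stopifnot(is(scores, "SubjectScores"), nBoot >= 2L)
  covariates <- as.data.frame(covariates)
  N <- length(subjectIds(scores))
  if (is.null(specs)) specs <- buildCovariateSpecs(covariates)

  full <- fitJointModel(scores, covariates, specs, nImputations = nImputations)
  pointMat <- covariateLatentCorrelations(full)
  qNames <- as.vector(outer(rownames(pointMat), colnames(pointMat),
                            function(a, b) paste0(a, ":", b)))
  point <- as.vector(pointMat)

  reps <- matrix(NA_real_, nBoot, length(point),
                 dimnames = list(NULL, qNames))
  failures <- integer(0)
  flog <- character(0)
  for (b in seq_len(nBoot)) {
    res <- tryCatch({
      idx <- withSeed(subSeed(seed, b), sample.int(N, N, replace = TRUE))
      sub <- new("SubjectScores",
                 ids = as.character(seq_len(N)),
                 mean = scoreMeans(scores)[idx, , drop = FALSE],
                 cov = scoreCovariances(scores)[, , idx, drop = FALSE],
                 draws = scoreDraws(scores)[idx, , , drop = FALSE],
                 nDraws = scores@nDraws, prior = scores@prior)
      jm <- fitJointModel(sub, covariates[idx, , drop = FALSE], specs,
                          nImputations = nImputations)
      as.vector(covariateLatentCorrelations(jm))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, b)
      flog <- c(flog, sprintf("replicate %d: %s", b, conditionMessage(res)))
    } else reps[b, ] <- res
  }
  if (length(failures) > maxFailFraction * nBoot)
    stop(sprintf("%d of %d bootstrap replicates failed", length(failures), nBoot))
  ok <- reps[setdiff(seq_len(nBoot), failures), , drop = FALSE]
  ci <- apply(ok, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  est <- data.frame(quantity = qNames, point = point,
                    lower = ci[1L, ], upper = ci[2L, ],
                    violation = point < ci[1L, ] | point > ci[2L, ],
                    stringsAsFactors = FALSE)
  new("BootstrapResult", nBoot = as.integer(nBoot), estimates = est,
      replicates = ok, seed = as.integer(seed),
      failures = failures, log = flog)
}
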