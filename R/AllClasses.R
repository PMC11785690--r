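#' @import methods
NULL

# ---- ItemParameters ---------------------------------------------------------

#' Item parameters for one histological score
#'
#' Holds the response model for a single biopsy item: a two-parameter logistic
#' model for binary lesions (absent/present) or a graded-response model for
#' ordered scores (e.g. steatosis 0-3, fibrosis 0-4). The linear predictor for
#' cumulative category k is `a . theta + d_k` on the logit scale, where `theta`
#' is the latent disease-facet vector, `a` the slope (discrimination) vector
#' with zeros outside the item's loading pattern, and `d` strictly decreasing
#' intercepts.
#'
#' @slot name single item identifier.
#' @slot kind `"binary"` or `"ordered"`.
#' @slot nCategories number of response categories (binary items have 2).
#' @slot loadingPattern integer indices of the latent variables the item loads on.
#' @slot slopes numeric slope vector, one entry per latent variable; entries
#'   outside `loadingPattern` are fixed at zero.
#' @slot intercepts numeric vector of `nCategories - 1` strictly decreasing
#'   cumulative-logit intercepts.
#' @export
setClass("ItemParameters",
  representation(name = "character", kind = "character",
                 nCategories = "integer", loadingPattern = "integer",
                 slopes = "numeric", intercepts = "numeric"))

setValidity("ItemParameters", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!object@kind %in% c("binary", "ordered"))
    msg <- c(msg, "'kind' must be \"binary\" or \"ordered\"")
  if (object@nCategories < 2L)
    msg <- c(msg, "'nCategories' must be >= 2")
  if (object@kind == "binary" && object@nCategories != 2L)
    msg <- c(msg, "binary items must have exactly 2 categories")
  if (length(object@intercepts) != object@nCategories - 1L)
    msg <- c(msg, "need nCategories - 1 intercepts")
  if (length(object@intercepts) > 1L && any(diff(object@intercepts) >= 0))
    msg <- c(msg, sprintf("intercepts of item '%s' must be strictly decreasing",
                          object@name))
  if (!all(is.finite(object@slopes)))
    msg <- c(msg, "slopes must be finite")
  if (length(object@loadingPattern) == 0L)
    msg <- c(msg, "loading pattern must be nonempty")
  if (any(object@loadingPattern < 1L) ||
      any(object@loadingPattern > length(object@slopes)))
    msg <- c(msg, "loading pattern indices out of range")
  off <- setdiff(seq_along(object@slopes), object@loadingPattern)
  if (length(off) && any(object@slopes[off] != 0))
    msg <- c(msg, sprintf(
      "item '%s': nonzero slope outside its loading pattern", object@name))
  if (length(msg)) msg else TRUE
})

#' Construct item parameters
#'
#' @param name item identifier.
#' @param kind `"binary"` or `"ordered"`.
#' @param nCategories number of response categories.
#' @param loadingPattern integer vector of latent-variable indices.
#' @param slopes numeric vector, one slope per latent variable (zero outside
#'   the loading pattern).
#' @param intercepts strictly decreasing cumulative-logit intercepts,
#'   length `nCategories - 1`.
#' @return An [ItemParameters-class] object.
#' @examples
#' itemParameters("fibrosis", "ordered", 5L, 4L,
#'                slopes = c(0, 0, 0, 1.8, 0),
#'                intercepts = c(1.5, 0, -1.5, -3))
#' @export
itemParameters <- function(name, kind, nCategories, loadingPattern, slopes,
                           intercepts) {
  new("ItemParameters", name = as.character(name), kind = as.character(kind),
      nCategories = as.integer(nCategories),
      loadingPattern = sort(unique(as.integer(loadingPattern))),
      slopes = as.numeric(slopes), intercepts = as.numeric(intercepts))
}

#' @describeIn itemParameters item identifier accessor
#' @param object,x an `ItemParameters` object.
#' @export
setGeneric("itemName", function(object) standardGeneric("itemName"))
#' @export
setMethod("itemName", "ItemParameters", function(object) object@name)

#' @rdname itemParameters
#' @export
setGeneric("itemKind", function(object) standardGeneric("itemKind"))
#' @export
setMethod("itemKind", "ItemParameters", function(object) object@kind)

#' @rdname itemParameters
#' @export
setGeneric("nCategories", function(object) standardGeneric("nCategories"))
#' @export
setMethod("nCategories", "ItemParameters", function(object) object@nCategories)

#' @rdname itemParameters
#' @export
setGeneric("loadingPattern", function(object) standardGeneric("loadingPattern"))
#' @export
setMethod("loadingPattern", "ItemParameters", function(object) object@loadingPattern)

#' @rdname itemParameters
#' @export
setGeneric("slopes", function(object) standardGeneric("slopes"))
#' @export
setMethod("slopes", "ItemParameters", function(object) object@slopes)

#' @rdname itemParameters
#' @export
setGeneric("intercepts", function(object) standardGeneric("intercepts"))
#' @export
setMethod("intercepts", "ItemParameters", function(object) object@intercepts)

setMethod("show", "ItemParameters", function(object) {
  cat(sprintf("ItemParameters '%s' (%s, %d categories)\n", object@name,
              object@kind, object@nCategories))
  cat("  loads on LV:", paste(object@loadingPattern, collapse = ", "), "\n")
  cat("  slopes:    ", paste(format(object@slopes, digits = 3), collapse = " "), "\n")
  cat("  intercepts:", paste(format(object@intercepts, digits = 3), collapse = " "), "\n")
})

# ---- LoadingMap -------------------------------------------------------------

#' Loading map of items onto latent disease facets
#'
#' Records which latent variables each of the 13 histological items loads on.
#' In the default structure the four cardinal NAFLD features (steatosis,
#' lobular inflammation, hepatocellular ballooning, fibrosis) each load on one
#' exclusive latent variable, while the nine residual lesions load on all five.
#'
#' @slot items named list; each element an integer vector of latent-variable
#'   indices.
#' @slot nLatent number of latent variables.
#' @export
setClass("LoadingMap",
  representation(items = "list", nLatent = "integer"))

setValidity("LoadingMap", function(object) {
  msg <- character()
  if (is.null(names(object@items)) || any(!nzchar(names(object@items))))
    msg <- c(msg, "items must be named")
  if (anyDuplicated(names(object@items)))
    msg <- c(msg, "duplicated item names")
  for (nm in names(object@items)) {
    p <- object@items[[nm]]
    if (length(p) == 0L)
      msg <- c(msg, sprintf("item '%s' has an empty loading pattern", nm))
    if (any(p < 1L) || any(p > object@nLatent))
      msg <- c(msg, sprintf("item '%s': latent index out of range", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("nLatent", function(object) standardGeneric("nLatent"))
#' @rdname buildDefaultLoadingMap
#' @param object a `LoadingMap` (or model) object.
#' @export
setMethod("nLatent", "LoadingMap", function(object) object@nLatent)

setMethod("show", "LoadingMap", function(object) {
  cat(sprintf("LoadingMap: %d items on %d latent variables\n",
              length(object@items), object@nLatent))
  for (nm in names(object@items))
    cat(sprintf("  %-28s LV %s\n", nm,
                paste(object@items[[nm]], collapse = ",")))
})

# ---- LatentModel / FittedModel ---------------------------------------------

#' Histological liver score model
#'
#' The combination of item parameters for all items and the correlation matrix
#' of the latent disease facets. `FittedModel` extends it with estimation
#' metadata (convergence flag, approximate standard errors, the
#' Robbins-Monro trajectory log and the fit options used).
#'
#' @slot items list of [ItemParameters-class], one per item.
#' @slot Sigma latent correlation matrix (unit diagonal, positive definite).
#' @export
setClass("LatentModel", representation(items = "list", Sigma = "matrix"))

setValidity("LatentModel", function(object) {
  msg <- character()
  if (!length(object@items)) msg <- c(msg, "no items")
  if (!all(vapply(object@items, is, TRUE, "ItemParameters")))
    msg <- c(msg, "items must be ItemParameters objects")
  nms <- vapply(object@items, itemName, "")
  if (anyDuplicated(nms)) msg <- c(msg, "duplicated item names")
  L <- nrow(object@Sigma)
  ok <- tryCatch({ validateCorrelation(object@Sigma); TRUE },
                 error = function(e) { msg <<- c(msg, conditionMessage(e)); FALSE })
  if (ok && !all(vapply(object@items, function(it) length(slopes(it)) == L, TRUE)))
    msg <- c(msg, "slope length must match the latent dimension")
  if (length(msg)) msg else TRUE
})

#' Construct a latent model
#' @param items list of [ItemParameters-class].
#' @param Sigma latent correlation matrix.
#' @return A [LatentModel-class] object.
#' @export
latentModel <- function(items, Sigma) {
  nms <- vapply(items, itemName, "")
  names(items) <- nms
  new("LatentModel", items = items, Sigma = symmetrize(as.matrix(Sigma)))
}

#' @rdname latentModel
#' @param object a `LatentModel`.
#' @export
setGeneric("modelItems", function(object) standardGeneric("modelItems"))
#' @export
setMethod("modelItems", "LatentModel", function(object) object@items)

#' @rdname latentModel
#' @export
setGeneric("latentCorrelation", function(object) standardGeneric("latentCorrelation"))
#' @export
setMethod("latentCorrelation", "LatentModel", function(object) object@Sigma)

#' @export
setMethod("nLatent", "LatentModel", function(object) nrow(object@Sigma))

#' @rdname latentModel
#' @export
setGeneric("itemNames", function(object) standardGeneric("itemNames"))
#' @export
setMethod("itemNames", "LatentModel", function(object)
  vapply(object@items, itemName, ""))

setMethod("show", "LatentModel", function(object) {
  cat(sprintf("%s: %d items, %d latent variables\n", class(object),
              length(object@items), nLatent(object)))
  cat("latent correlations (upper triangle):\n")
  S <- round(object@Sigma, 3)
  S[lower.tri(S, diag = TRUE)] <- NA
  print(S, na.print = "")
})

#' @rdname latentModel
#' @slot converged logical convergence flag.
#' @slot standardErrors named list of per-item approximate standard errors.
#' @slot trajectory data.frame log of the stochastic-approximation run.
#' @slot options list of fit options used.
#' @export
setClass("FittedModel", contains = "LatentModel",
  representation(converged = "logical", standardErrors = "list",
                 trajectory = "data.frame", options = "list"))

#' @rdname latentModel
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @export
setMethod("converged", "FittedModel", function(object) object@converged)

#' @rdname latentModel
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))
#' @export
setMethod("standardErrors", "FittedModel", function(object) object@standardErrors)

#' @rdname latentModel
#' @export
setGeneric("trajectory", function(object) standardGeneric("trajectory"))
#' @export
setMethod("trajectory", "FittedModel", function(object) object@trajectory)

setMethod("show", "FittedModel", function(object) {
  callNextMethod()
  cat(sprintf("converged: %s after %d cycles\n", object@converged,
              nrow(object@trajectory)))
})

# ---- SubjectScores ----------------------------------------------------------

#' Per-subject latent disease scores
#'
#' Expected a posteriori (EAP) summaries of the latent vector given a
#' subject's item responses: posterior mean, posterior covariance and retained
#' posterior draws (used as multiple imputations by the covariate stage).
#'
#' @slot ids subject identifiers.
#' @slot mean N x L matrix of posterior means.
#' @slot cov L x L x N array of posterior covariances.
#' @slot draws N x L x M array of retained posterior draws.
#' @slot nDraws number of posterior draws the summaries are based on.
#' @slot prior the latent correlation matrix the scores were computed under.
#' @export
setClass("SubjectScores",
  representation(ids = "character", mean = "matrix", cov = "array",
                 draws = "array", nDraws = "integer", prior = "matrix"))

setValidity("SubjectScores", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (nrow(object@mean) != n) msg <- c(msg, "mean rows must match ids")
  if (dim(object@cov)[3] != n) msg <- c(msg, "cov slices must match ids")
  if (nrow(object@prior) != ncol(object@mean))
    msg <- c(msg, "prior dimension must match the latent dimension")
  for (i in seq_len(min(n, 5L))) {
    ev <- eigen(symmetrize(object@cov[, , i]), symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev < -1e-8)) { msg <- c(msg, "posterior covariance not PSD"); break }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname eapScores
#' @param object a `SubjectScores` object.
#' @export
setGeneric("scoreMeans", function(object) standardGeneric("scoreMeans"))
#' @export
setMethod("scoreMeans", "SubjectScores", function(object) object@mean)

#' @rdname eapScores
#' @export
setGeneric("scoreCovariances", function(object) standardGeneric("scoreCovariances"))
#' @export
setMethod("scoreCovariances", "SubjectScores", function(object) object@cov)

#' @rdname eapScores
#' @export
setGeneric("scoreDraws", function(object) standardGeneric("scoreDraws"))
#' @export
setMethod("scoreDraws", "SubjectScores", function(object) object@draws)

#' @rdname eapScores
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @export
setMethod("subjectIds", "SubjectScores", function(object) object@ids)

setMethod("show", "SubjectScores", function(object) {
  cat(sprintf("SubjectScores: %d subjects, %d latent variables, %d draws\n",
              length(object@ids), ncol(object@mean), object@nDraws))
})
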