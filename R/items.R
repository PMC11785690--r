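# Item response functions: two-parameter logistic (binary lesions) and
# graded-response (ordered scores) models over a multidimensional latent
# disease vector.

asThetaMatrix <- function(theta, L) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1L)
  theta <- as.matrix(theta)
  if (ncol(theta) != L)
    stop(sprintf("theta must have %d columns", L))
  if (!all(is.finite(theta))) stop("theta must be finite")
  theta
}

#' Cumulative category probabilities of a graded-response item
#'
#' Returns `P(Y >= k | theta) = plogis(a . theta + d_k)` for
#' `k = 1, ..., K - 1`. For a binary item this is the 2PL success probability.
#'
#' @param item an [ItemParameters-class] object.
#' @param theta latent vector (length L) or an N x L matrix.
#' @return A numeric vector of length `K - 1`, or an `N x (K - 1)` matrix when
#'   `theta` is a matrix. Entries are strictly decreasing in `k` (enforced by
#'   the decreasing intercepts).
#' @examples
#' it <- itemParameters("steatosis", "ordered", 3L, 1L, c(1, 0, 0, 0, 0), c(1, -1))
#' grmCumulative(it, rep(0, 5))
#' @export
grmCumulative <- function(item, theta) {
  stopifnot(is(item, "ItemParameters"))
  theta <- asThetaMatrix(theta, length(slopes(item)))
  eta <- drop(theta %*% slopes(item))
  p <- stats::plogis(outer(eta, intercepts(item), "+"))
  if (length(eta) == 1L) drop(p) else p
}

#' Category probabilities of an item
#'
#' Adjacent differences of the cumulative probabilities; for a binary item this
#' is `(1 - p, p)` with `p` the 2PL success probability.
#'
#' @inheritParams grmCumulative
#' @return Numeric vector of length `K` (or `N x K` matrix) of probabilities
#'   summing to one.
#' @export
categoryProbs <- function(item, theta) {
  theta <- asThetaMatrix(theta, length(slopes(item)))
  eta <- drop(theta %*% slopes(item))
  cum <- stats::plogis(outer(eta, intercepts(item), "+"))
  p <- cbind(1, cum) - cbind(cum, 0)
  dimnames(p) <- NULL
  if (length(eta) == 1L) drop(p) else p
}

#' Expected item score
#'
#' `E(Y | theta) = sum_k k P(Y = k | theta)`; equals the sum of the cumulative
#' probabilities. Monotone nondecreasing in every latent component with a
#' nonnegative slope.
#'
#' @inheritParams grmCumulative
#' @return Scalar (or length-N vector) in `[0, K - 1]`.
#' @export
expectedItemScore <- function(item, theta) {
  cum <- grmCumulative(item, theta)
  if (is.matrix(cum)) rowSums(cum) else sum(cum)
}

#' Simulate item responses
#'
#' Draws integer categories (0-based) from the item's category distribution at
#' the given latent values. Reproducible given `seed`.
#'
#' @inheritParams grmCumulative
#' @param seed optional integer seed.
#' @return Integer vector of categories in `0:(K - 1)`, one per row of `theta`.
#' @export
simulateResponse <- function(item, theta, seed = NULL) {
  theta <- asThetaMatrix(theta, length(slopes(item)))
  withSeed(seed, {
    cum <- grmCumulative(item, theta)
    if (!is.matrix(cum)) cum <- matrix(cum, nrow = nrow(theta))
    u <- stats::runif(nrow(theta))
    # category = number of cumulative thresholds exceeded
    as.integer(rowSums(u < cum))
  })
}

#' Log-likelihood of a subject's responses
#'
#' Sum over non-missing items of the log category probability at the observed
#' category; missing responses contribute zero (missing-at-random skip).
#'
#' @param items list of [ItemParameters-class] objects.
#' @param responses integer vector (one subject) or N x J matrix of 0-based
#'   categories, `NA` allowed; columns ordered as `items`.
#' @param theta latent vector or N x L matrix.
#' @return Numeric log-likelihood, one value per subject.
#' @export
subjectLoglik <- function(items, responses, theta) {
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1L)
  responses <- as.matrix(responses)
  L <- length(slopes(items[[1L]]))
  theta <- asThetaMatrix(theta, L)
  if (nrow(theta) != nrow(responses))
    stop("responses and theta must have matching rows")
  ll <- numeric(nrow(responses))
  for (j in seq_along(items)) {
    y <- responses[, j]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    if (any(y[obs] < 0 | y[obs] > nCategories(items[[j]]) - 1L))
      stop(sprintf("responses for item '%s' outside its category range",
                   itemName(items[[j]])))
    p <- categoryProbs(items[[j]], theta[obs, , drop = FALSE])
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    ll[obs] <- ll[obs] + log(pmax(p[cbind(seq_along(obs), y[obs] + 1L)], 1e-300))
  }
  ll
}

# ---- JSON serialization -----------------------------------------------------

#' Serialize a latent model to JSON
#'
#' The document holds a list of items with fixed field names `name`, `kind`,
#' `n_categories`, `loading_pattern`, `slopes`, `intercepts`, plus the latent
#' correlation matrix under `sigma`.
#'
#' @param model a [LatentModel-class] (or fitted model).
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
modelToJson <- function(model, path = NULL) {
  stopifnot(is(model, "LatentModel"))
  doc <- list(
    items = lapply(unname(modelItems(model)), function(it) list(
      name = itemName(it), kind = itemKind(it),
      n_categories = nCategories(it), loading_pattern = loadingPattern(it),
      slopes = slopes(it), intercepts = intercepts(it))),
    sigma = latentCorrelation(model))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' Deserialize a latent model from JSON
#'
#' @param json a JSON string or path to a JSON file written by [modelToJson()].
#' @return A [LatentModel-class] object.
#' @export
modelFromJson <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  items <- lapply(doc$items, function(it)
    itemParameters(it$name, it$kind, it$n_categories, it$loading_pattern,
                   it$slopes, it$intercepts))
  sigma <- doc$sigma
  if (is.list(sigma)) sigma <- do.call(rbind, lapply(sigma, unlist))
  latentModel(items, sigma)
}
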