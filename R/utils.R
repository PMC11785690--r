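# Internal numerical and RNG helpers shared across modules.

#' Run an expression under a temporary RNG seed
#'
#' Sets the seed if non-NULL, restores the caller's RNG state on exit, so
#' seeded package functions do not disturb the user's random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a replicate sub-seed from a master seed by a counter scheme
#' @noRd
subSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(counter)) %% 2147483399) + 1L
}

#' Draw from a multivariate normal via Cholesky
#'
#' Accepts a pre-generated standard-normal matrix `z` so callers can use
#' common random numbers across conditioning values.
#' @noRd
rmvn <- function(n, mean, sigma, z = NULL) {
  p <- length(mean)
  if (is.null(z)) z <- matrix(stats::rnorm(n * p), n, p)
  R <- chol(symmetrize(sigma) + diag(1e-12, p))
  sweep(z %*% R, 2L, mean, "+")
}

#' Multivariate normal log-density with precomputed Cholesky
#' @noRd
dmvnLog <- function(x, sigma, cholSigma = chol(sigma)) {
  if (is.vector(x)) x <- matrix(x, 1L)
  p <- ncol(x)
  z <- backsolve(cholSigma, t(x), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(cholSigma))) - 0.5 * p * log(2 * pi)
}

#' @noRd
symmetrize <- function(m) (m + t(m)) / 2

#' Project a symmetric matrix to the nearest correlation-like PD matrix
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal.
#' @noRd
nearestPDCorr <- function(m, minEig = 1e-8) {
  m <- symmetrize(m)
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values > minEig) && all(abs(diag(m) - 1) < 1e-12)) return(m)
  v <- pmax(e$values, minEig)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  dimnames(m2) <- dimnames(m)
  symmetrize(m2)
}

#' Sample moment skewness (g1)
#' @noRd
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' @noRd
isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
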