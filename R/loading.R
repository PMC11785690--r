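# Latent structure: the 13-item loading map, validation of the latent
# correlation matrix and its unconstrained (Cholesky) reparameterization.

#' The 13 histological items
#'
#' Five ordered scores (steatosis 0-3, lobular inflammation 0-3,
#' hepatocellular ballooning 0-2, portal chronic inflammation 0-2,
#' fibrosis 0-4 after collapsing sub-stages 1a/1b/1c) and eight binary
#' lesions. The qualitative lesion-location feature of the scoring system is
#' not an item.
#'
#' @return Data frame with columns `name`, `kind`, `nCategories`, `cardinal`.
#' @export
itemCatalog <- function() {
  data.frame(
    name = c("steatosis", "lobular_inflammation", "ballooning",
             "portal_inflammation", "fibrosis",
             "microvesicular_steatosis", "microgranulomas",
             "large_lipogranulomas", "acidophil_bodies",
             "pigmented_macrophages", "megamitochondria",
             "mallory_hyaline", "glycogen_nuclei"),
    kind = c(rep("ordered", 5L), rep("binary", 8L)),
    nCategories = c(4L, 4L, 3L, 3L, 5L, rep(2L, 8L)),
    cardinal = c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 8L)),
    stringsAsFactors = FALSE)
}

cardinalItems <- function() c("steatosis", "lobular_inflammation",
                              "ballooning", "fibrosis")

#' Default loading map of the histological liver score model
#'
#' Five latent disease facets: the four cardinal NAFLD features each load
#' exclusively on one of LV1-LV4 (steatosis, lobular inflammation,
#' hepatocellular ballooning, fibrosis in that order), while the nine residual
#' histological features load on all five latent variables. LV5 carries only
#' residual features.
#'
#' @return A [LoadingMap-class] with 5 latent variables.
#' @export
buildDefaultLoadingMap <- function() {
  cat13 <- itemCatalog()
  items <- list()
  card <- cardinalItems()
  for (i in seq_len(nrow(cat13))) {
    nm <- cat13$name[i]
    items[[nm]] <- if (nm %in% card) match(nm, card) else 1:5
  }
  new("LoadingMap", items = items, nLatent = 5L)
}

#' Exploratory loading map
#'
#' Every item loads on every latent variable (free estimation of all
#' item-facet associations, as used to guide the confirmatory structure). The
#' exploratory model is identified only up to rotation; fits with it are
#' interpretable through communalities and correlations, not individual
#' loadings.
#'
#' @param nLatentVars number of latent variables.
#' @return A [LoadingMap-class].
#' @export
exploratoryLoadingMap <- function(nLatentVars = 5L) {
  cat13 <- itemCatalog()
  items <- stats::setNames(
    rep(list(seq_len(nLatentVars)), nrow(cat13)), cat13$name)
  new("LoadingMap", items = items, nLatent = as.integer(nLatentVars))
}

#' Validate a latent correlation matrix
#'
#' Checks symmetry, unit diagonal, off-diagonal magnitudes below one and
#' positive definiteness, rejecting with a named violation.
#'
#' @param Sigma candidate matrix.
#' @param tol numerical tolerance.
#' @return The validated matrix, invisibly.
#' @export
validateCorrelation <- function(Sigma, tol = 1e-8) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma)) stop("correlation matrix must be square")
  if (!all(is.finite(Sigma))) stop("correlation matrix must be finite")
  if (max(abs(Sigma - t(Sigma))) > tol) stop("correlation matrix not symmetric")
  if (max(abs(diag(Sigma) - 1)) > tol) stop("correlation matrix diagonal must be 1")
  off <- Sigma[upper.tri(Sigma)]
  if (length(off) && any(abs(off) >= 1)) stop("off-diagonal correlation >= 1 in magnitude")
  ev <- eigen(symmetrize(Sigma), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= tol)) stop("correlation matrix not positive definite")
  invisible(Sigma)
}

#' Unconstrained parameterization of a correlation matrix
#'
#' Maps a correlation matrix to a vector of unconstrained reals (and back) via
#' spherical coordinates of its Cholesky rows: each row of the Cholesky factor
#' is a unit vector parameterized by angles, so any real vector maps to a valid
#' correlation matrix. The identity maps to the zero vector.
#'
#' @param Sigma correlation matrix.
#' @return `corrToUnconstrained`: numeric vector of length `L (L - 1) / 2`.
#' @export
corrToUnconstrained <- function(Sigma) {
  validateCorrelation(Sigma)
  L <- nrow(Sigma)
  R <- t(chol(symmetrize(Sigma)))   # lower triangular, rows unit norm
  ang <- numeric(0)
  for (i in 2:L) {
    rem <- 1
    for (j in 1:(i - 1L)) {
      ct <- R[i, j] / sqrt(rem)
      ct <- max(-1, min(1, ct))
      u <- (acos(ct) / pi - 0.001) / 0.998   # inverse of the clamped angle map
      u <- min(max(u, 1e-12), 1 - 1e-12)
      ang <- c(ang, stats::qlogis(u))
      rem <- rem * sin(acos(ct))^2
      if (rem < 1e-300) rem <- 1e-300
    }
  }
  ang
}

#' @rdname corrToUnconstrained
#' @param v unconstrained vector of length `L (L - 1) / 2`.
#' @param L matrix dimension.
#' @return `unconstrainedToCorr`: an `L x L` correlation matrix.
#' @export
unconstrainedToCorr <- function(v, L) {
  stopifnot(length(v) == L * (L - 1) / 2)
  R <- matrix(0, L, L)
  R[1, 1] <- 1
  k <- 0L
  for (i in 2:L) {
    rem <- 1
    for (j in 1:(i - 1L)) {
      k <- k + 1L
      # angle clamped inside (0, pi) so the Cholesky stays full rank
      phi <- pi * (0.001 + 0.998 * stats::plogis(v[k]))
      R[i, j] <- sqrt(rem) * cos(phi)
      rem <- rem * sin(phi)^2
    }
    R[i, i] <- sqrt(max(rem, 0))
  }
  S <- tcrossprod(R)
  diag(S) <- 1
  symmetrize(S)
}
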