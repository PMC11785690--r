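# Joint modelling of the latent disease facets and the noninvasive
# covariates: the covariates enter a joint multivariate-normal model with the
# latent vector (binary/categorical covariates as 0/1 indicators, skewed
# positive continuous covariates on the log scale), missing covariate cells
# are integrated out by EM, and covariate impact is read off the estimated
# correlation matrix. Posterior draws of the latent vector serve as multiple
# imputations; the latent-covariate cross-covariance is corrected for
# posterior shrinkage (see the vignette).

#' Covariate specifications
#'
#' Classification of each covariate column: kind (continuous, binary,
#' categorical), transform (none or log), reference level for categorical
#' covariates, and units.
#'
#' @slot table data.frame with columns `name`, `kind`, `transform`,
#'   `reference`, `units`.
#' @slot levels named list of level sets for binary/categorical covariates.
#' @export
setClass("CovariateSpecs", representation(table = "data.frame", levels = "list"))

setValidity("CovariateSpecs", function(object) {
  msg <- character()
  need <- c("name", "kind", "transform", "reference", "units")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "spec table must have columns name/kind/transform/reference/units")
  else {
    bad <- !object@table$kind %in% c("continuous", "binary", "categorical")
    if (any(bad)) msg <- c(msg, "kind must be continuous/binary/categorical")
    if (any(!object@table$transform %in% c("none", "log")))
      msg <- c(msg, "transform must be none or log")
    if (any(object@table$transform == "log" &
            object@table$kind != "continuous"))
      msg <- c(msg, "log transform only applies to continuous covariates")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname buildCovariateSpecs
#' @param object a `CovariateSpecs` object.
#' @export
setGeneric("specTable", function(object) standardGeneric("specTable"))
#' @export
setMethod("specTable", "CovariateSpecs", function(object) object@table)

setMethod("show", "CovariateSpecs", function(object) {
  tab <- table(object@table$kind)
  cat(sprintf("CovariateSpecs: %d covariates (%s)\n", nrow(object@table),
              paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")))
})

#' Classify covariate columns
#'
#' Builds [CovariateSpecs-class] from a covariate table: factors/characters
#' with two levels become binary, with more levels categorical (indicator per
#' non-reference level; the reference is the most frequent level); numeric 0/1
#' columns become binary; remaining numeric columns are continuous and get a
#' log transform when strictly positive with sample skewness above 1.
#' Percentiles are always reported on the original scale.
#'
#' @param covariates data frame of per-subject covariate values (`NA` allowed).
#' @param overrides named list of per-covariate overrides, each a list with
#'   any of `kind`, `transform`, `reference`, `units`.
#' @param skewnessThreshold skewness above which a positive continuous
#'   covariate is log transformed.
#' @return A [CovariateSpecs-class] object.
#' @export
buildCovariateSpecs <- function(covariates, overrides = list(),
                                skewnessThreshold = 1) {
  covariates <- as.data.frame(covariates)
  nms <- names(covariates)
  rows <- list()
  lvls <- list()
  for (nm in nms) {
    x <- covariates[[nm]]
    ov <- overrides[[nm]]
    units <- if (!is.null(ov$units)) ov$units else ""
    if (is.logical(x)) x <- as.integer(x)
    if (is.factor(x) || is.character(x)) {
      lv <- sort(unique(as.character(x[!is.na(x)])))
      freq <- table(factor(as.character(x), levels = lv))
      ref <- if (!is.null(ov$reference)) ov$reference
             else names(freq)[which.max(freq)]
      kind <- if (!is.null(ov$kind)) ov$kind
              else if (length(lv) <= 2L) "binary" else "categorical"
      rows[[nm]] <- data.frame(name = nm, kind = kind, transform = "none",
                               reference = ref, units = units,
                               stringsAsFactors = FALSE)
      lvls[[nm]] <- lv
    } else {
      ux <- unique(x[!is.na(x)])
      if (!is.null(ov$kind)) kind <- ov$kind
      else kind <- if (length(ux) <= 2L && all(ux %in% c(0, 1))) "binary"
                   else "continuous"
      transform <- "none"
      if (kind == "continuous") {
        transform <- if (!is.null(ov$transform)) ov$transform
        else if (all(x > 0, na.rm = TRUE) &&
                 sampleSkewness(x) > skewnessThreshold) "log" else "none"
      }
      if (kind == "binary") lvls[[nm]] <- c(0, 1)
      rows[[nm]] <- data.frame(name = nm, kind = kind, transform = transform,
                               reference = if (kind == "binary") "0" else NA_character_,
                               units = units, stringsAsFactors = FALSE)
    }
  }
  new("CovariateSpecs", table = do.call(rbind, rows), levels = lvls)
}

# analysis-scale design matrix: continuous (possibly logged) columns,
# 0/1 indicators for binary, one indicator per non-reference level for
# categorical covariates
covariateDesign <- function(covariates, specs) {
  covariates <- as.data.frame(covariates)
  tab <- specs@table
  cols <- list()
  colNames <- character()
  colList <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    x <- covariates[[nm]]
    if (is.null(x)) stop(sprintf("covariate '%s' not found", nm))
    if (all(is.na(x))) stop(sprintf("covariate '%s' is entirely missing", nm))
    if (tab$kind[i] == "continuous") {
      x <- as.numeric(x)
      if (tab$transform[i] == "log") {
        if (any(x <= 0, na.rm = TRUE))
          stop(sprintf("covariate '%s': log transform needs strictly positive values", nm))
        x <- log(x)
      }
      if (stats::sd(x, na.rm = TRUE) == 0)
        stop(sprintf("covariate '%s' is constant", nm))
      cols[[length(cols) + 1L]] <- x
      colNames <- c(colNames, nm)
      colList[[nm]] <- nm
    } else if (tab$kind[i] == "binary") {
      if (is.factor(x) || is.character(x)) {
        lv <- specs@levels[[nm]]
        x <- as.numeric(as.character(x) != tab$reference[i])
        x[is.na(covariates[[nm]])] <- NA
      } else x <- as.numeric(x)
      if (stats::sd(x, na.rm = TRUE) == 0)
        stop(sprintf("covariate '%s' is constant", nm))
      cols[[length(cols) + 1L]] <- x
      colNames <- c(colNames, nm)
      colList[[nm]] <- nm
    } else {
      lv <- specs@levels[[nm]]
      nonref <- setdiff(lv, tab$reference[i])
      nmCols <- character()
      for (l in nonref) {
        ind <- as.numeric(as.character(x) == l)
        ind[is.na(x)] <- NA
        cn <- paste0(nm, "=", l)
        cols[[length(cols) + 1L]] <- ind
        colNames <- c(colNames, cn)
        nmCols <- c(nmCols, cn)
      }
      if (!length(nmCols)) stop(sprintf("covariate '%s' has no non-reference level", nm))
      colList[[nm]] <- nmCols
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- colNames
  list(X = X, columns = colList)
}

# marginal summaries on the original scale
covariateMarginalSummaries <- function(covariates, specs) {
  tab <- specs@table
  out <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    x <- covariates[[nm]]
    if (tab$kind[i] == "continuous") {
      q <- stats::quantile(as.numeric(x), c(0.025, 0.5, 0.975), na.rm = TRUE,
                           names = FALSE)
      out[[nm]] <- list(kind = "continuous", median = q[2L], p2.5 = q[1L],
                        p97.5 = q[3L])
    } else {
      lv <- specs@levels[[nm]]
      xx <- as.character(x[!is.na(x)])
      if (tab$kind[i] == "binary" && !is.character(x) && !is.factor(x))
        lv <- c(0, 1)
      pr <- as.numeric(table(factor(xx, levels = as.character(lv))))
      pr <- pr / sum(pr)
      out[[nm]] <- list(kind = tab$kind[i], levels = as.character(lv),
                        probs = pr, reference = tab$reference[i])
    }
  }
  out
}

#' EM estimation of a multivariate normal with missing cells
#'
#' Maximum likelihood mean and covariance of a multivariate normal from data
#' with values missing at random, by expectation-maximization. The E-step uses
#' the precision matrix so each row only requires a solve of the size of its
#' missing block.
#'
#' @param X numeric matrix with `NA` cells.
#' @param maxIter,tol iteration cap and convergence tolerance on the largest
#'   parameter change (standardized scale).
#' @param ridge relative ridge added to the covariance diagonal each
#'   iteration, stabilizing the solve under (near-)collinear columns.
#' @return List with `mean`, `cov` (MLE, denominator `n`), `iterations`,
#'   `converged`.
#' @export
mvnEM <- function(X, maxIter = 200L, tol = 1e-6, ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0L)) stop("column entirely missing")
  # standardize internally: EM conditioning is scale sensitive and covariate
  # scales span many orders of magnitude; results are mapped back at the end
  ctr <- colMeans(X, na.rm = TRUE)
  scl <- apply(X, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(scl) | scl == 0)) stop("constant or degenerate column")
  X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  mu <- colMeans(X, na.rm = TRUE)
  S0 <- stats::cov(X, use = "pairwise.complete.obs")
  S0[!is.finite(S0)] <- 0
  # shrink the pairwise-complete start toward the diagonal so it is PD
  S <- symmetrize(0.8 * S0 + 0.2 * diag(diag(S0)))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-4) S <- S + diag(1e-4 - min(ev), p)
  pat <- do.call(paste0, as.data.frame(obs * 1L))
  patIdx <- split(seq_len(n), pat)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    Lam <- solve(S)
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (rows in patIdx) {
      o <- obs[rows[1L], ]
      m <- which(!o); oI <- which(o)
      Xr <- X[rows, , drop = FALSE]
      if (!length(m)) {
        T1 <- T1 + colSums(Xr)
        T2 <- T2 + crossprod(Xr)
        next
      }
      Cmm <- solve(Lam[m, m, drop = FALSE])
      resid <- sweep(Xr[, oI, drop = FALSE], 2L, mu[oI])
      Xhat <- Xr
      Xhat[, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE) -
        resid %*% t(Cmm %*% Lam[m, oI, drop = FALSE])
      T1 <- T1 + colSums(Xhat)
      T2 <- T2 + crossprod(Xhat)
      T2[m, m] <- T2[m, m] + length(rows) * Cmm
    }
    muNew <- T1 / n
    SNew <- symmetrize(T2 / n - tcrossprod(muNew))
    # relative ridge keeps the solve stable under exact collinearity
    # (e.g. a log ratio alongside its logged components)
    SNew <- SNew + diag(ridge * pmax(diag(SNew), 1e-12))
    delta <- max(max(abs(muNew - mu)), max(abs(SNew - S)))
    mu <- muNew
    S <- SNew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  mu <- mu * scl + ctr
  S <- S * tcrossprod(scl)
  list(mean = mu, cov = symmetrize(S), iterations = iter,
       converged = converged)
}

#' Joint latent-covariate model
#'
#' Joint mean and covariance of the latent disease vector and the transformed
#' covariates, with the derived correlation matrix and per-covariate marginal
#' summaries.
#'
#' @slot mean named joint mean vector.
#' @slot cov joint covariance matrix.
#' @slot corr joint correlation matrix.
#' @slot latentNames names of the latent components.
#' @slot columns named list mapping covariates to their analysis columns.
#' @slot marginals per-covariate marginal summaries (original scale).
#' @slot specs the [CovariateSpecs-class] used.
#' @slot nImputations,nSubjects integers.
#' @export
setClass("JointModel",
  representation(mean = "numeric", cov = "matrix", corr = "matrix",
                 latentNames = "character", columns = "list",
                 marginals = "list", specs = "CovariateSpecs",
                 nImputations = "integer", nSubjects = "integer"))

setValidity("JointModel", function(object) {
  msg <- character()
  ev <- eigen(symmetrize(object@cov), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) msg <- c(msg, "joint covariance not PSD")
  if (any(abs(object@corr) > 1 + 1e-8)) msg <- c(msg, "correlations outside [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname fitJointModel
#' @param object a `JointModel`.
#' @export
setGeneric("jointCorrelation", function(object) standardGeneric("jointCorrelation"))
#' @export
setMethod("jointCorrelation", "JointModel", function(object) object@corr)

#' @rdname fitJointModel
#' @export
setGeneric("jointMean", function(object) standardGeneric("jointMean"))
#' @export
setMethod("jointMean", "JointModel", function(object) object@mean)

#' @rdname fitJointModel
#' @export
setGeneric("jointCovariance", function(object) standardGeneric("jointCovariance"))
#' @export
setMethod("jointCovariance", "JointModel", function(object) object@cov)

#' @rdname fitJointModel
#' @export
setGeneric("covariateLatentCorrelations",
           function(object) standardGeneric("covariateLatentCorrelations"))
#' @describeIn fitJointModel analysis-column x latent-variable correlation matrix
#' @export
setMethod("covariateLatentCorrelations", "JointModel", function(object) {
  xCols <- setdiff(colnames(object@corr), object@latentNames)
  object@corr[xCols, object@latentNames, drop = FALSE]
})

#' @rdname fitJointModel
#' @export
setGeneric("covariateMarginals", function(object) standardGeneric("covariateMarginals"))
#' @export
setMethod("covariateMarginals", "JointModel", function(object) object@marginals)

setMethod("show", "JointModel", function(object) {
  cat(sprintf("JointModel: %d latent variables, %d covariate columns, %d subjects\n",
              length(object@latentNames),
              ncol(object@corr) - length(object@latentNames), object@nSubjects))
  cr <- covariateLatentCorrelations(object)
  top <- order(apply(abs(cr), 1L, max), decreasing = TRUE)[seq_len(min(5L, nrow(cr)))]
  cat("strongest covariate-latent correlations:\n")
  print(round(cr[top, , drop = FALSE], 3))
})

#' Fit the joint latent-covariate model
#'
#' Stage-2 estimation of the joint multivariate-normal model of the latent
#' disease facets and the (transformed) covariates. The retained posterior
#' draws of the latent vectors serve as multiple imputations
#' (`nImputations` consecutive blocks of draws, each imputation the block
#' mean); pooling across imputations averages them per subject
#' (Rao-Blackwellized pooling — linear functionals of the joint MVN are
#' unchanged in expectation while the draw noise is minimized, and the
#' result is invariant to the imputation count by construction). The joint
#' mean/covariance is estimated by [mvnEM()] over missing covariate cells on
#' `[theta-bar | X]`. Because posterior summaries carry only the
#' shrunken signal `cov(EAP, x)`, the latent-covariate cross-covariance is
#' deattenuated by `Sigma W^-1` where `W` is the covariance of the posterior
#' means and `Sigma` the latent correlation implied by the scores (see the
#' vignette). The sign convention follows the orientation of the latent
#' variables: positive correlation means a high biomarker value accompanies
#' high disease activity.
#'
#' @param scores a [SubjectScores-class] from [eapScores()].
#' @param covariates data frame of per-subject covariates, rows aligned with
#'   the scored subjects (checked against rownames when present).
#' @param specs a [CovariateSpecs-class]; built from the data when `NULL`.
#' @param nImputations number of posterior draws used as imputations.
#' @param emMaxIter,emTol EM controls passed to [mvnEM()].
#' @return A [JointModel-class] object.
#' @export
fitJointModel <- function(scores, covariates, specs = NULL, nImputations = 10L,
                          emMaxIter = 200L, emTol = 1e-6) {
  stopifnot(is(scores, "SubjectScores"), isCount(nImputations))
  covariates <- as.data.frame(covariates)
  N <- length(subjectIds(scores))
  if (nrow(covariates) != N)
    stop("covariate rows do not match the number of scored subjects")
  if (!is.null(rownames(covariates)) &&
      !all(rownames(covariates) == as.character(seq_len(N))) &&
      all(subjectIds(scores) %in% rownames(covariates)))
    covariates <- covariates[subjectIds(scores), , drop = FALSE]
  if (is.null(specs)) specs <- buildCovariateSpecs(covariates)
  des <- covariateDesign(covariates, specs)
  X <- des$X
  L <- ncol(scoreMeans(scores))
  latentNames <- paste0("LV", seq_len(L))
  M <- min(nImputations, dim(scoreDraws(scores))[3L])

  # Rao-Blackwellized imputation: the retained draws are partitioned into M
  # consecutive blocks (one imputation per block, each the block mean) and
  # pooled by averaging. The pooled latent value per subject is then the
  # grand mean over all retained draws, so the estimates are invariant to the
  # imputation count by construction — the method does not depend on an
  # arbitrary M, while the draw noise entering the cross-covariances is
  # minimized. The EM runs once on [theta-bar | X].
  thetaBar <- apply(scoreDraws(scores), c(1L, 2L), mean)
  D <- cbind(thetaBar, X)
  colnames(D) <- c(latentNames, colnames(X))
  fit <- mvnEM(D, maxIter = emMaxIter, tol = emTol)
  mu <- fit$mean
  S <- fit$cov

  li <- seq_len(L)
  Vbar <- apply(scoreCovariances(scores), c(1L, 2L), mean)
  SigmaHat <- if (nrow(scores@prior) == L) stats::cov2cor(scores@prior)
    else stats::cov2cor(symmetrize(
      stats::cov(scoreMeans(scores)) * (N - 1L) / N + Vbar))
  # shrinkage correction: averaged draws carry cov(EAP, x) = W B' where
  # W = cov(EAP) and B is the regression of x on theta; the latent signal is
  # Sigma B'. W is taken model-implied (law of total variance:
  # cov(EAP) = Sigma - mean posterior covariance), which is far less noisy
  # than the empirical covariance of the posterior means.
  W <- symmetrize(SigmaHat - Vbar)
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) W <- W + diag(1e-8 - min(ev), L)
  corrFactor <- SigmaHat %*% solve(W + diag(1e-10, L))
  cross <- corrFactor %*% S[li, -li, drop = FALSE]
  S2 <- S
  S2[li, li] <- SigmaHat
  S2[li, -li] <- cross
  S2[-li, li] <- t(cross)
  S2 <- symmetrize(S2)
  # guard against indefiniteness introduced by the correction
  sdv <- sqrt(diag(S2))
  R <- S2 / tcrossprod(sdv)
  diag(R) <- 1
  R <- nearestPDCorr(R)
  S2 <- R * tcrossprod(sdv)
  mu[li] <- 0

  new("JointModel", mean = stats::setNames(mu, colnames(S2)), cov = S2,
      corr = R, latentNames = latentNames, columns = des$columns,
      marginals = covariateMarginalSummaries(covariates, specs),
      specs = specs, nImputations = as.integer(M),
      nSubjects = as.integer(N))
}

#' Conditional latent distribution given one covariate
#'
#' Closed-form multivariate-normal conditioning of the latent vector on a
#' single covariate held at a given value (continuous covariates are
#' conditioned on the transform scale; `value` is supplied on the original
#' scale) or at a given level (binary/categorical covariates condition on
#' their full indicator coding).
#'
#' @param joint a [JointModel-class].
#' @param covariate covariate name.
#' @param value numeric value (continuous, original scale) or level
#'   (binary/categorical).
#' @return List with `mean` (length L) and `cov` (L x L).
#' @export
conditionalLatent <- function(joint, covariate, value) {
  stopifnot(is(joint, "JointModel"))
  tab <- specTable(joint@specs)
  i <- match(covariate, tab$name)
  if (is.na(i)) stop(sprintf("unknown covariate '%s'", covariate))
  cols <- joint@columns[[covariate]]
  li <- match(joint@latentNames, colnames(joint@cov))
  ci <- match(cols, colnames(joint@cov))
  if (tab$kind[i] == "continuous") {
    v <- as.numeric(value)
    if (tab$transform[i] == "log") {
      if (v <= 0) stop("value must be positive for a log-transformed covariate")
      v <- log(v)
    }
  } else if (tab$kind[i] == "binary") {
    lv <- joint@specs@levels[[covariate]]
    v <- if (is.character(value) || is.factor(value))
      as.numeric(as.character(value) != tab$reference[i])
    else as.numeric(value)
    if (!v %in% c(0, 1)) stop("binary covariate value must be 0/1 or a level")
  } else {
    lv <- as.character(value)
    known <- joint@specs@levels[[covariate]]
    if (!lv %in% known)
      stop(sprintf("unknown level '%s' for covariate '%s'", lv, covariate))
    v <- as.numeric(paste0(covariate, "=", lv) == cols)
  }
  Soo <- joint@cov[ci, ci, drop = FALSE]
  Slo <- joint@cov[li, ci, drop = FALSE]
  B <- Slo %*% solve(Soo)
  mu <- drop(joint@mean[li] + B %*% (v - joint@mean[ci]))
  Sg <- symmetrize(joint@cov[li, li] - B %*% t(Slo))
  dimnames(Sg) <- list(joint@latentNames, joint@latentNames)
  list(mean = stats::setNames(mu, joint@latentNames), cov = Sg)
}
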