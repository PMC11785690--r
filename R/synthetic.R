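# Synthetic population generator. Produces cohorts with the statistical
# structure the analysis assumes -- correlated latent disease facets, item
# responses from the item models, mixed-type covariates tied to the facets
# through a Gaussian copula with marginals anchored to the published summary
# table, configurable missingness -- together with a truth record sufficient
# for parameter-recovery experiments. Item parameters and the full covariate
# correlation structure of the original study are not public; the defaults
# here are synthetic and labelled as such.

#' Truth configuration of the synthetic population
#'
#' @slot N number of subjects.
#' @slot items list of true [ItemParameters-class].
#' @slot Sigma true latent correlation matrix.
#' @slot covariates data.frame of covariate definitions: kind, marginal
#'   family and parameters, missingness rate, copula-scale correlations with
#'   the five latent facets, derived-ratio bookkeeping.
#' @slot catLevels named list of level sets and probabilities for categorical
#'   covariates.
#' @slot anchorItem the residual item anchoring the fifth facet.
#' @export
setClass("TruthConfig",
  representation(N = "integer", items = "list", Sigma = "matrix",
                 covariates = "data.frame", catLevels = "list",
                 anchorItem = "character"))

setValidity("TruthConfig", function(object) {
  msg <- character()
  if (object@N < 1L) msg <- c(msg, "N must be positive")
  ok <- tryCatch({ validateCorrelation(object@Sigma); TRUE },
                 error = function(e) { msg <<- c(msg, conditionMessage(e)); FALSE })
  if (ok) {
    # the joint copula over (theta, covariate scores) must be proper:
    # each covariate needs c' Sigma^-1 c < 1
    Si <- solve(object@Sigma)
    cc <- as.matrix(object@covariates[, paste0("c", 1:5)])
    q <- rowSums((cc %*% Si) * cc)
    bad <- which(!object@covariates$derived & q >= 1)
    if (length(bad))
      msg <- c(msg, sprintf("joint latent-covariate correlation not PD for: %s",
                            paste(object@covariates$name[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthConfig", function(object) {
  cat(sprintf("TruthConfig: N = %d, %d items, %d covariates\n", object@N,
              length(object@items), nrow(object@covariates)))
})

defaultTruthItems <- function() {
  # Synthetic item parameters: cardinal items load their exclusive facet,
  # hepatocellular ballooning with the largest slope (it discriminates
  # disease intensity best); the portal chronic inflammation anchor loads
  # only the residual facet; the eight binary lesions load all five facets
  # weakly with the residual facet dominating. Lobular inflammation
  # intercepts reproduce the scarcity of grade 0 (under 1% of subjects).
  sl <- function(...) c(...)
  list(
    itemParameters("steatosis", "ordered", 4L, 1L, sl(1.8, 0, 0, 0, 0),
                   c(2.0, 0.0, -2.0)),
    itemParameters("lobular_inflammation", "ordered", 4L, 2L,
                   sl(0, 1.6, 0, 0, 0), c(6.8, 0.6, -2.5)),
    itemParameters("ballooning", "ordered", 3L, 3L, sl(0, 0, 2.4, 0, 0),
                   c(1.0, -1.0)),
    itemParameters("portal_inflammation", "ordered", 3L, 1:5,
                   sl(0, 0, 0, 0, 1.4), c(2.0, -1.5)),
    itemParameters("fibrosis", "ordered", 5L, 4L, sl(0, 0, 0, 1.8, 0),
                   c(1.5, 0.0, -1.5, -3.0)),
    itemParameters("microvesicular_steatosis", "binary", 2L, 1:5,
                   sl(0.6, 0.2, 0.2, 0.2, 0.8), -2.0),
    itemParameters("microgranulomas", "binary", 2L, 1:5,
                   sl(0.2, 0.6, 0.2, 0.2, 0.7), -1.5),
    itemParameters("large_lipogranulomas", "binary", 2L, 1:5,
                   sl(0.5, 0.3, 0.2, 0.4, 0.6), -2.2),
    itemParameters("acidophil_bodies", "binary", 2L, 1:5,
                   sl(0.2, 0.5, 0.5, 0.2, 0.7), -1.8),
    itemParameters("pigmented_macrophages", "binary", 2L, 1:5,
                   sl(0.3, 0.3, 0.4, 0.4, 0.9), -0.5),
    itemParameters("megamitochondria", "binary", 2L, 1:5,
                   sl(0.3, 0.2, 0.3, 0.2, 0.6), -2.5),
    itemParameters("mallory_hyaline", "binary", 2L, 1:5,
                   sl(0.3, 0.4, 0.6, 0.5, 0.8), -2.0),
    itemParameters("glycogen_nuclei", "binary", 2L, 1:5,
                   sl(0.4, 0.2, 0.2, 0.3, 0.7), -1.0))
}

#' Default latent correlation matrix
#'
#' Ballooning-fibrosis 0.69, inflammation-ballooning 0.62,
#' steatosis-inflammation 0.60 (the three published latent-scale
#' correlations); all remaining entries 0.3 (synthetic default).
#' @return A 5 x 5 correlation matrix.
#' @export
defaultLatentCorrelation <- function() {
  S <- matrix(0.3, 5, 5)
  S[1, 2] <- S[2, 1] <- 0.60
  S[2, 3] <- S[3, 2] <- 0.62
  S[3, 4] <- S[4, 3] <- 0.69
  diag(S) <- 1
  S
}

# marginal family per the asymmetry of the printed percentiles: right-skewed
# positive covariates are generated log-normally, the rest normally
marginalFamily <- function(median, p2.5, p97.5) {
  if (is.na(p2.5) || p2.5 <= 0) return("normal")
  if ((p97.5 - median) > 1.5 * (median - p2.5)) "lognormal" else "normal"
}

marginalParams <- function(family, median, p2.5, p97.5) {
  if (family == "lognormal") {
    s <- mean(c(log(p97.5 / median), log(median / p2.5))) / stats::qnorm(0.975)
    c(mu = log(median), sigma = s)
  } else {
    c(mu = median, sigma = (p97.5 - p2.5) / (2 * stats::qnorm(0.975)))
  }
}

#' Default truth configuration
#'
#' The study conditions the generator emulates: 914 subjects; the default
#' latent correlation matrix; synthetic item parameters (see
#' `defaultTruthItems`); 69 covariates with marginals anchored to the
#' published population table (medians, 2.5th/97.5th percentiles,
#' prevalences), missingness 0-34.4% except 56.9% for alpha-fetoprotein, and
#' synthetic copula-scale correlations with the latent facets. AST/ALT and
#' waist/hip enter as ratios of their generated components.
#'
#' @param N number of subjects.
#' @return A [TruthConfig-class] object.
#' @export
defaultTruth <- function(N = 914L) {
  cfgPath <- system.file("extdata", "covariate_config_synthetic.csv",
                         package = "hepirt", mustWork = TRUE)
  tab <- utils::read.csv(cfgPath, stringsAsFactors = FALSE)
  tab$derived <- tab$derived == 1
  tab$family <- NA_character_
  tab$mu <- NA_real_
  tab$sigma <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (tab$kind[i] == "continuous" && !tab$derived[i]) {
      tab$family[i] <- marginalFamily(tab$median[i], tab$p2_5[i], tab$p97_5[i])
      pp <- marginalParams(tab$family[i], tab$median[i], tab$p2_5[i], tab$p97_5[i])
      tab$mu[i] <- pp["mu"]
      tab$sigma[i] <- pp["sigma"]
    }
  }
  catLevels <- list()
  for (i in which(tab$kind == "categorical")) {
    catLevels[[tab$name[i]]] <- list(
      levels = strsplit(tab$levels[i], ";")[[1L]],
      probs = as.numeric(strsplit(tab$probs[i], ";")[[1L]]))
  }
  new("TruthConfig", N = as.integer(N), items = defaultTruthItems(),
      Sigma = defaultLatentCorrelation(), covariates = tab,
      catLevels = catLevels, anchorItem = "portal_inflammation")
}

#' True covariate-latent correlations on the analysis scale
#'
#' The correlations the stage-2 joint model estimates, derived from the
#' copula-scale configuration: continuous covariates keep the copula
#' correlation (their analysis scale is an affine map of the Gaussian score);
#' binary and categorical indicator columns are attenuated by the biserial
#' factor `phi(z) / sqrt(p (1 - p))` of their thresholds. Derived ratio
#' covariates are excluded (no closed form on the analysis scale).
#'
#' @param config a [TruthConfig-class].
#' @return data.frame with `column`, `covariate`, `kind` and `LV1`..`LV5`.
#' @export
truthCorrelations <- function(config) {
  tab <- config@covariates
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    if (tab$derived[i]) next
    cc <- as.numeric(tab[i, paste0("c", 1:5)])
    if (tab$kind[i] == "continuous") {
      rows[[length(rows) + 1L]] <- data.frame(
        column = tab$name[i], covariate = tab$name[i], kind = "continuous",
        t(stats::setNames(cc, paste0("LV", 1:5))))
    } else if (tab$kind[i] == "binary") {
      p <- tab$prevalence[i]
      fac <- stats::dnorm(stats::qnorm(1 - p)) / sqrt(p * (1 - p))
      rows[[length(rows) + 1L]] <- data.frame(
        column = tab$name[i], covariate = tab$name[i], kind = "binary",
        t(stats::setNames(cc * fac, paste0("LV", 1:5))))
    } else {
      cl <- config@catLevels[[tab$name[i]]]
      cum <- c(0, cumsum(cl$probs))
      for (k in seq_along(cl$levels)) {
        a <- stats::qnorm(cum[k]); b <- stats::qnorm(cum[k + 1L])
        pk <- cl$probs[k]
        fac <- (stats::dnorm(a) - stats::dnorm(b)) / sqrt(pk * (1 - pk))
        rows[[length(rows) + 1L]] <- data.frame(
          column = paste0(tab$name[i], "=", cl$levels[k]),
          covariate = tab$name[i], kind = "categorical",
          t(stats::setNames(cc * fac, paste0("LV", 1:5))))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic study population
#'
#' Draws the latent vectors from `MVN(0, Sigma)`, item responses from the
#' item models, and covariates through a Gaussian copula: each covariate's
#' Gaussian score is `b' theta + s eps` with `b = Sigma^-1 c` so its
#' correlation with the latent vector equals the configured `c` exactly;
#' marginals are applied by the configured normal/log-normal quantile maps,
#' prevalence thresholds (binary) or probability thresholds (categorical).
#' Missingness is MCAR at the configured per-covariate rates. Derived ratios
#' (AST/ALT, waist/hip) are computed by division from their components.
#'
#' @param config a [TruthConfig-class].
#' @param seed integer seed; the output is deterministic given config + seed.
#' @return List with `responses` (N x 13 integer matrix), `covariates`
#'   (data.frame with `NA` for missing cells), `theta` (N x 5 true latent
#'   matrix), `truth` (the config plus [truthCorrelations()]).
#' @export
generatePopulation <- function(config, seed = 1L) {
  stopifnot(is(config, "TruthConfig"))
  validObject(config)
  N <- config@N
  tab <- config@covariates
  L <- nrow(config@Sigma)
  Si <- solve(config@Sigma)
  withSeed(seed, {
    theta <- rmvn(N, rep(0, L), config@Sigma)
    responses <- vapply(config@items, function(it) simulateResponse(it, theta),
                        integer(N))
    colnames(responses) <- vapply(config@items, itemName, "")
    rownames(responses) <- as.character(seq_len(N))

    covs <- list()
    for (i in seq_len(nrow(tab))) {
      if (tab$derived[i]) next
      cc <- as.numeric(tab[i, paste0("c", 1:5)])
      b <- drop(Si %*% cc)
      s2 <- 1 - sum(cc * b)
      u <- drop(theta %*% b) + sqrt(max(s2, 0)) * stats::rnorm(N)
      nm <- tab$name[i]
      if (tab$kind[i] == "continuous") {
        x <- if (tab$family[i] == "lognormal") exp(tab$mu[i] + tab$sigma[i] * u)
             else tab$mu[i] + tab$sigma[i] * u
      } else if (tab$kind[i] == "binary") {
        x <- as.integer(u > stats::qnorm(1 - tab$prevalence[i]))
      } else {
        cl <- config@catLevels[[nm]]
        br <- stats::qnorm(cumsum(cl$probs))
        br[length(br)] <- Inf
        x <- cl$levels[findInterval(u, c(-Inf, utils::head(br, -1L))) ]
      }
      covs[[nm]] <- x
    }
    for (i in which(tab$derived)) {
      comp <- strsplit(tab$components[i], ";")[[1L]]
      covs[[tab$name[i]]] <- covs[[comp[1L]]] / covs[[comp[2L]]]
    }
    covs <- as.data.frame(covs, stringsAsFactors = FALSE)[, tab$name]
    rownames(covs) <- as.character(seq_len(N))
    # MCAR missingness; a derived ratio is missing when either component is
    for (i in seq_len(nrow(tab))) {
      if (tab$derived[i] || tab$miss_rate[i] <= 0) next
      miss <- stats::runif(N) < tab$miss_rate[i]
      covs[[tab$name[i]]][miss] <- NA
    }
    for (i in which(tab$derived)) {
      comp <- strsplit(tab$components[i], ";")[[1L]]
      covs[[tab$name[i]]][is.na(covs[[comp[1L]]]) | is.na(covs[[comp[2L]]])] <- NA
    }
    list(responses = responses, covariates = covs, theta = theta,
         truth = list(config = config, correlations = truthCorrelations(config)))
  })
}

#' Generate dated raw form records
#'
#' Wraps a generated population in the raw record layout the preprocessing
#' rules consume: per subject one to three dated biopsies (82.8% have one,
#' 1.42% three, the rest two), dated liver-panel records, and long-format
#' biomarker records whose dates mostly fall inside the one-year window
#' around the analysis biopsy. The analysis biopsy (the one closest to a
#' liver panel) carries the population's item scores, with fibrosis stage 1
#' written as a random sub-stage 1a/1b/1c; additional biopsies lie farther
#' from the panels and carry perturbed scores. Missing covariate cells
#' either emit no record or an out-of-window record. One subject gets a
#' biomarker exactly 366 days from the biopsy (boundary fixture: must end
#' missing).
#'
#' @param config a [TruthConfig-class].
#' @param seed integer seed.
#' @return List with `biopsies`, `liver_panel`, `biomarkers` data.frames and
#'   the generating `population`.
#' @export
generateRawRecords <- function(config, seed = 1L) {
  pop <- generatePopulation(config, seed = seed)
  N <- config@N
  tab <- config@covariates
  itemNms <- colnames(pop$responses)
  panelVars <- c("alt", "ast", "alkaline_phosphatase", "ggt",
                 "bilirubin_total", "bilirubin_direct", "albumin",
                 "total_protein")
  withSeed(subSeed(seed, 9L), {
    baseDate <- as.Date("2005-01-01") + sample.int(1200L, N, replace = TRUE)
    nBiopsy <- sample(c(1L, 2L, 3L), N, replace = TRUE,
                      prob = c(0.828, 1 - 0.828 - 0.0142, 0.0142))
    bioRows <- list()
    for (i in seq_len(N)) {
      sc <- pop$responses[i, ]
      fib <- as.character(sc[["fibrosis"]])
      if (fib == "1") fib <- sample(c("1a", "1b", "1c"), 1L)
      row <- data.frame(subject_id = as.character(i),
                        biopsy_date = baseDate[i], stringsAsFactors = FALSE)
      for (nm in itemNms)
        row[[nm]] <- if (nm == "fibrosis") fib else as.character(sc[[nm]])
      row$lesion_location <- sample(c("zone1", "zone2", "zone3"), 1L)
      bioRows[[length(bioRows) + 1L]] <- row
      if (nBiopsy[i] > 1L) for (k in seq_len(nBiopsy[i] - 1L)) {
        # extra biopsies: farther from every liver panel, perturbed scores
        row2 <- row
        row2$biopsy_date <- baseDate[i] + 200L * k + sample.int(50L, 1L)
        jit <- pmin(pmax(sc + sample(c(-1L, 0L, 1L), length(sc), TRUE), 0L),
                    vapply(config@items, nCategories, 0L) - 1L)
        for (nm in itemNms)
          row2[[nm]] <- if (nm == "fibrosis") {
            f <- jit[[nm]]
            if (f == 1L) sample(c("1a", "1b", "1c"), 1L) else as.character(f)
          } else as.character(jit[[nm]])
        bioRows[[length(bioRows) + 1L]] <- row2
      }
    }
    biopsies <- do.call(rbind, bioRows)

    panelDelta <- sample(-20:20, N, replace = TRUE)
    lp <- data.frame(subject_id = as.character(seq_len(N)),
                     panel_date = baseDate + panelDelta,
                     stringsAsFactors = FALSE)
    for (v in panelVars) lp[[v]] <- pop$covariates[[v]]

    bmRows <- list()
    otherVars <- setdiff(tab$name[!tab$derived], panelVars)
    for (nm in otherVars) {
      x <- pop$covariates[[nm]]
      delta <- sample(-180:180, N, replace = TRUE)
      present <- !is.na(x)
      if (any(present))
        bmRows[[length(bmRows) + 1L]] <- data.frame(
          subject_id = as.character(which(present)),
          date = baseDate[present] + delta[present],
          name = nm, value = as.character(x[present]),
          stringsAsFactors = FALSE)
      missIdx <- which(!present)
      if (length(missIdx)) {
        # some missing cells exist as stale records outside the window
        stale <- missIdx[stats::runif(length(missIdx)) < 0.3]
        if (length(stale))
          bmRows[[length(bmRows) + 1L]] <- data.frame(
            subject_id = as.character(stale),
            date = baseDate[stale] + 400L + sample.int(200L, length(stale), TRUE),
            name = nm, value = as.character(
              if (tab$kind[match(nm, tab$name)] == "continuous")
                stats::median(x, na.rm = TRUE) else x[present][1L]),
            stringsAsFactors = FALSE)
      }
    }
    biomarkers <- do.call(rbind, bmRows)
    # boundary fixture: subject 1 gets a tsh record exactly 366 days out and
    # no in-window tsh record
    biomarkers <- biomarkers[!(biomarkers$subject_id == "1" &
                               biomarkers$name == "tsh"), ]
    biomarkers <- rbind(biomarkers, data.frame(
      subject_id = "1", date = baseDate[1L] + 366L, name = "tsh",
      value = "1.75", stringsAsFactors = FALSE))
    rownames(biomarkers) <- NULL
    list(biopsies = biopsies, liver_panel = lp, biomarkers = biomarkers,
         population = pop)
  })
}
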