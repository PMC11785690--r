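# Expected histological scores conditional on covariate extremes, and the
# score-range coverage criterion used to flag influential noninvasive
# biomarkers (a biomarker is influential for a score when its 2.5th-97.5th
# percentile span covers at least 25% of the score's theoretical range).

nasComponents <- function() c("steatosis", "lobular_inflammation", "ballooning")

targetRange <- function(model, target) {
  if (identical(target, "NAS")) {
    comp <- nasComponents()
    if (!all(comp %in% itemNames(model)))
      stop("model lacks the NAS component items")
    return(sum(vapply(modelItems(model)[comp], nCategories, 0L) - 1L))
  }
  it <- modelItems(model)[[target]]
  if (is.null(it)) stop(sprintf("unknown target '%s'", target))
  nCategories(it) - 1L
}

expectedScoreAt <- function(model, target, mu, Sg, nMC, z) {
  theta <- rmvn(nMC, mu, Sg, z = z)
  if (identical(target, "NAS")) {
    sum(vapply(nasComponents(), function(nm)
      mean(expectedItemScore(modelItems(model)[[nm]], theta)), 0))
  } else {
    mean(expectedItemScore(modelItems(model)[[target]], theta))
  }
}

#' Expected histological score given a covariate value
#'
#' Monte Carlo estimate of `E[score | covariate = value]`: the latent vector is
#' drawn from its conditional distribution given the covariate
#' ([conditionalLatent()]) and the item's expected score is averaged over the
#' draws. The NAS composite is the sum of the expected scores of steatosis,
#' lobular inflammation and hepatocellular ballooning (linearity of
#' expectation), computed on the same draws.
#'
#' @param joint a [JointModel-class].
#' @param model the [LatentModel-class] holding the item parameters.
#' @param target an item name or `"NAS"`.
#' @param covariate covariate name.
#' @param value covariate value (original scale) or level.
#' @param nMC number of Monte Carlo draws.
#' @param seed integer seed; the same seed yields common random numbers across
#'   conditioning values (variance reduction for contrasts).
#' @return Expected score, a scalar within the target's score range.
#' @export
expectedScoreGiven <- function(joint, model, target, covariate, value,
                               nMC = 20000L, seed = 1L) {
  stopifnot(is(joint, "JointModel"), is(model, "LatentModel"))
  targetRange(model, target)  # validates target
  cond <- conditionalLatent(joint, covariate, value)
  L <- length(cond$mean)
  z <- withSeed(seed, matrix(stats::rnorm(nMC * L), nMC, L))
  expectedScoreAt(model, target, cond$mean, cond$cov, nMC, z)
}

#' Score-range coverage of a covariate
#'
#' Expected scores at the covariate's 2.5th and 97.5th percentiles (or at all
#' category levels), the fraction of the theoretical score range they span,
#' and the influential flag (coverage at or above the threshold). The mean
#' expected score is evaluated at the covariate's median (continuous) or as
#' the prevalence-weighted mean over levels (binary/categorical).
#'
#' @inheritParams expectedScoreGiven
#' @param threshold coverage fraction flagging an influential covariate.
#' @return A one-row data.frame: `target`, `covariate`, `valueLow`,
#'   `valueHigh`, `scoreLow`, `scoreHigh`, `meanScore`, `coverage`,
#'   `influential`.
#' @export
scoreCoverage <- function(joint, model, target, covariate, threshold = 0.25,
                          nMC = 20000L, seed = 1L) {
  rng <- targetRange(model, target)
  tab <- specTable(joint@specs)
  i <- match(covariate, tab$name)
  if (is.na(i)) stop(sprintf("unknown covariate '%s'", covariate))
  L <- length(joint@latentNames)
  z <- withSeed(seed, matrix(stats::rnorm(nMC * L), nMC, L))
  marg <- joint@marginals[[covariate]]
  if (tab$kind[i] == "continuous") {
    vals <- c(marg$p2.5, marg$p97.5)
    es <- vapply(vals, function(v) {
      cond <- conditionalLatent(joint, covariate, v)
      expectedScoreAt(model, target, cond$mean, cond$cov, nMC, z)
    }, 0)
    condMed <- conditionalLatent(joint, covariate, marg$median)
    meanScore <- expectedScoreAt(model, target, condMed$mean, condMed$cov, nMC, z)
    low <- es[1L]; high <- es[2L]
    valueLow <- vals[1L]; valueHigh <- vals[2L]
  } else {
    lv <- marg$levels
    es <- vapply(lv, function(l) {
      cond <- conditionalLatent(joint, covariate, l)
      expectedScoreAt(model, target, cond$mean, cond$cov, nMC, z)
    }, 0)
    meanScore <- sum(es * marg$probs)
    iLow <- which.min(es); iHigh <- which.max(es)
    low <- es[iLow]; high <- es[iHigh]
    valueLow <- lv[iLow]; valueHigh <- lv[iHigh]
  }
  cov <- abs(high - low) / rng
  data.frame(target = target, covariate = covariate,
             valueLow = as.character(valueLow), valueHigh = as.character(valueHigh),
             scoreLow = low, scoreHigh = high, meanScore = meanScore,
             coverage = cov, influential = cov >= threshold,
             stringsAsFactors = FALSE)
}

#' Coverage screen over all targets and covariates
#'
#' Runs [scoreCoverage()] for every target (the 13 items and the NAS
#' composite, by default) against every covariate, returning one row per pair
#' ordered by target then by decreasing coverage.
#'
#' @inheritParams scoreCoverage
#' @param targets character vector of item names and/or `"NAS"`; defaults to
#'   all model items plus the NAS composite.
#' @param covariates covariate names; defaults to all in the joint model.
#' @return A data.frame with one row per target x covariate pair.
#' @export
coverageScreen <- function(joint, model, targets = NULL, covariates = NULL,
                           threshold = 0.25, nMC = 20000L, seed = 1L) {
  if (is.null(targets)) {
    targets <- itemNames(model)
    if (all(nasComponents() %in% targets)) targets <- c(targets, "NAS")
  }
  if (is.null(covariates)) covariates <- specTable(joint@specs)$name
  rows <- list()
  for (tg in targets) for (cv in covariates)
    rows[[length(rows) + 1L]] <-
      scoreCoverage(joint, model, tg, cv, threshold = threshold,
                    nMC = nMC, seed = seed)
  out <- do.call(rbind, rows)
  out[order(match(out$target, targets), -out$coverage), , drop = FALSE]
}

#' Coverage bar chart
#'
#' Horizontal bar chart of expected scores at the covariate extremes for one
#' target, in the style of a biomarker-impact panel: one bar pair per
#' covariate, a dashed line at the mean expected score.
#'
#' @param screen data.frame from [coverageScreen()] (one target).
#' @param target the target to plot.
#' @param onlyInfluential drop covariates below the coverage threshold.
#' @return A ggplot object.
#' @export
plotCoverage <- function(screen, target = screen$target[1L],
                         onlyInfluential = TRUE) {
  df <- screen[screen$target == target, , drop = FALSE]
  if (onlyInfluential) df <- df[df$influential, , drop = FALSE]
  if (!nrow(df)) stop("nothing to plot")
  df <- df[order(df$coverage), , drop = FALSE]
  df$covariate <- factor(df$covariate, levels = df$covariate)
  long <- rbind(
    data.frame(covariate = df$covariate, end = "P2.5/low", score = df$scoreLow),
    data.frame(covariate = df$covariate, end = "P97.5/high", score = df$scoreHigh))
  ggplot2::ggplot(long, ggplot2::aes(x = score, y = covariate,
                                     fill = end)) +
    ggplot2::geom_col(position = "dodge", width = 0.7) +
    ggplot2::geom_vline(xintercept = mean(df$meanScore), linetype = "dashed") +
    ggplot2::labs(x = sprintf("expected %s score", target), y = NULL,
                  fill = "covariate end") +
    ggplot2::theme_minimal()
}
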