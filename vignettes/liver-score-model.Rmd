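---
title: "Modelling histological liver scores and their noninvasive correlates"
author: "hepirt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling histological liver scores and their noninvasive correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepirt)
```

## The problem

Nonalcoholic fatty liver disease (NAFLD) is assessed histologically with the
NASH-CRN scoring system: five ordered biopsy scores (steatosis 0–3, lobular
inflammation 0–3, hepatocellular ballooning 0–2, portal chronic inflammation
0–2, fibrosis 0–4) and eight binary lesion indicators (microvesicular
steatosis, microgranulomas, large lipogranulomas, acidophil bodies, pigmented
macrophages, megamitochondria, Mallory's hyaline, glycogen nuclei). The sum
steatosis + lobular inflammation + ballooning is the NAFLD activity score
(NAS, 0–8). Biopsies are invasive, noisy and hard to repeat, so a central
applied question is which *noninvasive* characteristics (routine labs,
anthropometry, comorbidities) track which histological scores, and over how
much of each score's range.

`hepirt` treats the 13 scores as items of a multidimensional item response
theory (IRT) model, scores each subject on latent disease facets, relates the
facets to a large panel of mixed-type covariates through a joint correlation
model, and summarizes each covariate's reach as the fraction of a score's
range spanned between its 2.5th and 97.5th percentile.

## The item response model

Item $j$ with $K_j$ ordered categories follows a graded-response model over a
latent vector $\theta \in \mathbb{R}^5$:
$$
P(Y_j \ge k \mid \theta) = \operatorname{logit}^{-1}(a_j^\top \theta + d_{jk}),
\qquad k = 1, \dots, K_j - 1,
$$
with slope vector $a_j$ (zero outside the item's loading pattern) and strictly
decreasing intercepts $d_{j1} > \dots > d_{j,K_j-1}$. Binary lesions are the
$K_j = 2$ special case (the two-parameter logistic model). The latent vector
is standard multivariate normal with correlation matrix $\Sigma$; all latent
variances are fixed at one so slopes are free and facet associations are read
directly as correlations.

The default loading structure ties each of the four cardinal NAFLD features
(steatosis, lobular inflammation, ballooning, fibrosis) exclusively to one
facet LV1–LV4, while the nine residual lesions load on all five facets; LV5
carries only residual features. An exploratory map with every item on every
facet is also constructible (`exploratoryLoadingMap()`), but is identified
only up to rotation and is meant as a structural guide, not a reporting
model.

### Identification

With the default map the model has a genuine partial rotation problem: any
unit-variance linear combination $\theta_5^* = c^\top\theta$ leaves the
likelihood unchanged while reshuffling the residual loadings and the fifth
row of $\Sigma$, because no item loads on LV5 alone. `fitIRT()` therefore
designates an anchor item for any facet without an exclusive loader —
portal chronic inflammation by default — and fixes its loadings on the other
facets to zero during estimation, which removes the indeterminacy exactly.
Orientation (sign) is fixed by constraining each facet's exclusive or anchor
item to a positive slope, so "higher $\theta$" always means more severe
disease. The synthetic truth configuration uses the same convention, making
parameter recovery a well-posed question.

## Estimation: MHRM with chain averaging

`fitIRT()` maximizes the marginal likelihood by Metropolis–Hastings
Robbins-Monro stochastic approximation: each cycle draws one random-walk
Metropolis sweep of every subject's $\theta$ given the current parameters,
then applies gain-weighted Fisher-scoring updates to each item's parameters
and a gain-weighted update of $\Sigma$ from the sampled latent vectors
(projected back to a correlation matrix). Defaults: 200 burn-in cycles at
gain 1 (stochastic EM), then up to 400 decaying-gain cycles with
$\gamma_k = \max(0.1,\, k^{-0.75})$, proposal scale adapted during burn-in to
a 0.35 acceptance rate, convergence declared when every parameter update
stays below $10^{-3}$ over three consecutive 10-cycle windows.

Two numerical choices matter and were selected after systematic synthetic
experiments:

* **Gain floor and tail averaging.** Cross-loadings of rare binary lesions on
  five correlated facets are weakly identified; with a purely decaying gain
  their iterates freeze wherever burn-in noise leaves them, while a
  constant-gain tail keeps the iterates orbiting the maximum likelihood
  estimate so that the Polyak average over the last 70% of the
  Robbins-Monro phase centers on it.
* **Multiple chains.** A single chain still carries stochastic-approximation
  noise of roughly $\pm 0.1$ on weakly identified parameters at moderate
  cohort sizes. `fitIRT(..., nStarts = n)` runs $n$ chains from derived
  sub-seeds and averages their parameters; all chains target the same
  maximizer, so averaging cancels this noise at linear cost.

Ordered intercepts are kept strictly decreasing by step halving;
a violation simply skips that cycle's update for the item. Standard errors
come from the accumulated expected complete-data information and are
documented as approximate (anti-conservative); the bootstrap covers the
covariate stage. Items observed in a single category are rejected with the
item named, and non-finite likelihood states abort with the cycle index.

## Subject scores

`eapScores()` samples $\theta \mid$ responses per subject with a vectorized
random-walk chain and reports posterior means, posterior covariances and
retained draws. Missing item responses drop out of the likelihood
(missing at random); a subject with no observed items gets the prior (mean
zero, covariance $\Sigma$) exactly. Burn-in and thinning defaults are
generous on purpose: the covariate stage divides by
$W = \Sigma - \overline{V}$, where $\overline{V}$ is the average posterior
covariance, and an under-mixed chain underestimates $\overline{V}$, which
showed up in synthetic runs as residual attenuation of covariate
correlations, not merely extra Monte Carlo noise.

## The joint latent–covariate model

Covariates are classified by `buildCovariateSpecs()`: binary and categorical
covariates enter as 0/1 indicators (one per non-reference level), and a
strictly positive continuous covariate with sample skewness above 1 is log
transformed; percentiles are always reported on the original scale. The
joint mean and covariance of (latent vector, covariate columns) is estimated
by EM over missing covariate cells (`mvnEM()`), with columns standardized
internally (raw scales span ten orders of magnitude) and a $10^{-6}$
relative ridge per iteration, which keeps the estimate usable even when a
derived log ratio is exactly collinear with its logged components. The
E-step works on the precision matrix so each row costs a solve the size of
its missing block only.

Posterior draws serve as multiple imputations of $\theta$. Pooling is done
at the draw level (each imputation is a block mean of the retained draws and
the pooled value is the grand mean): linear functionals of the joint
Gaussian are unchanged in expectation, the draw noise entering the
cross-covariances is minimal, and the estimate is invariant to the
imputation count by construction — results should not depend on an arbitrary
choice of that tuning parameter.

### Shrinkage correction

Posterior summaries of $\theta$ are shrunken toward the prior, so the naive
cross-covariance estimates $\operatorname{cov}(\mathrm{EAP}, x) = W B^\top$
rather than $\operatorname{cov}(\theta, x) = \Sigma B^\top$ (with $B$ the
regression of the covariate columns on $\theta$). With 13 items the per-facet
reliability is only about 0.55–0.7, an attenuation far too large to ignore.
`fitJointModel()` therefore deattenuates the cross block by
$\Sigma W^{-1}$, taking $W$ model-implied via the law of total variance
($W = \Sigma - \overline{V}$), which is much less noisy than the empirical
covariance of the posterior means. The latent block of the joint matrix is
set to the scoring model's $\Sigma$, and the result is projected to the
nearest positive-definite correlation-consistent matrix if the correction
leaves the eigenvalue cone. $W$ is genuinely ill-conditioned along facet
combinations the items barely measure; no eigenvalue flooring is applied
because the floored estimator proved more biased in synthetic experiments —
the price is visible variance (not bias) on correlations involving those
directions, which the bootstrap reports honestly.

The sign convention follows the latent orientation: a positive correlation
means high covariate values accompany high disease activity.

## Expected scores and the coverage criterion

`conditionalLatent()` conditions the latent vector on one covariate by exact
multivariate-normal conditioning (on the transform scale for logged
covariates, on the full indicator coding for categorical ones).
`expectedScoreGiven()` averages the item's expected score over Monte Carlo
draws from that conditional (default 20 000 draws, common random numbers
across conditioning values so contrasts are low-variance); the NAS composite
is the sum of its three components' expectations on the same draws.
`scoreCoverage()` evaluates the expected score at the covariate's 2.5th and
97.5th percentile (or at every category level), and divides the spanned
score difference by the *theoretical* score range (e.g. 8 for the NAS) —
matching the idea that an ideal biomarker would sweep the full range of the
score. A covariate is flagged influential when this coverage reaches 25%.
The mean expected score is evaluated at the covariate's median
(prevalence-weighted over levels for categorical covariates); the choice is a
convention, stated here because the quantity is only loosely defined by the
plotting tradition it imitates. `coverageScreen()` applies this to all
13 items plus the NAS against every covariate.

## Uncertainty and diagnostics

`bootstrapJoint()` resamples subjects with replacement (200 replicates by
default), refits the covariate stage per replicate with the item model held
fixed, and reports equal-tailed 2.5/97.5 percentile intervals. Holding
stage 1 fixed makes this a conditional bootstrap that understates total
uncertainty by the item-parameter component; refitting MHRM inside every
replicate would dominate the cost budget for little change in the covariate
intervals at these reliabilities. Replicate failures are logged and skipped,
and more than 10% failures abort. Sub-seeds derive from the master seed by a
counter scheme, so results are reproducible.

`simulateDatasets()` draws replicate cohorts under the model (500 by
default), `correlationPPC()` compares observed item-pair Pearson correlations
with the central 95% band of the simulated ones, and `mirrorFrequencies()`
provides the observed-versus-simulated category proportions behind a
back-to-back mirror plot. Pearson correlations on the raw integer scores are
used for both binary and ordered items — a single uniform, assumption-light
summary; a polychoric alternative would presume the model's own latent
normality while checking it.

## Preprocessing rules

Raw dated records reduce to one analysis row per subject deterministically:
the analysis biopsy is the one closest in time to a liver-panel measurement
(ties to the earlier biopsy; subjects without any biopsy are dropped, and
without any panel the earliest biopsy is used and logged); each biomarker
takes its nearest measurement within 365 days of that biopsy, otherwise it is
missing (ties to the earlier record); fibrosis sub-stages 1a/1b/1c collapse
to stage 1; the qualitative lesion-location field is dropped; AST/ALT and
waist/hip ratios are derived by division and are missing when either
component is. "One year" is interpreted as 365 whole days, time of day
ignored — both undocumented in the tradition these rules follow, so fixed
here by convention and tested at the boundary (day 365 attaches, day 366
does not).

## The synthetic population

`defaultTruth()` encodes the study conditions every test runs under: 914
adults; latent correlations 0.69 (ballooning–fibrosis), 0.62
(inflammation–ballooning), 0.60 (steatosis–inflammation) and 0.3 elsewhere;
69 covariates whose medians, 2.5th/97.5th percentiles and prevalences follow
the published population table; missingness 0–34.4% except 56.9% for
alpha-fetoprotein; and 82.8%/1.42% of subjects with one/three biopsies in the
raw-record generator. Item parameters are *synthetic* (the originals are not
public): cardinal slopes around 1.8 with hepatocellular ballooning largest
(2.4, echoing its reported discriminating role), residual lesions loading
weakly on all facets with LV5 dominant, and lobular-inflammation intercepts
set so that grade 0 is rare (under 1% of subjects, matching the study's
imbalance). Covariate–latent correlations are likewise synthetic defaults
chosen for clinical plausibility: age and platelets (negative) strongest on
the fibrosis facet, aminotransferases on the activity facets, glycaemia
markers on ballooning and fibrosis, and near-zero elsewhere (sex in
particular), with magnitudes capped at 0.45.

Continuous marginals are generated through a Gaussian copula: each
covariate's Gaussian score is $b^\top\theta + s\,\varepsilon$ with
$b = \Sigma^{-1}c$, so its correlation with the facets equals the configured
$c$ exactly, then mapped through a normal or log-normal quantile map. The
family is chosen by percentile asymmetry — log-normal when
$P_{97.5} - \mathrm{median} > 1.5\,(\mathrm{median} - P_{2.5})$ — a
difference-based rule, because ratio-based asymmetry is identically 1 for
log-symmetric data and would misclassify clearly skewed lab values.
Binary covariates threshold the Gaussian score at the prevalence quantile,
so their indicator-scale correlations carry the standard biserial
attenuation factor $\phi(z_p)/\sqrt{p(1-p)}$; `truthCorrelations()` reports
the analysis-scale truth accordingly. AST/ALT and waist/hip are generated by
division from their components — consistent with preprocessing at the cost
of marginals that only approximately match the printed percentiles — and are
excluded from the analytic truth table (a ratio's correlation has no clean
closed form on the analysis scale).

What the generator does *not* emulate: missingness is MCAR (the real data's
missingness need not be); covariate–covariate dependence arises only through
the latent facets; item responses are generated from the very model family
that is fitted. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated under the model's assumptions at the
study's size and imbalance — not that the model is true of any real cohort.

## Problem sizes used by the test suite

Recovery experiments run at N = 2000 over three cohort seeds (the latent
correlation matrix recovers to ~0.05 mean absolute error, seed-averaged
slopes to rank correlation ~0.94, sizable covariate correlations to within
0.08); the oracle comparison fits N = 5000 on a unidimensional three-item
model against direct Gauss–Hermite marginal maximum likelihood; posterior
predictive calibration uses 20 replicate cohorts of 914 with 100 simulations
each; the bootstrap coverage study uses 100 replications at N = 400 with 100
bootstrap replicates on a three-covariate configuration. These sizes were
chosen so each property is measured with enough precision to be meaningful
while the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The per-dataset maximum likelihood estimates of weak residual
  cross-loadings are intrinsically noisy (their information is small and the
  facets are correlated); single-fit slope estimates should be read with the
  reported approximate standard errors, or averaged over chains.
* The conditional bootstrap omits item-parameter uncertainty.
* The shrinkage correction assumes the scoring model's $\Sigma$; its
  near-singular directions propagate visible variance into correlations for
  facets the items barely measure.
* Expected-score conditioning treats 0/1 indicators as jointly Gaussian with
  the facets (the usual full-random-effects convention); conditional means
  are exact for the two binary levels, but the approximation is a convention,
  not a claim about the indicator's distribution.
* One-step joint estimation of item parameters and covariate correlations
  (rather than the two-stage fit with shrinkage correction) is an
  acknowledged extension.
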