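Package: hepirt
Title: Multidimensional Item Response Models for Histological Liver Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint modelling of histological nonalcoholic fatty liver disease
    (NAFLD) biopsy scores and noninvasive biomarkers. Fits a multidimensional
    item response model (two-parameter logistic items for binary lesions,
    graded-response items for ordered scores) over five correlated latent
    disease facets by Metropolis-Hastings Robbins-Monro marginal maximum
    likelihood, scores subjects by expected a posteriori estimation, and
    relates the latent facets to mixed-type noninvasive covariates through a
    full random-effects style joint correlation model with EM handling of
    missing covariate cells. Includes expected-score profiles at covariate
    percentile extremes with a score-range coverage criterion, nonparametric
    bootstrap uncertainty, simulation-based posterior predictive diagnostics,
    deterministic preprocessing rules for dated biopsy and biomarker records,
    and a synthetic population generator emulating the statistical structure
    of an adult NAFLD cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, ggplot2
Suggests: testthat (>= 3.0.0), pracma, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
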