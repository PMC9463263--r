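Package: twinsleep
Title: Genetic and Environmental Architecture of Sleep-Quality Components in Twin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate biometric modelling of the seven Pittsburgh Sleep
    Quality Index (PSQI) components in classical twin designs. Implements
    full-information maximum likelihood for twin-pair data mixing continuous
    and ordinal (liability-threshold) phenotypes under ACE/ADE-family,
    common-pathway and independent-pathway covariance structures with the
    direct symmetric parameterization, derived etiological correlations
    (rA, rE) and bivariate decompositions of phenotypic correlations,
    likelihood-ratio and AIC model comparison, phenotypic confirmatory
    factor analysis with from-scratch fit indices (RMSEA, SRMR, CFI, TLI,
    BIC), PSQI component scoring, and a synthetic twin-cohort generator
    with known variance-component structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mvtnorm,
    jsonlite,
    stats,
    utils
Suggests:
    numDeriv,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
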