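# twinsleep

Multivariate biometric modelling of the seven Pittsburgh Sleep Quality
Index (PSQI) components — sleep latency, duration, habitual efficiency,
disturbances, subjective quality, medication use, and daytime
dysfunction — in classical twin designs.

## The scientific problem

Poor sleep runs in families, but a global "sleep quality" score hides
*why*. The classical twin design compares monozygotic (MZ) twins, who
share all segregating genetic variants, with dizygotic (DZ) twins, who
share half on average. For each trait the phenotypic variance splits into
additive-genetic (A), shared-environmental (C), possibly dominance (D),
and non-shared environmental (E) parts; for each *pair* of traits the
phenotypic correlation splits into a genetic and an environmental piece.

The core model: a twin pair's 2p-vector of trait scores is multivariate
normal with covariance

    Sigma_zyg = | A + C + E        kA·A + kC·C |
                | kA·A + kC·C      A + C + E   |

where the cross-twin coefficients are kA = 1 (MZ) or 1/2 (DZ) and
kC = 1 (and kD = 1 or 1/4 for dominance). Component matrices are free
symmetric matrices (the *direct symmetric* parameterization); only the
total covariance must be positive definite. Ordinal components are
handled by the liability-threshold model (standard-normal liability, free
increasing thresholds, unit total liability variance), and estimation is
full-information maximum likelihood over mixed continuous/ordinal,
possibly incomplete pairs.

Derived quantities follow the standard field notation: heritability
h² = A_ii / Sigma_ii, etiological correlations
rA = A_ij / sqrt(A_ii A_jj) (likewise rE), and the bivariate
decomposition

    rPH = rA·sqrt(h²_i h²_j) + rE·sqrt(e²_i e²_j),

whose first term divided by rPH is the genetic share ("bivariate
heritability") of the correlation between traits i and j.

The package also provides common- and independent-pathway (factor)
models with AIC/likelihood-ratio model selection, phenotypic confirmatory
factor analysis with from-scratch fit indices (RMSEA with CI, SRMR, CFI,
TLI, BIC), PSQI scoring utilities, and a synthetic twin-cohort generator
whose defaults reproduce the study conditions (five zygosity groups at
the published sizes, truncated-normal ages 43–71, right-skewed latency
and disturbances, 4-category ordinal components, incomplete pairs).

## Worked example

Simulate a cohort at the default (study-condition) settings, fit a
bivariate AE model to sleep duration and efficiency, and decompose their
phenotypic correlation:

```r
library(twinsleep)

cohort <- simulate_twins(twin_sim_config(seed = 42))
cohort
#> <twin_dataset> 1178 families, 7 traits (4 continuous, 3 ordinal)
#>   46.5% male, 32.2% MZ, age 54.3 (SD 6.2, range 43-71)

sp  <- psqi_specs()[match(c("duration", "efficiency"), psqi_specs()$trait), ]
sub <- twin_dataset(cohort$data[, c("family_id", "zygosity", "age",
                                    "sex1", "sex2", "duration_1",
                                    "duration_2", "efficiency_1",
                                    "efficiency_2")], sp)
fit <- fit_twin_model(build_multivariate("AE", specs = sp), sub, restarts = 1)
fit
#> <twin_fit> multivariate AE: -2LL = 10957.701, k = 8, AIC = 10973.701, converged
#>   1178 pairs used

round(standardize_components(fit$vc), 2)
#>              h2   e2
#> duration   0.30 0.70
#> efficiency 0.14 0.86

ec <- etiological_correlations(fit$vc)
round(c(rA = ec$rA[2, 1], rE = ec$rE[2, 1]), 2)
#>   rA   rE
#> 0.71 0.65

std <- standardize_components(fit$vc)
dec <- decompose_phenotypic_correlation(std[1, "h2"], std[2, "h2"],
                                        std[1, "e2"], std[2, "e2"],
                                        ec$rA[2, 1], ec$rE[2, 1])
sprintf("rPH = %.2f, genetic share = %.2f", dec$rPH, dec$propA)
#> [1] "rPH = 0.65, genetic share = 0.23"
```

`selection_driver()` fits the saturated, independent-pathway and
common-pathway models with nested warm starts and ranks them by AIC;
`run_pipeline()` chains the whole analysis (description, cross-twin
correlations, model selection, decomposition tables, pathway shares,
CFA) into a CSV/JSON report bundle.

## Documentation

The methods vignette (`vignettes/twin-architecture.Rmd`) describes the
model, the likelihood and its numerical treatment, the pathway and CFA
structures, the generator's realism choices, chosen problem sizes, and
limitations.
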