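---
title: "Genetic and environmental architecture of sleep-quality components: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic and environmental architecture of sleep-quality components: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsleep)
```

## The scientific problem

The Pittsburgh Sleep Quality Index (PSQI) summarizes self-reported sleep
in seven component scores — sleep latency, duration, habitual efficiency,
disturbances, subjective quality, sleeping-medication use, and daytime
dysfunction — each on a 0–3 scale, summed to a 0–21 global score (a global
score above 5 indicates poor sleep). Treating poor sleep as a single trait
hides structure: the components may differ in how much of their variation
is genetic, and pairs of components may correlate for genetic or for
environmental reasons.

The classical twin design separates these sources. Monozygotic (MZ) twins
share all their segregating genetic variants; dizygotic (DZ) twins share
half on average. If a trait's MZ cross-twin correlation exceeds its DZ
correlation, additive-genetic variance (A) is implicated; equal
correlations implicate shared environment (C); a DZ correlation below half
the MZ correlation suggests non-additive (dominance, D) variance. Variance
not shared within pairs is non-shared environment (E), which includes
measurement error.

`twinsleep` implements the full analysis chain for this design: component
scoring, a realistic synthetic cohort generator, full-information
maximum-likelihood (FIML) estimation of multivariate variance-component
models for mixed continuous/ordinal twin data, pathway (factor) models,
model selection, bivariate decomposition of phenotypic correlations, and
phenotypic confirmatory factor analysis (CFA).

## The model

### Expected twin covariance

For $p$ traits, let $A$, $C$ (or $D$), and $E$ be $p \times p$ symmetric
component covariance matrices. A twin pair's $2p$-vector of scores has
expected covariance

$$
\Sigma_{zyg} =
\begin{pmatrix}
A + C + E & \kappa_A A + \kappa_C C \\
\kappa_A A + \kappa_C C & A + C + E
\end{pmatrix},
$$

with cross-twin coefficients $\kappa_A = 1$, $\kappa_C = 1$ for MZ pairs
and $\kappa_A = \tfrac12$, $\kappa_C = 1$ for DZ pairs (for dominance,
$\kappa_D = 1$ and $\tfrac14$). The package uses the *direct symmetric*
parameterization: the component matrices are free symmetric matrices, and
only the total $\Sigma$ is required to be positive definite (enforced by a
penalty during optimization). Constraining each component to be positive
definite — as a Cholesky parameterization does — is known to bias variance
estimates at the boundary; the direct approach avoids that at the price of
admitting slightly indefinite component estimates in small samples.

### Mixed measurement: liability thresholds

Four components (latency, duration, efficiency, disturbances) are analyzed
as continuous scores after a $\log(x+1)$ transform of the right-skewed
latency and disturbances. The other three (quality, medication, daytime
dysfunction) are ordinal with four categories and are modeled by the
liability-threshold model: an unobserved standard-normal liability is cut
at three free, strictly increasing thresholds
($\tau_1 < \tau_2 < \tau_3$, parameterized as $\tau_1$ plus positive
increments). Identification fixes each ordinal trait's total liability
variance to one: the E diagonal entry is substituted as
$1 - A_{ii} - C_{ii}$ rather than estimated. Optional age and sex
covariates shift the means/liabilities linearly (age rescaled to $[0,1]$
over its observed range for numerical balance).

### The likelihood

Each pair contributes its own likelihood from whatever it has observed
(FIML). Splitting a pair's observed variables into the continuous part $y$
and the ordinal part with category rectangle
$[l, u]$:

$$
\ell = \log \phi(y;\, \mu_y, \Sigma_{yy}) +
\log \Pr\!\left(l \le Z \le u\right),
\qquad
Z \sim N\!\left(\mu_{z} + \Sigma_{zy}\Sigma_{yy}^{-1}(y - \mu_y),\;
\Sigma_{zz} - \Sigma_{zy}\Sigma_{yy}^{-1}\Sigma_{yz}\right),
$$

i.e. the exact conditional decomposition: a multivariate-normal density
for the continuous block and a multivariate-normal rectangle probability
for the liabilities conditioned on it. Pairs with a missing co-twin
marginalize to the singleton terms.

### Numerical choices

- **Rectangle probabilities** use `mvtnorm`: the deterministic Miwa
  algorithm (128 grid points) up to dimension four, and Genz–Bretz
  quasi–Monte Carlo (`abseps = 1e-6`, fixed internal seed, so results are
  reproducible) above that. Dimension one falls back to `pnorm`. Infinite
  bounds are clamped at $\pm 40$ conditional standard deviations, which is
  exact at double precision and avoids spurious warnings.
- **Optimizer**: `stats::nlminb` (PORT), relative tolerance $10^{-10}$,
  box constraints on increments and variances, moment-based starting
  values (double-entry within- and cross-twin covariances mapped to
  component starts, thresholds from observed category margins) plus
  optional jittered restarts.
- **Analytic gradient** for all-continuous data: with residual matrix $R$
  and per-group precision $P = \Sigma_g^{-1}$, the gradient of
  $-2\ell = \sum_g n_g(\log|\Sigma_g| + d\log 2\pi) + \mathrm{tr}(S_g P)$
  with respect to $\Sigma_g$ is $W_g = n_g P - P S_g P$, mapped onto the
  half-vectorized component matrices through the $\kappa$ coefficients.
  Mixed continuous/ordinal likelihoods use finite differences.
- **Vectorization**: continuous pairs are grouped by relatedness class and
  missingness pattern and evaluated in blocks; all-ordinal records with no
  covariates are pooled by identical response patterns.

### Pathway models and model selection

Two constrained alternatives to the saturated ("multivariate") component
structure are provided, both for the AE case:

- **Common pathway**: one or more latent phenotypes with unit variance and
  latent decomposition $a_L^2 + e_L^2 = 1$ transmit to the traits through
  loadings $\lambda$; traits keep specific A and E variances. With unit
  latent variance the latent heritability $a_L^2$ is directly readable. A
  three-factor variant with free latent A- and E-correlation matrices
  matches the published three-cluster structure.
- **Independent pathway**: common A and E factors load directly on each
  trait ($A = f_a f_a' + \mathrm{diag}(a_s)$, similarly for E), without an
  intervening latent phenotype.

These are nested in likelihood (common $\subseteq$ independent
$\subseteq$ saturated for the parameterizations used here), and the
selection driver exploits this: the common-pathway solution seeds the
independent-pathway fit, which seeds the saturated fit, guaranteeing the
$-2\mathrm{LL}$ ordering up to optimizer tolerance. Models are ranked by
AIC ($-2\mathrm{LL} + 2k$) with likelihood-ratio tests against the
saturated model.

### Bivariate decomposition

Standardizing the fitted components gives each trait's heritability
$h^2_i = A_{ii}/\Sigma_{ii}$, and etiological correlations
$r_{A,ij} = A_{ij}/\sqrt{A_{ii}A_{jj}}$ (likewise $r_E$). The phenotypic
correlation then splits as

$$
r_{PH} = \underbrace{r_A \sqrt{h^2_i h^2_j}}_{\text{genetic}} +
\underbrace{r_E \sqrt{e^2_i e^2_j}}_{\text{environmental}},
$$

and the genetic share ("bivariate heritability") is the first term divided
by $r_{PH}$. When the two contributions have opposite signs the share is
not a proportion; the package reports the signed contributions and flags
the pair instead.

### Confirmatory factor analysis

Phenotypic CFA uses one randomly selected complete twin per family
(pairs are dependent). The ML discrepancy
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}(\theta)) - \log|S| - p$
is minimized directly; $\chi^2 = (n-1)F$. Fit indices are computed from
first principles: RMSEA with a 90% interval by inverting the noncentral
chi-square distribution, CFI and TLI against the independence baseline,
SRMR as the root-mean-square residual correlation, and
$\mathrm{BIC} = \chi^2 + k\log n$ for ranking. The three candidate
structures are the one-factor model, the one-factor model with residual
duration–efficiency and latency–efficiency covariances, and a
three-factor clustering (sleep efficiency, perceived quality, daily
disturbances) with free factor correlations.

## The synthetic cohort generator

Because the original cohort is restricted, the package ships a generator
whose defaults are the study conditions; its ground truth is the published
estimate set itself (heritabilities and etiological correlations assembled
into component matrices, verified positive definite). Realism choices:

- Five zygosity groups (MZ and DZ by sex plus opposite-sex DZ) at the
  published group sizes, including the published complete/incomplete
  split; incomplete pairs have the second twin missing.
- Ages from a truncated normal (mean 53.7, SD 7.3, range 43–71);
  opposite-sex pairs have randomized birth order.
- Liabilities for a pair are drawn from the exact $2p$-dimensional twin
  covariance via its Cholesky factor.
- Latency and disturbances are exponentiated (then rescaled by the
  lognormal SD) to produce the right skew that motivates the
  $\log(x+1)$ transform; ordinal components are cut at thresholds chosen
  to match typical observed category frequencies.

## Problem sizes

The test-suite experiment sizes are the package's own desk-scale choices:
single fits of the seven-trait continuous model at the published group
sizes take about a second with the analytic gradient; the recovery study
uses 20 replicates; the model-selection study uses 25 replicates at 30% of
the published group sizes (a three-model selection run takes roughly 15–20
seconds there); the common-pathway recovery uses 5,000 pairs.

## Limitations

- Pathway builders cover the AE case (the one selected in the motivating
  analysis); ACE/ADE pathway variants are not implemented.
- Mixed continuous/ordinal fits use finite-difference gradients and
  per-pair likelihoods; a full seven-trait ordinal-included fit is much
  slower than the continuous path and is not exercised at scale in the
  tests.
- Profile-likelihood intervals re-optimize under a quadratic penalty;
  very flat or boundary-adjacent profiles are flagged rather than refined.
- The generator simulates liabilities from multivariate normal components;
  it does not model genotype–environment interaction, assortative mating,
  or sex-limitation of genetic effects.
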