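---
title: "Twin variance-component models for epigenetic age metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin variance-component models for epigenetic age metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The scientific problem

Epigenetic clocks -- DNA-methylation-based estimators of biological age or
of the pace of aging (GrimAge, PhenoAge, DunedinPACE and their
principal-component variants) -- differ between people of the same
chronological age. Twin designs ask how much of that variation is genetic
and how much environmental, and, when the same people are measured twice a
few years apart, whether the *same* genes and environments act at both
times. `twinace` implements the two workhorse models of that literature:

1. the **univariate ACE/ADE variance decomposition** with saturated-model
   references, likelihood-ratio/AIC model selection and profile-likelihood
   confidence intervals, and
2. the **longitudinal bivariate Cholesky model** for a phenotype measured
   at two waves, with the derived cross-time genetic and environmental
   correlations.

Because cohort data of this kind are typically restricted, the package
ships a synthetic twin-pair generator that draws from the exact
model-implied moments, so every stage of the pipeline is testable and
parameter-recovery experiments can use published point estimates as
generating truths.

## The univariate model

A phenotype measured on both members of a twin pair is decomposed into
latent standard-normal components: additive genetic (A), common (shared)
environment (C) *or* dominance genetic (D), and unique environment (E),
with path coefficients $a, c, d, e$. The variance components are the
squared paths. MZ pairs share all additive and dominance effects; DZ pairs
share on average half the additive and a quarter of the dominance effects;
C is shared fully; E (which also absorbs measurement error) is unshared.
The implied within-pair covariance matrix is therefore

$$\Sigma_{MZ} = \begin{pmatrix} V & a^2+c^2+d^2 \\ a^2+c^2+d^2 & V \end{pmatrix},
  \qquad
  \Sigma_{DZ} = \begin{pmatrix} V & \tfrac12 a^2+c^2+\tfrac14 d^2 \\
  \tfrac12 a^2+c^2+\tfrac14 d^2 & V \end{pmatrix},$$

with $V = a^2+c^2+d^2+e^2$. C and D are not jointly identifiable from
twins reared together, so the families are ACE and ADE with sub-models AE,
CE and E. Heritability is $h^2 = a^2/V$ in the ACE family and
$(a^2+d^2)/V$ in the ADE family.

Covariates (sex; sex and chronological age for pace-of-aging metrics)
enter the *means* of every model, including the saturated one, with
coefficients shared across zygosity and twin order. Age-acceleration
metrics are residualized on cell composition and chronological age before
modelling (below), which is why their twin models need only a sex
adjustment.

### Likelihood and missing data

Each pair contributes the bivariate-normal density of its observed values
(full-information maximum likelihood): a pair with a missing co-twin
contributes the marginal univariate density. Pairs are grouped by zygosity
and missingness pattern so one Cholesky factorization serves the whole
group. A non-positive-definite implied covariance returns a large finite
penalty instead of an exception, so gradient-based optimizers retreat.

### Estimation, in detail

* **Parameterization.** Paths are optimized unconstrained and reported as
  absolute values; the sign of a path is not identified because only its
  square enters the covariance.
* **Multi-start.** BFGS from a moments-based start (Falconer-style
  estimates computed from the double-entered MZ/DZ correlations of
  covariate-adjusted residuals) plus four jittered restarts drawn under a
  fixed internal seed, keeping the best objective. The jitter seed is part
  of the algorithm, so fits are deterministic.
* **Convergence.** The optimizer tolerance is `reltol = 1e-12`; after the
  fit the finite-difference gradient norm is recorded and the fit is
  flagged (never silently accepted) if the optimizer code is nonzero or
  the gradient norm exceeds `1e-5` relative to the deviance.
* **Degenerate inputs.** A zero-variance phenotype is an error; `e = 0` is
  outside the admissible region (E contains measurement error) and is
  excluded by the positive-definiteness penalty.

### Model selection

The saturated model (per-zygosity means and covariances, unconstrained
across twin order, shared covariate coefficients) bounds every constrained
model. `select_model()` fits saturated, ACE and ADE, keeps the full family
with the lower AIC, then fits that family's sub-models. A candidate is
admissible when its likelihood-ratio test against the full family model
and against the saturated model are both non-significant at $\alpha =
0.05$; among admissible candidates the lowest AIC wins, ties going to the
model with fewest parameters. When nothing is admissible the full family
model is kept and flagged. The LRT uses the naive $\chi^2$ reference even
though variance components sit on the boundary under the null -- the
common default of twin-SEM software; it makes dropping a component
slightly too hard, i.e. selection is conservative toward the richer model.

### Confidence intervals

Intervals for standardized quantities ($h^2$, component shares) are
profile-likelihood intervals: the bound is where the profiled deviance
rises by $\chi^2_1(0.95) = 3.841$, found by root-finding over a
reparameterization that fixes the target share and re-optimizes total
variance, the mixing of the remaining shares, and the means. Bounds are
clipped to $[0, 1]$; when profiling fails numerically a delta-method
interval is substituted and flagged in `ci_method`. Profile intervals were
chosen because shares near 0 or 1 make Wald intervals misleading; the
delta fallback exists so a fit never lacks an interval entirely.

## The longitudinal bivariate Cholesky model

With the same metric at baseline and follow-up, each component K gets a
lower-triangular path matrix
$\bigl(\begin{smallmatrix} k_{11} & 0 \\ k_{21} & k_{22} \end{smallmatrix}\bigr)$:
$k_{11}^2$ is K's baseline variance, $k_{21}^2$ the follow-up variance
transmitted from baseline, $k_{22}^2$ the variance new at follow-up, and
$k_{11}k_{21}$ the cross-wave covariance carried by K. The 4-variate pair
covariance has within-twin block $\sum_K L_K L_K^\top$ and cross-twin
block $\rho_A A + C + \rho_D D$ with $(\rho_A, \rho_D)$ = (1, 1) for MZ
and (0.5, 0.25) for DZ. Heritability per wave is
$h^2_1 = a_{11}^2 / V_1$ and $h^2_2 = (a_{21}^2+a_{22}^2)/V_2$.

From the fitted paths, `derive_bivariate_statistics()` computes the
cross-time component correlations
$R_a = a_{11}a_{21}\big/\sqrt{a_{11}^2\,(a_{21}^2+a_{22}^2)}$ (defined as
0 when either wave's component variance vanishes, and flagged), the
phenotypic stability $R_{ph}$, its decomposition $P_a/P_c/P_e$ (component
cross-covariance over total cross-covariance), and the model-implied
cross-twin cross-trait (CTCT) correlations. On standardized parameters
these satisfy the identity
$R_{ph} = R_a\sqrt{h^2_1 h^2_2} + R_c\sqrt{c^2_1 c^2_2} +
R_e\sqrt{e^2_1 e^2_2}$, which the test suite checks to $10^{-10}$.

The *observed* CTCT correlation is the double-entered Pearson correlation
between one twin's baseline and the co-twin's follow-up value, with a
Fisher-z interval using the number of pairs (not entries) as the effective
sample size -- deliberately conservative. Published tables do not say
whether such values come from raw double entry or from a saturated model,
so the package reports both the observed and the model-implied versions.
For the same reason the within-pair correlations in `twin_summary()` are
double-entered: plain Pearson on (twin 1, twin 2) would depend on the
arbitrary twin order, and all statistics in this package are
order-invariant by construction (and by test).

Intervals for $R_a$/$R_c$/$R_e$ are profile-likelihood intervals over a
reparameterization fixing the correlation ($k_{21} = R\sqrt{w}$,
$k_{22} = \sqrt{w(1-R^2)}$ with $w$ the wave-2 component variance),
clipped to $[-1, 1]$ -- which is how published bounds like "1.00" arise.

### Inverting printed summaries

`cholesky_from_summary()` turns a published row -- per-wave
heritabilities, $R_a$, $R_e$, optionally C shares and $R_c$ -- into
standardized paths ($V_1 = V_2 = 1$):
$a_{11} = \sqrt{h^2_1}$, $a_{21} = R_a\sqrt{h^2_2}$,
$a_{22} = \sqrt{h^2_2(1-R_a^2)}$, analogously for C and E, the E share
being the remainder $1 - h^2 - c^2$. `derive_bivariate_statistics()` on
the result reproduces the inputs exactly, and the constructor is the
bridge from printed tables to generating truths for recovery experiments.

## Preprocessing

`compute_age_acceleration()` forms AA as the OLS residual of a clock on
its predictors (typically six estimated blood-cell proportions plus
chronological age). Rank deficiency is an error naming the collinear
columns rather than a silent drop. Individuals missing any predictor get a
missing AA and are excluded from the fit. `standardize()` z-scores a
metric with the sample SD ($n-1$); metrics are standardized before
modelling so components are comparable across clocks. Whether
residualization should be done once on the pooled sample or separately
within the cross-sectional and longitudinal subsets is not decidable from
published descriptions; the function operates on whatever vector it is
given, so both policies are available, and the pooled form is what the
examples use.

## The synthetic generator

`simulate_univariate_twins()` / `simulate_bivariate_twins()` draw each
pair directly from the model-implied multivariate normal for its zygosity
-- exactly equivalent in distribution to simulating latent A/C/D/E draws
and much easier to verify against closed-form moments; a latent-draw mode
(`method = "latent"`) exists for didactic traces and is tested to agree
distributionally. Covariates emulate the same-sex adult twin registry
design: sex ~ Bernoulli(0.5 by default) and age ~ Uniform(30, 70) years
are shared within a pair, with a 5-year gap between waves; covariate
effects default to zero so recovery targets stay clean. Generation is
bit-reproducible given the seed and leaves the caller's RNG state
untouched.

What the generator does *not* emulate: non-normal phenotypes, array batch
effects, selection into follow-up, zygosity misclassification, and
age-dependent variance components. Passing recovery tests therefore shows
that the estimation machinery is correct under the model's own
assumptions, not that real cohort estimates are unbiased.

## Problem sizes and numerical checks

Recovery experiments use 4000 MZ + 4000 DZ pairs: large enough that
Monte-Carlo error (roughly 0.01--0.02 on shares and correlations) is well
inside reporting precision, small enough that a simulation-plus-fit cycle
takes seconds. Bias properties are checked over 20 replicates at 2000 +
2000 pairs (mean $\hat h^2$ bias below 0.01; bivariate $R_a$, $R_e$ and
per-wave $h^2$ bias below 0.02). Likelihood correctness is checked against
explicit inverse/determinant oracles on fixtures of at most 30 pairs, and
the ML optimum against a dense grid search at 0.01 resolution.

## Known limitations

* No sex-limitation or gene-environment-interaction models; same-sex
  pairs only (opposite-sex pairs are rejected at validation).
* No DE model (D without A is not meaningful in this design), and no
  three-wave or cross-trait extensions of the Cholesky model.
* The boundary-naive LRT reference and the pair-count CTCT interval are
  both conservative conventions, documented rather than corrected.
* Unstandardized component tables from published univariate analyses can
  sum to less than 1 even for standardized phenotypes (components are not
  re-normalized after sub-model selection); this package therefore reports
  both raw squared paths and standardized shares.
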