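---
title: "Fractional polynomial modelling of the BMI-mortality curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional polynomial modelling of the BMI-mortality curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The relationship between body mass index (BMI, kg/m²) and short-horizon
all-cause mortality is nonlinear and asymmetric: mortality is elevated both
at low BMI (where chronically ill lean subjects accumulate) and, steeply,
at high BMI. Two conventional modelling strategies distort this curve in
opposite ways. Categorizing BMI (WHO classes) assumes constant risk within
wide, heterogeneous classes and truncates the steep right tail; a
linear-plus-quadratic term forces a symmetric parabola on the logit scale.
`fpmort` implements the data-driven alternative: **multivariable fractional
polynomials (MFP)**, which lets a closed family of power transformations
choose the curve's shape, stratified by sex and adjusted for age and
smoking history.

## The model

For subject $i$, the 5-year death indicator is modelled as

$$\operatorname{logit}(\pi_i) = \beta_0 + \beta_1\,\tilde b_i^{\,p_1} +
\beta_2\,\tilde b_i^{\,p_2} + \beta_3\, \tilde a_i^{\,q_1} +
\beta_4\,\text{SMOKE}_i,$$

where $\tilde b = \text{BMI}/10$ and $\tilde a = \text{age}/10$ are scaled
covariates and the powers are drawn from the canonical set
$S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, with $0$ denoting $\ln$. A
repeated power $(p, p)$ denotes the pair $\{x^p,\ x^p \ln x\}$ (so a
degree-2 fractional polynomial spans 36 candidate shapes: 28 distinct
pairs plus 8 repeated ones). Survey weights enter as pseudo-likelihood
frequency weights; fitting is by iteratively reweighted least squares
(`wlogit()`), with the model-based covariance (inverse weighted
information) as the default and a design-based sandwich covariance
available via `vcov(fit, type = "sandwich")`.

### Function selection: the closed test

For each continuous covariate, `mfp_logit()` applies the closed test
procedure:

1. best FP2 vs. the null model, $\chi^2_4$ — is the covariate needed at all?
2. best FP2 vs. the linear model, $\chi^2_3$ — is any transformation needed?
3. best FP2 vs. best FP1, $\chi^2_2$ — is second degree needed?

Testing stops at the first non-significant step, which controls the
familywise error of the selection by construction. With several covariates
the procedure cycles (most significant first, by the Wald test of a
preliminary all-linear fit) until a full cycle changes nothing, with a cap
of 5 cycles. Age is restricted to first degree — flexibility beyond one
power for the adjuster invites collinearity with the exposure — and binary
covariates such as smoking are kept in the model throughout.

Candidates whose fit fails to converge are skipped with a warning. Ties in
candidate deviance (within $10^{-8}$) resolve to the earliest candidate in
ascending lexicographic power order, for reproducibility.

### Scaling and centering

Each transformed column is centered at the transform of the covariate's
unweighted sample mean, $c_j = h_j(\bar x / \text{scale})$. Centering moves
only the intercept — non-intercept coefficients and all deviances are
invariant — and makes the intercept the linear predictor of a
mean-covariate subject. This convention, with BMI and age both scaled by
10, is the one under which the package's closed-form optima reproduce the
published age-specific female optima from the published coefficient table.
Weights are rescaled to unit mean inside `mfp_logit()`: only relative
weights matter for point estimation, and the rescaling keeps deviances on
the sample-size scale so that deviance-difference $\chi^2$ tests stay
calibrated.

### Interactions (MFPI) and their verification

With main-effect forms frozen, `mfpi()` represents each candidate
interaction by the products of the two terms' design columns (two added
columns for age × an FP2 exposure, one for age × smoking) and tests it by
a deviance difference on that many degrees of freedom, assembling the
final model by forward selection at the same $\alpha$. An interaction of
age with a binary smoking indicator is reported as stratum-specific age
slopes in `coef_report()`. `logit_lowess()` provides the graphical
cross-check: binned, continuity-corrected empirical logits
($\hat p = (d + 0.5)/(n + 1)$) smoothed by Lowess (span 0.6, tricube
weights, one robustness iteration — conventional values, configurable);
diverging smoothed slopes across strata corroborate an interaction.

### The optimum (nadir) and its uncertainty

Setting the fitted curve's derivative to zero gives closed forms per FP
family; for instance the repeated-power family $b_1 x^{p} + b_2 x^p \ln x$
has its stationary point at $\ln x^\ast = -(p b_1 + b_2)/(p b_2)$, and the
linear-quadratic special case reduces to $-\beta_1 / (2\beta_2)$. When the
exposure interacts with age, the interaction is folded into effective
coefficients $b_1' = b_1 + c\,g(\text{age})$ before solving, which makes
the optimum a function of age. The second derivative is checked to confirm
a minimum; if the closed form has no interior minimum the package falls
back to a grid search and flags the estimate as a boundary solution
without a confidence interval (the delta method is invalid there).

Confidence intervals propagate the full coefficient covariance through the
closed form: $\operatorname{se} = \sqrt{g^\top \Sigma g}$ with the
analytic gradient $g$, cross-checked at every call against central
differences (relative step $10^{-6}$; disagreement beyond $10^{-4}$
relative is an error rather than a warning).

## The synthetic cohort generator

`generate_cohort()` emulates the kind of pooled national interview survey
the method was designed for, so the whole pipeline is testable without
restricted linked mortality data:

* **Age**: truncated normal on [18, 99], sd 17.5, locations calibrated so
  the stratum means are 45.49 (men) and 47.13 (women).
* **Smoking**: Bernoulli, prevalence 54.93% (men) / 40.47% (women).
* **BMI**: shifted lognormal per sex; parameters were fit once by least
  squares so that the WHO-category prevalences among included subjects
  (BMI ≥ 18.5) match the published stratum prevalences to within a third
  of a percentage point, and are frozen in the configuration. About 8% of
  raw female draws fall below 18.5 and are removed by `apply_inclusion()`.
* **Weights**: gamma with mean 1 and cv 0.25, divided by the 4 pooled
  survey years. The dispersion is deliberately mild: the analysis treats
  weights as frequency-type weights in $\chi^2$ tests and model-based
  covariances, which is well calibrated only when the weight variance is
  modest (independent random weights inflate both by $1 + \mathrm{cv}^2$).
  Emulating full multistage design effects is out of scope.
* **Outcome**: Bernoulli 5-year death from the true FP logit, using the
  published sex-specific coefficient sets under this package's
  scaling/centering conventions; death times uniform on (0, horizon], with
  an optional hook that injects excess first-year deaths below a BMI
  threshold to emulate reverse causation for the early-death sensitivity
  analysis.

Two features of real data the generator does **not** emulate: cluster
sampling (weights are the only design feature carried) and the original
survey's intercept calibration — the published intercept absorbs that
study's own unpublished centering constants, so the generator's marginal
5-year death rates come out near 4.8% (men) and 4.0% (women) rather than
the published 6.37%/5.55%. Absolute predicted probabilities from refits of
real data are therefore not desk-reproducible, while every *relative* and
*structural* quantity (curve shapes, optima, deviance orderings, coverage)
is; passing tests should be read accordingly.

## Numerical choices

* IRLS convergence: relative deviance change below $10^{-10}$ or 100
  iterations; probabilities clipped to $[10^{-12}, 1 - 10^{-12}]$ so that
  quasi-separated fits run to the cap and are *flagged* non-converged
  (fitted probabilities pinned at the clip boundary are reported as a
  separation diagnostic) instead of erroring.
* Rank-deficient designs are an error naming the collinear columns;
  collinear interaction candidates are skipped with a warning.
* Deviance-difference statistics are clamped at zero; a negative
  difference beyond $10^{-6}$ (non-nested models or a failed fit) is an
  error.
* Non-nested comparisons (FP vs. categorical; FP vs. linear-quadratic at
  equal parameter count) report the deviance gap and curve divergence but
  no p-value unless `chisq_compat = TRUE` explicitly requests the
  conventional $\chi^2$ referral.
* The narrow-bin comparator uses 30 bins (unit bins to BMI 40, 2-unit bins
  to 54, one open bin above) with the bin containing BMI 22 as reference;
  the reference only shifts the displayed curve's intercept. The first bin
  is effectively [18.5, 19) because inclusion starts at 18.5.

## Problem sizes used by the test suite

Simulation-backed properties run at sizes chosen to give comfortable Monte
Carlo resolution: type-I error of the closed test on 200 null cohorts of
n = 20,000; power/recovery and qualitative curve shapes on n = 50,000
(men) and n = 65,000 (women) across 5 and 3 seeded replicates; delta-CI
coverage on 500 replicates of n = 50,000; Wald-interval coverage of the
IRLS engine on 500 replicates of n = 4,000. Exact FP-power identification
is *not* almost-sure at these sizes — adjacent families such as
$(-2, -0.5)$ sit within a few deviance units of $(-2, -2)$ — so recovery
and robustness claims are majority-over-seeds statements, matching how the
method behaves on real data.

## Known limitations

* The logistic 5-year-death formulation discards exact death times (a
  deliberate match to the method being reproduced); the time axis enters
  only through the inclusion horizon and the early-death sensitivity
  filter.
* Model-based standard errors ignore design effects beyond scalar
  weights; the sandwich option is available but is not what the default
  reports use.
* The closed test's df-4 referral for a best-of-36 statistic is the
  standard approximation — slightly conservative in our own type-I
  measurements, as expected.
* Degree-3 fractional polynomials, spline alternatives, and hazard-scale
  optima are out of scope.

## A worked run

```{r, eval = FALSE}
library(fpmort)
coh <- rbind(generate_cohort(cohort_config("male", n = 50000, seed = 1)),
             generate_cohort(cohort_config("female", n = 65000, seed = 2)))
study <- run_study(coh, out_dir = "study-out")
study
```

The bundle contains the per-sex descriptives, coefficient tables (with
stratum-specific age slopes when an age-by-smoking interaction is
present), the optimum-BMI table with delta-method intervals, curve CSVs
for plotting, the full selection trace as JSON, and a run log.
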