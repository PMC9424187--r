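---
title: "Estimating disability-free life expectancy with multistate life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disability-free life expectancy with multistate life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthspan)
```

## The model

`healthspan` implements a three-state illness–death model with recovery for
disability in older adults: non-disabled (nd), disabled (dis), and dead.
Four transitions are possible — incidence (nd → dis), recovery (dis → nd),
and death from either living state — plus retention in each living state.
Time advances in elementary steps of one month, and the probability of each
transition over one step is a multinomial-logit function of current age
$x$ (in years):

$$
p_{ij}(x) \;=\; \frac{\exp(a_{ij} + b_{ij}x)}
                     {1 + \sum_{k \ne i} \exp(a_{ik} + b_{ik}x)},
\qquad
p_{ii}(x) \;=\; \frac{1}{1 + \sum_{k \ne i} \exp(a_{ik} + b_{ik}x)},
$$

for transient origin $i \in \{\mathrm{nd}, \mathrm{dis}\}$; the dead state
is absorbing.  The eight parameters (an intercept and an age slope per
transition) are held in a `transition_params` object; an intercept of −50
is the sentinel for a structurally absent transition.  Age enters each
logit linearly — the standard choice for this class of panel estimators;
quadratic age is out of scope.

## The interval-censored likelihood

Disability state is observed only at annual waves, while deaths are dated
to the month through registry linkage and emigration right-censors
follow-up.  The state path between waves is never imputed.  Instead, the
likelihood of a pair of consecutive observations $(s_t, s_{t+g})$, $g$
months apart, is the $(s_t, s_{t+g})$ entry of the product of the $g$
intervening monthly step matrices, which integrates over all unobserved
intermediate paths.  A death in month $m$ after a last wave in state $s$
at time $t$ contributes the probability of reaching either living state
$l$ by month $m-1$ times $p_{l,\mathrm{dead}}$ of the final month.
Emigration contributes nothing beyond the last observed wave; the
estimator therefore assumes emigration is non-informative (independent of
health state), which is also how the synthetic generator draws it.

Two deliberate consequences of this design:

* Death dates are treated as known to the month.  If a source only
  reports an interval, the death is attributed to its recorded month — a
  documented approximation; the alternative (wave-interval censoring of
  deaths) is not implemented.
* Disability-certification events carry the month of onset in the data
  model, but the likelihood uses wave states plus dated deaths only, so
  certification-date information sharpens nothing beyond the wave grid.

Maximisation (`fit_transitions()`) is quasi-Newton (BFGS) from a
documented initial point (intercepts −4, slopes 0), with convergence
declared at a relative log-likelihood change below 1e-8 and at most 500
iterations.  Internally the optimiser works with age centred at 80 years
purely for conditioning; the transform is linear, so estimates and
covariance are reported exactly on the original scale.  The covariance is
the inverse of the numerically differentiated observed information.
Groups (and strata) are fitted as separate models — stratified maximum
likelihood — matching the group-specific design; the model carries no
covariates, and stratification is the only confounding control.

A transition with fewer directly observed occurrences than `min_support`
(default 1 in `fit_transitions()`, 10 in the pipeline's small-cell
policy) is dropped to the −50 sentinel.  In the exported likelihood the
sentinel is a structural zero, so an observed path that requires an
absent transition correctly yields $-\infty$.  Inside the fitter the
sentinel instead keeps its literal value ($e^{-50}$ per step), so the few
observed occurrences of a dropped sparse transition make the fit
improbable rather than impossible — otherwise a cell with, say, five
deaths from the disabled state and `min_support = 10` would have no
admissible likelihood at all.

## From transition probabilities to expectancies

`occupancy_curve()` accumulates $M_t = \prod_{u<t} P(x_0 + u h)$, whose
first row gives the state distribution at age $x_0 + t h$ of a person
non-disabled at the index age $x_0$.  Expected years in each living state
integrate the occupancy with trapezoid weights (half weight at the index
and closure ages, the usual half-interval life-table convention):

$$
e_j(x_0) = h \sum_{t=0}^{T} w_t \, [M_t]_{\mathrm{nd},\, j},
\qquad w_0 = w_T = \tfrac12 .
$$

DFLE is $e_{\mathrm{nd}}$, duration with disability $e_{\mathrm{dis}}$,
and total life expectancy their sum — exactly, since all three use the
same quadrature.  Design choices:

* **Conditioning.** The default conditions on being non-disabled at the
  index age, because the emulated design excludes prevalent disability at
  entry.  `prevalence_weighted` mixes the two living-state rows by a
  supplied initial distribution for population-style expectancies.
* **Closure age** $x_{\max} = 115$: beyond any data support, survival is
  negligible under realistic parameters; a warning fires when survival at
  closure exceeds 1e-4, since truncation would then bite.  Raising the
  closure from 110 to 115 moves the default results by well under 0.01
  years.
* **Step length.** Parameters are native to the monthly step.  Other
  step lengths rescale the off-diagonal probabilities proportionally (a
  first-order intensity approximation); halving the step changes DFLE by
  less than 0.02 years on the default parameter grid.

Uncertainty is propagated by a parametric bootstrap
(`bootstrap_ci()`): draw parameter vectors from the multivariate normal
with the MLE as mean and the inverse observed information as covariance,
recompute the expectancies per draw, and take percentile intervals.
Percentile rather than normal-theory intervals are used because the
expectancies are nonlinear functionals of the parameters.  A
non-positive-semi-definite covariance is repaired by eigenvalue clipping
when the repair is small, and refused otherwise.

`microsim_expectancy()` is an intentionally independent oracle: it
simulates individual trajectories from the same step matrices and
averages time in state with the same trapezoid convention.  The matrix
and Monte-Carlo estimators target the identical integral, so the test
suite requires agreement within three Monte-Carlo standard errors across
a grid of parameter sets, including ones with strong recovery.

## What the synthetic cohort emulates

`simulation_config()` describes the full generative model; its defaults
emulate an 11-year annual-wave disability follow-up of Japanese
community-dwelling adults aged 65 and over:

* an all-non-disabled entry cohort, four social-participation groups with
  published covariate marginals (group sizes, age means/SDs, % male,
  smoking, walking, depression, BMI, disease history);
* monthly latent transitions under true parameters calibrated with
  `calibrate_intercepts()` so the implied DFLE at 65 runs from 17.8 to
  22.7 years across groups in men and 21.8 to 26.7 in women — a roughly
  five-year gradient — with durations with disability near 1 year (men)
  and 4–4.7 years (women).  Age slopes are Gompertz-like: 0.100–0.105
  logit/year for men and 0.130–0.140 for women (the steeper female slopes
  keep survival at the closure age negligible while matching the large
  female disability durations); the disabled-mortality excess is fixed at
  +0.8 (men) and +0.3 (women) logit units and recovery at intercept −4.5;
* annual waves over 132 months, exact death months, first-entry
  disability-certification events, and independent monthly emigration
  with default probability 2.6e-4, calibrated against the model-implied
  person-months at risk so that about 3.1% of the cohort emigrates.

Depression-screen items are drawn independently with a per-item
probability solved so that the binomial score reaches the published
per-group depression prevalence; item directions follow the instrument
exactly, including the counterintuitive ones (a "yes" to "Is your life
pretty full?" scores toward depression — implemented as printed and
flagged here).  Baseline ages are truncated normals on [65, 100] rounded
to the month; note that truncation lifts the realised mean above the
nominal value (the no-activity group draws from nominal 75.1 but realises
about 75.9), and the tests compare against the truncated closed form.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: covariates other than sex, age and group
do not affect the true hazards (an optional `covariate_hazard_hook`
exists precisely so tests can inject confounding); there is no
certification lag between disability onset and its recorded month, no
household or geographic clustering, no detection bias in who applies for
certification, and emigration is exactly non-informative.

## Problem sizes and numerical checks

The test suite validates the estimation chain at sizes chosen to balance
statistical resolution against runtime: exhaustive path enumeration
against the likelihood for all start/end states over one to three steps
(agreement to 1e-12); the geometric closed form for a constant-hazard
chain (1e-10); microsimulation agreement at $N = 10^5$ per parameter set;
Wald coverage of all eight parameters over 200 replicate cohorts of
n = 10,000 (coverage required in 90–99%); bootstrap DFLE coverage over
50 cohorts (88–100%); and recovery of the five-year DFLE gradient with
correct group ordering at n = 20,000 per sex.

## Limitations

The transition model cannot adjust for covariates; stratified refits are
the only confounding control, exactly as in the emulated design.  The
monthly step is an assumption mirrored in both generator and likelihood;
data observed on a coarser event grid would need the `step` attribute
revisited.  Bootstrap intervals inherit the asymptotic-normality
approximation of the MLE, which can be poor in cells with very few
transitions — such cells are flagged by the pipeline rather than
silently smoothed.
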