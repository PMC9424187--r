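# healthspan

Multistate life table (MSLT) estimation of disability-free life expectancy
from interval-censored panel data.

## The problem

Cohort studies of older adults often observe disability status only at
annual waves, while deaths are dated to the month through registry linkage
and emigration censors follow-up.  `healthspan` estimates, from such
panels, the age-specific transition probabilities of a three-state
illness–death model with recovery — non-disabled (nd), disabled (dis),
dead — and converts them into the quantities health-expectancy studies
report at an index age (65 by default):

- **DFLE** — disability-free life expectancy, the expected years lived
  non-disabled;
- **duration with disability** — expected years lived disabled;
- **TLE** — total life expectancy, their sum;

each with parametric-bootstrap 95% confidence intervals, per sex and
exposure group (here, the number of social-participation activities, 0–3)
and within strata of smoking, BMI, walking time, depression and
NCD-risk count.

## The model

Over one elementary step (one month) at age `x`, transition probabilities
from a transient state `i` are multinomial-logit in age:

    p_ij(x) = exp(a_ij + b_ij x) / (1 + Σ_k exp(a_ik + b_ik x)),   j ≠ i
    p_ii(x) = 1 / (1 + Σ_k exp(a_ik + b_ik x))

with the dead state absorbing.  A pair of waves `g` months apart
contributes the `(s_t, s_{t+g})` entry of the product of the `g` monthly
step matrices (interval censoring is integrated out, never imputed); a
death dated to month `m` contributes the probability of reaching a living
state by `m − 1` times that state's death probability in the final month.
Maximum likelihood per sex × group; occupancy `M_t = Π P(x₀ + u·h)` is
integrated with trapezoid weights to give the expectancies.  An
independent microsimulation estimator of the same integrals cross-checks
the life-table math, and a synthetic cohort generator with a fully
specified generative model makes the whole chain testable end to end.
See the vignette (`vignettes/multistate-dfle.Rmd`) for the full account.

## Worked example

```r
library(healthspan)

cfg <- simulation_config(n = 5000, seed = 42)  # synthetic 11-year cohort
ds  <- generate_dataset(cfg)
fit <- fit_transitions(ds, sex = "male", group = 0)
bootstrap_ci(fit, B = 1000, seed = 42)
```

which prints

```
life table at age 65 (closure 115, step 0.08333 yr, nd_at_x0):
  DFLE:                      18.47 yr (95% CI 17.46-19.42)
  duration with disability:   1.34 yr (95% CI 1.01-1.72)
  TLE:                       19.81 yr (95% CI 18.83-20.78)
```

i.e. the 744 men with no social activities in this simulated cohort have
an estimated 18.5 disability-free years remaining at 65 (the generator's
true value for this group is 17.8), 1.3 of their remaining 19.8 expected
years being lived with disability.  The full study replica — exclusion
cascade, baseline/outcome tables, DFLE by group and by per-activity
frequency, and five stratified analyses — runs via

```r
report <- run_full_study(analysis_config(input = cfg, B = 1000, seed = 1))
render_report(report, "results/")
```

A thin CLI over the same functions is installed at
`inst/scripts/healthspan` (subcommands `synth`, `fit`, `expect`, `run`).

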