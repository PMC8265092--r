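---
title: "Methods: simulating and quantifying the consequences of ignoring clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying the consequences of ignoring clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question

Epidemiological and clinical data frequently arrive in clusters — study
centres, schools, general practices — so that the outcome varies less
within clusters than between them even after the explanatory variable is
accounted for. Analysts nevertheless often fit a cluster-unadjusted
ordinary least squares (OLS) regression. `clusterbias` provides the
machinery to quantify, by Monte-Carlo simulation, what that shortcut does
to point estimates, standard errors, 95% confidence-interval coverage and
Type I error, and how the damage depends on (a) how clustered the
*outcome* is and (b) how clustered the *explanatory variable* is.

## Generative model

Data are simulated from the random-intercept (RI) model

$$ y_{ij} = \beta_0 + \beta_1 x_{ij} + u_j + e_{ij}, \qquad
   u_j \sim N(0, SD_u^2), \quad e_{ij} \sim N(0, SD_e^2), $$

for observation $i$ in cluster $j$, with a balanced geometry of 100
clusters of 100 observations, $\beta_0 = 0$, $SD_e = 1$, and $\beta_1 = 1$
(effect scenarios) or $\beta_1 = 0$ (Type I scenarios). The intraclass
correlation coefficient of the outcome given $x$ is
$\mathrm{ICC} = SD_u^2 / (SD_u^2 + SD_e^2)$.

Six values of $SD_u$ (0.0316, 0.05485, 0.1005, 0.1759, 0.3333, 0.6547)
target sample ICCs at the midpoints 0.001, 0.003, 0.01, 0.03, 0.1 and 0.3
of six acceptance ranges (`icc_grid()`). A sample whose realized ICC falls
outside its range is discarded and regenerated *with the same shift SD*
until it lands inside (`generate_accepted_sample()`); the attempt count is
recorded, and a scenario whose analytic acceptance probability is below
$10^{-6}$ fails before any simulation rather than spinning.

The explanatory variable comes in two flavours:

* **Continuous**: $x_{ij} = x_{0ij} + \mathrm{shift}_j$ with
  $x_{0ij} \sim N(0,1)$ and $\mathrm{shift}_j \sim N(0, SD_{shift}^2)$,
  $SD_{shift} \sim U[0, 20]$ across samples. Within-cluster variance of
  $x$ is always 1, so the SD across clusters of the cluster means of $x$
  ("dispersion", `x_dispersion()`) measures how clustered $x$ is.
* **Binary**: each cluster receives prevalence
  $p_j = \mathrm{clip}(p_{target} + \mathrm{shift}_j,\, 0,\, 1)$ with
  $SD_{shift} \sim U[0, 0.05]$ and $p_{target} \in \{0.05, 0.1, 0.2,
  0.4\}$; exactly $\mathrm{round}(100\, p_j)$ of the cluster's values are
  1. Dispersion is the SD of realized cluster prevalences.

At full scale the study uses 1,000 shift SDs × 100 replicates per ICC
level (continuous) and 500 × 100 per (ICC level, prevalence) pair
(binary); `study_plan()` expresses those defaults and scales them down
proportionally for desk-scale runs.

## Decisions where the design was open

Several details of this generative protocol admit more than one
reasonable reading; the package fixes them as follows.

* **Screening ICC.** The acceptance step needs "the ICC of a sample".
  The default (`icc_method = "realized"`) computes it from the simulated
  draws as $\mathrm{var}(u_j) / (\mathrm{var}(u_j) + \mathrm{var}(e_{ij}))$
  with unbiased sample variances — the quantity the generative model
  actually controls, at zero extra cost. A `"fitted"` switch instead uses
  the RI model's estimated variance components (one extra fit per
  attempt) for sensitivity analysis; the two agree closely at this sample
  size.
* **Prevalence clipping.** Negative assigned prevalences are set to 0 (a
  stated rule of the design); symmetric clipping at 1 guards
  user-supplied configurations, though it is unreachable under the grid
  above.
* **Count rounding.** The per-cluster count of ones is rounded half away
  from zero (`floor(m p + 0.5)`), which preserves expected prevalence;
  base R's `round()` would round half to even. The worked rule "0.223
  becomes 22 ones out of 100" is consistent with either.
* **Rejection scope.** On rejection the *entire* sample — shifts,
  x, and outcome errors — is redrawn, keeping only the shift SD.
* **Sample-SD convention.** Dispersion and the realized ICC use the
  unbiased $n-1$ denominator throughout.
* **Seeding.** Every replicate's seed is a deterministic Lehmer-style
  hash of (master seed, scenario index, shift index, replicate index), so
  any subset of scenarios, run in any order, reproduces the full run's
  records bit for bit.

## Estimators

Both models are fitted to every accepted sample.

* `fit_ols()` solves the normal equations for `y ~ x`, ignoring clusters,
  with the conventional homoskedastic-independence SE (verified identical
  to `stats::lm` in the tests; the closed form keeps a study of $10^5$
  fits fast).
* `fit_ri()` maximizes the exact likelihood of the RI model. Balance is
  exploited: profiling out $(\beta_0, \beta_1, SD_e)$ leaves a
  one-dimensional problem in the variance ratio
  $\lambda = SD_u^2 / SD_e^2$, evaluated from between/within cluster sums
  in $O(J)$ after an $O(n)$ pass. A coarse log-grid scan brackets the
  optimum (guarding against local minima in degenerate tiny samples)
  before golden-section refinement; $\lambda$ is constrained to
  $[0, \infty)$ and at the boundary the fit coincides with OLS. ML is the
  default criterion, REML an option; at 100 clusters the slope difference
  is far below 0.1%. The tests pin the fitter to two independent oracles:
  `lme4::lmer` on full-size samples, and a dense-covariance ML oracle
  (explicit block covariance, two-parameter optimization) on ~100 tiny
  samples.

Confidence intervals and p-values are standard-normal Wald for **both**
models (`wald_interval()`), so any inferential difference between them
comes from the SEs alone; with $n = 10{,}000$ the t/z distinction is
negligible, and a t option with explicit degrees of freedom exists for
small data. Non-convergence is recorded honestly (`converged = FALSE`),
and such replicates are excluded and counted by the evaluation layer —
never silently replaced; a residual variance estimated at zero is
likewise flagged rather than reported as infinite precision.

## Evaluation

`summarize_records()` turns tidy per-replicate records into the four
metric families: mean deviation of $\hat\beta_1$ from the truth, mean
$SE^{RI}/SE^{OLS}$, coverage of 95% CIs, and rejection (Type I) rate at
the 5% level, each with a Monte-Carlo SE (binomial for rates, empirical
for means) so scaled-down runs remain interpretable.
`assign_dispersion_bins()` forms equal-count fifths or thirds of
dispersion *within* each (ICC level, prevalence) stratum — the shift SDs
are drawn per scenario, so pooled quantiles would mix distributions; ties
at boundaries break by replicate order for determinism. Under the null
and the shared z convention, `type1_rate` equals `100 − coverage_rate`
exactly; the test suite asserts this identity.

## Problem sizes

Replication counts are configurable; the package's own test and
acceptance runs use 2,000 accepted samples per continuous ICC level,
2,000–4,000 at the binary stress corner (prevalence 0.05, ICC 0.3) and
200–1,000 per low-ICC binary scenario. At those sizes binomial MC SEs are
0.5–1.6 percentage points, small against the effects of interest
(coverage collapsing from 95 to 30, Type I inflating from 5 to 70); the
analysis scripts default to 500 per level so a full desk run completes in
a few minutes. One structural point matters for dispersion-binned
metrics: replicates generated from the same shift SD have nearly the same
dispersion and fall into the same bin together, so precision there is
governed by the number of *distinct* shift values; arms whose headline
metric is binned therefore favour many shift values over many replicates
per shift.

## What the generator does and does not emulate

The simulations share every structural assumption of the design they
implement: equal cluster sizes, a single explanatory variable, cluster
effects independent of $x$ (no confounding by cluster), constant slope
across clusters, and normal errors at both levels. Passing tests
therefore say nothing about unequal or informative cluster sizes,
random slopes, non-normal or heteroskedastic errors, or multi-covariate
models — all outside scope. Within scope, the headline numbers
(OLS Type I ≈ 70% at ICC 0.3 with continuous x; binary-x coverage between
~87% and ~98% at prevalence 0.05, ICC 0.3) are properties of this
generative design, reproduced here at reduced replication, not new
empirical claims about any real dataset.

## Known limitations

* `fit_ri()` requires a balanced design; unbalanced user data get a
  clear error rather than a silently different likelihood.
* The acceptance-probability feasibility check treats the individual
  error variance as fixed at its expectation, which is accurate at
  $n = 10^4$ but conservative for very small geometries.
* The binary generator's "first $k$ rows are 1" layout is exchangeable
  under the outcome model, but means the *position* of ones carries no
  information; do not reuse the generator for models where it would.
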