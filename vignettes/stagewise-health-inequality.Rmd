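---
title: "Measuring stage-wise income-related health inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stage-wise income-related health inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hequity)
```

## The measurement problem

Public resident medical-insurance schemes move money between participants
three times: everyone pays a premium (income falls), the sick pay
out-of-pocket costs at treatment (income falls again), and insured costs
are partially reimbursed (income rises). Each flow re-orders participants
on the income scale, and because health is graded in income, each
re-ordering changes measured income-related health inequality. `hequity`
quantifies that change: it computes the concentration index of health over
income ranks at four income states — initial per-capita household income,
post-contribution, post-treatment, and post-reimbursement — and reports
the stage-to-stage differences. A negative total change
(`delta_total = CI_initial - CI_reimbursement`) means the scheme as a
whole widened inequality.

## Cardinalizing self-rated health

Self-rated health (SRH) is a 5-level ordinal variable; concentration
indices need a cardinal one. We use the ordered-probit latent-index
approach: SRH level $k$ is observed when the latent health
$H_i^* = \mathbf{x}_i'\beta + \varepsilon_i$, $\varepsilon_i \sim N(0,1)$,
falls between cutpoints $\tau_{k-1}$ and $\tau_k$. The regressors are the
stage income plus the controls gender, age, education years, marital
status, and region. The predicted *linear index* $\mathbf{x}_i'\hat\beta$
(cutpoints excluded, so the score is unbounded) is then min–max rescaled
to $[0,1]$ using the in-sample extrema:
$\mathrm{SaH}_i = (H_i - \min H)/(\max H - \min H)$.

Numerical choices:

* **Income transform.** Income enters the index as a signed log,
  $\operatorname{sign}(x)\log(1+|x|)$. On non-negative incomes this is
  exactly $\log(1+\text{income})$, the standard variance-stabilizing
  choice for right-skewed incomes; the signed extension keeps the index
  defined for the (rare) negative post-treatment incomes that large
  medical bills can produce.
* **Optimizer.** BFGS with an analytic gradient on a reparameterized
  scale (first cutpoint plus log-gaps, so cutpoints stay ascending),
  followed by Newton polish steps until the mean absolute gradient falls
  below $10^{-6}$ per observation; at most 200 BFGS iterations. A fit
  that does not meet this criterion is returned with
  `converged = FALSE` and refuses to predict rather than silently
  degrading. Design columns that are constant (a control that does not
  vary within a subgroup, or an unobserved factor level) are unidentified
  and are dropped before fitting.
* **Prediction covariates.** The latent index is evaluated at observed
  covariate values, not at covariate means.
* **Stage handling.** Two modes: `per_stage` (default) refits the probit
  with each stage's income as the income regressor and re-predicts the
  score, so both the health score and the ranks move between stages;
  `fixed` fits once on initial income and holds the score constant, so
  only ranks move. Reports record the mode used. The `fixed` mode
  isolates the pure re-ranking effect and is what the no-flow identity
  tests use.

The cardinal score is only identified up to the in-sample rescaling, so
its *absolute* level is not comparable across samples or to published
score means computed under other scalings; we only interpret its ordering
and its covariance with income ranks. Rescaling is invariant to positive
affine transformations of the latent index.

## Concentration and Erreygers indices

Fractional income ranks are $r_i = (i - 0.5)/n$, with tied incomes
sharing the average of their positional ranks (this keeps the mean rank
at exactly 0.5 and preserves the covariance identity). The concentration
index is

$$CI = \frac{2}{\bar h}\,\mathrm{cov}(h_i, r_i),$$

with the population ($1/n$) covariance — for untied ranks this equals the
summation form $\frac{2}{n\bar h}\sum_i h_i r_i - 1$, an identity the
test suite checks to $10^{-12}$ against an independent implementation.
$CI \in [-1, 1]$; positive values mean health is concentrated among the
rich. The CI is invariant to scaling of health but not to translation,
which is why the bounded-health correction matters.

For bounded health the Erreygers corrected index is

$$EI = \frac{1}{n}\sum_i \frac{4\,(h_i - h_{\min})}{h_{\max} - h_{\min}}\,(2 r_i - 1),$$

with bounds fixed at $(0, 1)$ for the cardinalized score (recorded in the
output metadata). On $[0,1]$ health with untied ranks, $EI = 4 \bar h \,
CI$ exactly. A useful closed-form check: if health *equals* the income
rank, $CI \to 1/3$ and hence $EI \to 2/3$.

Bootstrap standard errors resample participants with replacement,
recompute ranks and the index per resample, and report the SD of the
replicates plus a two-sided percentile p-value against zero (default
$B = 200$, seeded). The cardinalization fit is held fixed across
resamples: at survey sample sizes its estimation uncertainty is
negligible next to the ranking variability, and refitting the probit
inside every resample would dominate the cost.

## Group analyses

Income quintiles are cut at the 20/40/60/80th percentiles of *initial*
income, ties going to the lower group, and are held fixed across stages —
the analysis follows "the low-income group" as a fixed population through
the scheme. Within each quintile, stage indices use within-group ranks
but the pooled full-sample health score: within-quintile income variation
is too small to identify a probit income slope, and the stage comparison
should track one health variable.

Gender and education heterogeneity analyses instead *refit the
cardinalization within each subgroup*: a pooled probit has a single
income coefficient and by construction cannot express a subgroup-specific
income–health gradient, which is exactly what those analyses are after.
`subgroup_ci(sah = ...)` exposes the pooled alternative.

## Relative deprivation

As a corroborating measure, each participant's relative health
deprivation is the mean shortfall to all healthier participants,
normalized by mean health:
$RD_i = \frac{1}{n\,\bar x}\sum_j \max(x_j - x_i, 0)$, computed in
$O(n\log n)$ via the equivalent decomposition
$RD_i = \frac{1}{\bar x} r^+_i (\bar x^+_i - x_i)$, where $r^+_i$ is the
share of strictly healthier participants and $\bar x^+_i$ their mean
health. The population mean of $RD$ equals the Gini coefficient of
health — both identities are verified to $10^{-12}$ against brute-force
pairwise oracles. RD is computed on the raw 1–5 SRH scores by default
(`rd_on_sah` switches to the cardinalized score), with the full sample as
the reference group (a `group` argument allows within-group reference
populations). RD is then regressed by OLS on quintile dummies (lowest
quintile as reference), with and without the standard controls;
conventional non-robust standard errors.

## Horizontal equity of utilization

Utilization (annual outpatient visits, inpatient episodes) is modelled
linearly: $Y_i = \alpha + \beta' X_i + \gamma' Z_i + \varepsilon_i$ with
need factors $X$ (gender, age, SRH coded 1–5) and non-need factors $Z$
(log income, education years, marital status, urban/rural, region).
Need-expected utilization evaluates need factors at observed values and
every non-need factor at its sample mean; standardized utilization is
$Y_s = Y - \hat Y + \bar Y$, which preserves the grand mean exactly (a
least-squares identity). The per-quintile table reports actual, expected
and standardized means plus the coverage ratio
$100\cdot\text{actual}/\text{expected}$ (undefined, reported `NA`, if the
expected mean is not positive). The linear count model is deliberate —
it is the standard indirect-standardization regression — even though
counts are non-negative integers; a two-part or count model is out of
scope.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws survey-like microdata with the structure the
analysis assumes, with ground truth attached for recovery tests:

* **Income**: lognormal (meanlog 9.5, sdlog 0.8 — median ≈ 13,400
  currency units/year, right-skewed as household surveys are), used as
  per-capita household income.
* **Latent health**: intercept $-2.33$ + 0.3·log(1+income) + covariate
  effects + standard-normal noise, matching the probit's error
  assumption so cardinalization is well-specified. Cutpoints
  $(-1.74, -0.79, 0.36, 1.33)$ were calibrated once against this latent
  distribution so the marginal SRH distribution is approximately
  5/18/40/26/11% from worst to best — a realistic class imbalance for
  the probit fit — and then frozen.
* **Premium**: flat 250/year with the bottom 5% of the income
  distribution fully waived, mirroring categorized premium-assistance
  policies.
* **Utilization**: negative-binomial counts with a mean *linear* in a
  need score (5 − SRH), age and gender plus non-need income and
  education terms. Overdispersion stresses the linear standardization
  model; the linear mean keeps it correctly specified, so need-only
  configurations admit clean null recovery. Means ≈ 4.5 outpatient
  visits and 0.7 inpatient episodes/year.
* **Spending**: out-of-pocket cost proportional to utilization
  (unit costs 150/visit, 2500/episode) with a mild income elasticity and
  lognormal noise; reimbursement is 50% of spending, so
  reimbursement ≤ spending always holds.

Not emulated: household structure, survey weights, panel dynamics, item
non-response, regional price differences, and any calibration of the
joint income–spending distribution to a real survey — generator
parameters are stylized. Passing recovery tests therefore shows the
estimators recover known gradients under the model's own assumptions,
not that any particular published magnitude is reproduced; the published
index values come from access-restricted survey microdata that a
synthetic cohort cannot and should not replicate numerically.

## Problem sizes used in the test suite

Deterministic identities run on small random instances ($n \le 50$, 40
replicates). Recovery tests use the sizes at which the properties are
stated: single cohorts of 20,000 for coefficient recovery, 100 seeds at
$n = 5{,}000$ for directional claims (CI sign, standardized-use
gradient), 30 seeds at $n = 4{,}000$ for the gender-gradient
heterogeneity check, and $B = 200$ bootstrap replicates for the null-CI
band.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(n_individuals = 20000, seed = 1))
hi <- health_inequality(co, mode = "per_stage")
print(hi)
tab <- utilization_table(co)
print(tab)
```

## Known limitations

* The cardinal score's absolute level depends on the in-sample extrema;
  only orderings and indices are interpretable.
* `per_stage` mode changes both the health score and the ranks between
  stages, so stage deltas mix re-ranking with re-scoring; use `fixed`
  mode to isolate re-ranking.
* Bootstrap SEs ignore probit estimation uncertainty (see above).
* The linear utilization model can predict negative expected counts for
  extreme covariate combinations; coverage ratios are reported as
  undefined when a group's expected mean is not positive.
* Tie handling in ranks (average positional rank) is one of several
  defensible conventions; it is the one that keeps the covariance and
  summation forms identical.
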