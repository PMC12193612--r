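# hequity

Stage-wise income-related health-inequality analysis for medical-insurance
cohorts.

## The problem

Resident medical-insurance schemes redistribute income three times:
participants pay a premium (contribution), pay out-of-pocket costs at
treatment, and receive partial reimbursement. Each flow re-orders people
on the income scale, and because health is graded in income, each
re-ordering changes measured income-related health inequality. `hequity`
is for health economists and epidemiologists who want to quantify that
change from individual-level survey microdata with ordinal self-rated
health (SRH), incomes, monetary flows and utilization counts.

## The method

1. **Cardinalization.** Ordinal SRH (1–5) is mapped to a continuous
   score via an ordered probit
   H\*ᵢ = x′ᵢβ + εᵢ, ε ~ N(0,1), with stage income (as log(1+income))
   and controls (gender, age, education years, marital status, region);
   the predicted linear index is min–max rescaled to [0, 1]:
   SaHᵢ = (Hᵢ − min H)/(max H − min H).
2. **Concentration index** over fractional income ranks
   rᵢ = (i − 0.5)/n (ties averaged):
   CI = (2/h̄)·cov(SaHᵢ, rᵢ) ∈ [−1, 1], positive = pro-rich. Computed at
   the four stage incomes (initial, post-contribution, post-treatment,
   post-reimbursement), with stage deltas and
   Δ_total = CI_initial − CI_reimbursement (negative ⇒ the scheme widened
   inequality). The **Erreygers index**
   EI = (1/n)·Σ 4hᵢ/(h_max − h_min)·(2rᵢ − 1) serves as the
   bounded-health robustness check (EI = 4h̄·CI on [0,1] health).
3. **Relative deprivation** RDᵢ = Σⱼ max(xⱼ − xᵢ, 0)/(n·x̄), whose mean is
   the Gini coefficient of health, regressed on income-quintile dummies.
4. **Horizontal equity** of outpatient/inpatient utilization by indirect
   standardization: Y_s = Y − Ŷ + Ȳ with Ŷ the need-expected utilization
   (need factors at observed values, non-need factors at their means),
   plus per-quintile coverage ratios 100·actual/expected.

A seeded synthetic cohort generator with attached ground truth supports
recovery testing throughout. See the vignette
(`vignettes/stagewise-health-inequality.Rmd`) for assumptions, defaults
and limitations.

## Worked example

```r
library(hequity)
co <- generate_cohort(cohort_config(n_individuals = 20000, seed = 1))
hi <- health_inequality(co, mode = "per_stage")
print(hi)
```

```
Stage-wise income-related health inequality (n = 20000, mode = per_stage)

         stage     ci     ei mean_health
       initial 0.0973 0.1931      0.4959
  contribution 0.0985 0.1946      0.4941
     treatment 0.0419 0.1102      0.6568
 reimbursement 0.0309 0.0865      0.6994

Deltas (CI): contribution -0.0011, treatment +0.0565, reimbursement +0.0110
delta_total = +0.0664  (inequality narrowed post-reimbursement)
```

The initial CI of 0.097 says better health is concentrated among richer
participants in this synthetic cohort (the generator's latent-health
slope on log income is 0.3 by default). The premium stage barely moves
the index (a flat levy with a bottom-tail waiver), while the
out-of-pocket and reimbursement stages re-rank participants enough to
lower it; Δ_total > 0 means inequality narrowed overall here.

```r
utilization_table(co)[1:5, ]
```

```
        group    outcome actual_mean expected_mean standardized_mean coverage_ratio_pct    n
          low outpatient       4.317         4.766             4.065              90.58 4000
 lower_middle outpatient       4.354         4.604             4.264              94.58 4000
       middle outpatient       4.482         4.504             4.492              99.51 4000
 upper_middle outpatient       4.576         4.422             4.668             103.49 4000
         high outpatient       4.839         4.273             5.080             113.25 4000
```

The poorest quintile uses only 90.6% of its need-expected outpatient
care while the richest uses 113.3%, and the gradient survives
standardization — the pro-rich utilization pattern the horizontal-equity
analysis is designed to expose.

`run_pipeline()` orchestrates everything from a config (or YAML file)
and returns all six result tables; `inst/cli/hequity.R` wraps it for the
shell (`simulate`, `run`, `verify` subcommands).

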