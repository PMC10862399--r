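# depburden

Ten-year cost and mortality burden projection for newly diagnosed
depression, built around a six-state, time-inhomogeneous Markov cohort
model that separates treatment-resistant depression (TRD) and new-onset
comorbidity pathways.

The package is aimed at health-economic modellers and mental-health policy
analysts who need to project the care burden of a depression cohort from
patient-level service records: epidemiologists deriving transition inputs
from electronic medical records, and analysts running budget-impact style
closed- and open-cohort projections with sensitivity analyses.

## The model

Newly diagnosed patients all start in the non-treatment-resistant state
(NTRD) and move through six mutually exclusive health states:

```
NTRD ──► TRD ──► TRD-comorbid ──► { low-intensity, death }
  │        │
  │        └───► { low-intensity, death }
  ├────► NTRD-comorbid ──► { low-intensity, death }
  └────► { low-intensity, death }
```

`low_intensity` (a proxy for recovery) and `death` are absorbing. Cycles
are one year; the horizon is ten cycles.

For every transition, five parametric time-to-event families —
exponential, Weibull, lognormal, log-logistic, Gompertz — are fitted by
maximum likelihood with adjustment for age band, sex and baseline medical
history, and the best family is selected by lowest AIC (BIC is reported
and disagreements are flagged). The fitted survival function S(t) is
converted to the conditional per-cycle transition probability

    q(t) = 1 − S(t) / S(t−1),   t = 1, …, 10,

so transition probabilities vary over the disease course (the annual risk
of developing TRD, for instance, declines roughly 6.2% → 4.4% → 3.0% over
the first three years). State costs multiply negative-binomial regression
estimates of annual service use (outpatient, emergency, inpatient; each in
all-cause and psychiatric scope) by unit costs in 2023 US$; QALYs weight
state occupancy by utilities, with comorbid states carrying a 17% relative
utility decrement. The cohort engine runs closed (one incident cohort) or
open (staggered annual cohorts, each followed for at most ten cycles),
with optional 2.5% discounting, pandemic incidence uplifts (+25% in 2023,
+33% in 2019–2022 for the open scenario), one-way deterministic
sensitivity analysis with tornado ordering, and probabilistic sensitivity
analysis with 1000 Monte Carlo iterations.

Because real territory-wide medical records cannot be shared, the package
includes a synthetic cohort generator that emulates their statistical
structure (16 demographic subgroups, cause-specific event-time hazards
with covariate effects, administrative censoring, negative-binomial
service counts) and is calibrated to the published crude TRD risk sequence
and a ~9.8% ten-year case fatality.

## Worked example

```r
library(depburden)

cfg      <- generator_config(n_patients = 8000, seed = 1)
cohort   <- generate_cohort(cfg)
round(100 * crude_transition_probs(cohort, "NTRD", "TRD", years = 1:3), 1)
#> year1 year2 year3
#>   6.1   4.1   2.9

fits        <- fit_transition_models(cohort)   # 5 families per edge, AIC pick
sapply(fits[1:4], function(f) f$family)
#>           NTRD->TRD NTRD->NTRD_comorbid NTRD->low_intensity         NTRD->death
#>          "gompertz"           "weibull"       "exponential"         "lognormal"

schedules    <- build_schedules(fits)          # 16 subgroups x 10 cycles
state_inputs <- derive_state_inputs(cohort)    # NB costs + utilities

plan     <- build_incidence_plan("closed", "baseline")   # 9,147 entrants in 2023
entrants <- setNames(plan$new_patients, plan$subgroup)
trace    <- run_closed_cohort(schedules, state_inputs, entrants)
summary(trace)
#> closed-cohort burden summary (9147 entrants)
#>   cumulative all-cause cost:   US$315.6 million
#>   cumulative psychiatric cost: US$62.5 million (20% share)
#>   deaths: 966 (case fatality 10.6%)
#>   life-years: 86899   QALYs: 68510
#>   cost CAGR: all-cause -7.3%, psychiatric -6.9%
```

The crude probabilities are the cohort's empirical annual NTRD→TRD risks;
the summary lines are the ten-year projection for the 2023 incident
cohort: cumulative costs in both scopes with the psychiatric share,
cumulative deaths with the case fatality rate, life-years and QALYs, and
the compound annual growth rate of the annual cost series. Subgroup
tables, open-cohort runs (`run_open_cohort()`), pandemic scenarios
(`build_incidence_plan("closed", "pandemic")`) and sensitivity analyses
(`run_dsa()`, `run_psa()`) build on the same objects; `build_report()`
writes everything to CSV/JSON.

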