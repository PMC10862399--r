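---
title: "Modelling the ten-year burden of depression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ten-year burden of depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(depburden)
```

This vignette documents the scientific content of **depburden**: the model
and its assumptions, the parameters that matter and their defaults, what
the synthetic data generator does and does not emulate, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## The cohort model

The model is a time-inhomogeneous Markov cohort model with six mutually
exclusive health states and yearly cycles over a ten-year horizon:

* **NTRD** — non-treatment-resistant depression, the initial state of every
  newly diagnosed patient;
* **TRD** — treatment-resistant depression (failure of two adequate
  antidepressant regimens, confirmed under a third);
* **NTRD-comorbid** / **TRD-comorbid** — new-onset somatic or psychiatric
  comorbidity arising before vs. after TRD onset. Splitting the comorbid
  state in two relaxes the memoryless assumption: the model can carry
  different transition intensities and costs for the pre- and post-TRD
  disease stages without tracking individual history;
* **low-intensity service user** — an absorbing alive state proxying
  recovery (no further depression-related diagnoses or antidepressant
  prescriptions);
* **death** — absorbing, all causes.

Outcomes are stratified into 16 subgroups (four age bands at diagnosis ×
sex × baseline medical history). Expected state occupancy evolves by
`occ(t) = occ(t−1) %*% P(t)` per subgroup, where `P(t)` is the cycle-`t`
transition matrix.

## Time-varying transition probabilities

Each permitted transition is modelled as a cause-specific time-to-event
outcome: the clock starts at entry into the source state, and competing
transitions and the administrative cut-off are right-censoring events.
Five parametric families are fitted (exponential, Weibull, lognormal,
log-logistic, Gompertz) with covariate adjustment for age band, sex and
baseline history, and the family with the lowest AIC is selected.  BIC is
computed as `k·log(n) − 2·loglik` with `n` the number of subjects; when it
prefers a different family the selection is flagged and a message emitted,
but AIC wins — an automated rule must be deterministic, and the
traditional visual curve inspection is replaced by a recorded
quantile-deviation statistic (`qq_dev`: mean absolute gap between the
Kaplan–Meier curve and the mean fitted survival at the event-time
deciles).

The fitted survival function is converted to per-cycle conditional
probabilities as `q(t) = 1 − S(t)/S(t−1)`.  Note the complement: the ratio
`S(t)/S(t−1)` itself is the conditional probability of *remaining*
event-free through cycle `t`; only its complement yields transition
probabilities that decline over time toward long-term stability, which is
the behaviour the whole time-varying construction exists to capture.

**Covariate placement.** The Weibull, lognormal and log-logistic families
take covariates in accelerated-failure-time form (a multiplier on the time
scale). The exponential and Gompertz families have no distinct AFT
parameterisation in the fitting engine and carry covariates on the rate
(proportional hazards); for the exponential the two forms coincide up to
the sign of the coefficients. The synthetic generator applies covariate
effects as time-scale multipliers for *all* families, which is
well-defined regardless of parameterisation.

**Clock convention.** Survival clocks reset at entry into the source
state, but a cohort model cannot carry sojourn times without tunnel
states. Transition probabilities are therefore indexed by model cycle: for
transitions out of NTRD the two clocks coincide (everyone enters NTRD at
time 0); for post-TRD transitions the cycle index is used as the time
argument. With the default configuration all post-NTRD hazards are
exponential, for which the distinction vanishes.

**Combining competing causes.** Two conventions are implemented in
`assemble_schedule()`:

* `method = "sum"` (default): the cause-specific `q(t)` enter the row
  directly and the stay probability is their complement; should the sum
  exceed 1 the row is rescaled proportionally with a loud warning (this
  preserves relative cause-specific risk, and signals implausible inputs).
  This is the convention common in yearly-cycle health-economic models.
* `method = "hazard"`: each `q` is converted back to a cycle hazard
  increment `ΔH = −log(1 − q)` and the total exit probability
  `1 − exp(−ΣΔH)` is allocated proportionally to the increments. This
  reproduces a latent competing-risks simulation exactly when hazards are
  constant within the cycle.

The two agree to first order for small probabilities (the regime of this
model, where annual probabilities are mostly below 0.1); the default
follows the simpler convention, and the hazard method is available where
exact competing-risks semantics matter.

**Internal validation.** `validate_schedule_fit()` compares modelled
cumulative deaths and low-intensity users at cycle 4 against the cohort's
observed counts among patients followed at least that long, summarised as
a mean absolute percentage error (MAPE); the test suite requires MAPE
below 5% on the synthetic cohort.

## Costs and utilities

Annual service use is modelled per care setting (outpatient visits,
emergency attendances, inpatient bed-days) and scope (all-cause,
psychiatric) by negative-binomial regression on patient-year data, with
age band, sex, baseline history, and the TRD / comorbidity status implied
by the state occupied that year, plus a log-exposure offset for partial
years (variance parameterisation `μ + μ²/θ`). State-by-subgroup costs are
predictions at the indicator profile of each state — not stratified refits
— multiplied by unit costs and summed over settings. Covariates without
variation in the supplied data are dropped from the formula, so the same
function serves stratified inputs.

The packaged unit costs (US$ 170 / 160 / 650 per outpatient visit,
emergency attendance, bed-day; 2023 US$ at 7.85 HKD/USD) and the state
utilities (NTRD 0.80, TRD 0.60, low-intensity 0.85) are synthetic
placeholders of realistic magnitude, clearly labelled as such in their
JSON files; real schedules slot in via `read_unit_costs()` /
`read_utilities()`. Comorbid-state utilities carry a 17% relative
decrement against their non-comorbid counterparts
(`apply_utility_decrement()`), death has utility 0, and the low-intensity
and death states accrue zero cost in both scopes — their care is not
depression-related by definition; background costs of recovered patients
are out of scope.

## Incidence and scenarios

New-patient counts come from mean age-specific annual incidence (assumed
constant) times official population projections per five-year age group.
The packaged tables are synthetic stand-ins, reverse-engineered so that
the 2023 baseline projection is 9,147 patients — 15.0 per 10,000
population aged 10+ — with incidence rates equal within each of the four
model age bands and chosen so the entrant age mix matches the reference
cohort (10.6% / 20.0% / 55.6% / 13.8%); a uniform rate would instead tie
the entrant mix to the population pyramid and markedly age the cohort.
Within each age band, entrants are apportioned to sex and history by the
reference cohort's conditional mix; `reference_mix_2018()` provides the
alternative demographic structure (17.0% aged 10–24) for the
demographic-shift check, via `apportion = "mix"`.

The pandemic scenario raises 2023 entrants either uniformly by +25% or by
an age-band-specific profile (stronger in the young, calibrated so the
2023 total is 11,397); in open-cohort mode the 2019–2022 entrants are
additionally raised by +33%. Observed annual counts are used for
2014–2018 and the constant-incidence projection thereafter.

## The Markov engine

Accrual conventions, chosen once and testably simple:

* state membership is measured at cycle start; transitions apply at cycle
  end; no half-cycle correction;
* deaths within a cycle accrue no cost and no fraction of a life-year;
* life-years count all alive states *including* low-intensity, whereas
  "active patients living with depression" exclude it; attribution splits
  (TRD family = TRD + TRD-comorbid; comorbid family = NTRD-comorbid +
  TRD-comorbid) restrict the same sums;
* discounting divides by `(1 + r)^(t−1)` so the first cycle is
  undiscounted; main results use `r = 0`, with `r = 0.025` available;
* prevalent-case state shares are reported against alive cohort members.

The open-cohort mode introduces one incident cohort per plan year; each is
simulated for at most ten cycles, so a calendar year aggregates exactly
the cohorts diagnosed in the previous ten years. A cohort entering year
`Y` contributes its first-cycle outcomes to calendar year `Y`. By
construction the open run equals the superposition of independently run
closed cohorts at the matching offsets, and the test suite verifies this
to 1e-9. The calendar loop ends at the last plan year by default
(mirroring a projection that stops with the final incident cohort), and
`end_year` extends it when late cohorts should be followed to completion.

## Sensitivity analyses

The parameter registry holds one entry per uncertain input — entrants, the
four NTRD exit probabilities (perturbed as per-cycle probability vectors
with the stay probability re-complemented, not as survival coefficients),
the two cost scopes, and the base utilities — with bounds defaulting to
±20% where no confidence interval is carried. The one-way DSA reruns the
model at each bound and reports tornado-ordered swings; near-ties from
floating-point noise fall back to registry order. The PSA samples all
parameters jointly — beta for utilities (moment-matched to base and
bounds), gamma for cost and probability scales, zero-truncated normal for
entrants, conventions standard in health-economic practice rather than
facts about any particular dataset — and reports means and SDs over 1000
iterations by default, reproducibly under a fixed seed and parameter
order.

Because entrants, costs and utilities enter the cohort model linearly,
entrant perturbations move cost outcomes by exactly the same relative
amount; the tests assert this ±20% ↔ ∓20% equivalence exactly.

## The synthetic cohort generator

The generator emulates the statistical structure the estimation stages
assume, standing in for an unshareable territory-wide medical-record
extract of ~25,000 patients newly diagnosed 2014–2016 and followed to the
end of 2020 (at most seven years):

* subgroup membership drawn from the 16-way mix (74.8% women, 28.1% with
  baseline history, 10.6% aged 10–24);
* competing cause-specific event times per state, drawn independently per
  outgoing edge with the earliest realised event winning — matching the
  cause-specific survival modelling used downstream;
* administrative censoring at 31 December of the cut-off year, with
  diagnosis dates uniform within calendar years;
* negative-binomial annual service counts per setting with exposure equal
  to the fraction of the year spent active; psychiatric counts are a
  binomial thinning of all-cause counts (the negative binomial is closed
  under thinning, so the psychiatric scope stays NB with the same
  dispersion and can never exceed the all-cause count).

**Calibration.** The default NTRD→TRD hazard is Gompertz with negative
shape (`a = 0.0802`, `b = −0.354`). A Weibull cannot reproduce the crude
annual TRD risk sequence 6.2% → 4.4% → 3.0%: those ratios (0.71, 0.68)
decline almost geometrically, which is exactly the Gompertz pattern
(`q(t+1)/q(t) ≈ e^b`), whereas the best Weibull leaves year 3 about one
percentage point too high. The parameters were calibrated analytically —
numerical integration of the mixture crude probabilities *including*
competing risks over the 16 subgroups — against the target sequence, not
tuned against test outcomes. Comorbidity onset is Weibull with shape 0.75
(early-peaking); all other edges are exponential. Death hazards and
covariate acceleration factors were set so the simulated ten-year case
fatality is close to 9.8% and the TRD-family and comorbid-family shares of
alive cohort members stay below 20% in every cycle.

**What it does not emulate.** No prescription sequences or diagnostic
codes (TRD entry time is generated directly, dated at the event itself —
how a registry would date an entry that is only confirmed under a third
regimen is left open); no seasonality, no secular drift in incidence or
practice, no within-patient correlation of counts across years beyond the
state path, no suicide or cause-of-death detail. Passing tests therefore
show the *pipeline* recovers what the generator encodes — they do not
validate the clinical realism of any particular parameter against real
records.

## Numerical choices and problem sizes

Event times are drawn by inversion/standard samplers per family; defective
Gompertz distributions (negative shape) yield infinite times for the
never-event fraction, which censoring handles naturally. Survival
evaluation is closed-form throughout; the tests check it against numerical
hazard quadrature to 1e-9 and against the fitting engine's own predictions
to 1e-8. Sparse-event fits retry from moment-based starting values when
the default initialisation fails. Exact AIC ties are broken by the fixed
family order (exponential first — fewest parameters). Probabilities are
clamped to [0, 1] only against last-ulp rounding; a row that genuinely
exceeds 1 is rescaled with a warning, and `S(t−1) = 0` raises an error
rather than producing 0/0.

The test suite exercises parameter recovery at n = 10,000 (50 replicates
per family for interval coverage), the crude-sequence check at the full
n = 25,190, engine oracles on exact closed forms, and the end-to-end
pipeline on a 4,000-patient cohort; these sizes were chosen as the
smallest at which sampling error is negligible relative to the tolerances
asserted. The acceptance script runs the complete pipeline at full size.

## Known limitations

* The cohort engine tracks expected occupancy, not individuals: no
  sojourn-time effects beyond the state split, no microsimulation.
* Post-TRD transition probabilities are indexed by model cycle rather than
  sojourn time (see clock convention above) — exact only for
  constant-hazard post-NTRD transitions.
* Packaged unit costs, utilities, incidence and population tables are
  labelled synthetic stand-ins; absolute cost and QALY levels from the
  defaults are illustrative, while the structural results (ratios,
  trends, shares, sensitivity rankings) are the tested surface.
* The payer perspective excludes productivity losses and undiagnosed
  depression, so projected totals are conservative by construction.
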