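---
title: "Two-period Cox models with a bootstrap-selected change point"
author: "coxcpt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-period Cox models with a bootstrap-selected change point}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`coxcpt` targets treatment-initiator cohorts in which the effect of the
initiated drug on the hazard of a composite clinical endpoint changes over
follow-up. The working model is a Cox proportional-hazards model in which
only the treatment indicator is time-split: with cut-off day c the
indicator X becomes two interval copies X₁(t) = X·1{t ≤ c} and
X₂(t) = X·1{t > c}, giving

λ(t | X, Z) = λ₀(t) · exp(β₁X₁(t) + β₂X₂(t) + γ'Z),

so exp(β₁) and exp(β₂) are the before- and after-cut-off hazard ratios
while every adjustment covariate Z keeps a constant coefficient. The model
assumes proportional hazards *within* each period — an assumption the
package re-checks per interval with a score test on the scaled Schoenfeld
residuals — and, as in any Cox analysis of claims data, that censoring is
uninformative and covariates are measured at baseline.

Counting-process rows are left-open/right-closed, `(start, stop]`: the risk
set at an event day d contains rows with start < d ≤ stop. Splitting at
any cut-off therefore changes neither risk sets nor the likelihood when a
common coefficient is used — a refinement invariance the test suite checks
to 1e-8 — and conserves person-time and event counts exactly.

## Selecting the cut-off

Candidates are placed at monthly marks (m·30 days, every m with
m·30 < maximum follow-up), first as single cut-offs (two periods), with
ordered pairs (three periods) examined only when no two-period candidate
satisfies the per-interval proportional-hazards check — "more if
necessary". For each candidate the *univariate* time-split model (treatment
only, Breslow ties) is maximised. Because the cut-off that maximises the
observed profile is sensitive to the realised event times, the procedure
draws B = 500 resamples with replacement, stratified by arm so every
resample has the original sample size and treatment proportion, recomputes
each candidate's maximised log partial likelihood per resample, and selects
the candidate maximising the **median** of the B values, restricted to
candidates whose per-interval proportional-hazards verdicts pass on the
original data. Ties in the median go to the earliest cut-off.

Three procedural choices are deliberately fixed and documented because the
underlying procedure leaves them open:

* the proportional-hazards gate is evaluated on the original cohort, not
  per resample (configurable via `ph_check`); re-testing within resamples
  would multiply the test's noise into the selection;
* a candidate is *feasible* only when each interval holds at least five
  events per arm — interval coefficients with fewer events are
  unidentifiable or explode, and the procedure's source is silent on empty
  intervals;
* "month" means 30 days: calendar months are undefined relative to
  subject-level index dates.

The per-candidate, per-resample fits use a specialised scalar Newton solver
on a per-event-day aggregate (at-risk and event counts per arm): for a
single binary split covariate the Breslow partial likelihood separates into
independent one-dimensional concave problems per interval, which makes the
full 30-candidate × 500-resample search run in about a second on a
20,000-subject cohort. The solver is cross-checked against
`survival::coxph(ties = "breslow")` to 1e-6 in the test suite; the
general-purpose fits (`cox_fit()`) delegate to `survival::coxph` with
Efron ties by default (day-granular claims data produce many ties; Breslow
remains available for oracle comparisons), tolerance 1e-9 on the
log-likelihood change, and at most 100 iterations.

## Cohort construction parameters

All times are integer days relative to the study epoch (opening of the
inclusion window); "30 months" is 913 days, "one year" 365 days, the
"six-month" censoring gap 183 days. The defaults of
`eligibility_criteria()`:

| parameter | default | meaning |
|---|---|---|
| `washout_days` | 913 | lipid-lowering-free lookback before index |
| `index_window` | 0–549 | admissible index days (18-month window) |
| `min_consecutive_reimbursements` | 2 | reimbursements defining initiation |
| `max_refill_gap_days` | 120 | maximum spacing of those reimbursements |
| `min_disease_reimbursements` / `disease_window_days` | 3 / 365 | treated diabetes and hypertension |
| `min_age_male` / `min_age_female` | 50 / 60 | inclusive age thresholds |
| `require_gp_prescriber` | TRUE | index prescription from a GP |

"Consecutive" reimbursements need a spacing bound to be computable; 120
days is a generous maximal dispensing interval and is configurable. An
event on the index day is given one day of risk time so that every subject
contributes positive follow-up (partial-likelihood machinery requires it).
Exclusion rules run in a fixed, reported order (age/sex, diabetes,
hypertension, prior cardiovascular event), so the attrition table sums from
initiators to the included cohort. The "3 reimbursements over one year"
criterion is evaluated over any rolling 365-day window inside the washout.
Follow-up stops at the first composite-endpoint occurrence; the
amputation-excluded endpoint variant recomputes first occurrence over
death/stroke/MI.

## Estimation choices

* **Mantel–Haenszel rates.** Annual event rates are events per 100
  person-years of first-event follow-up (the source scale, "percent per
  year", never defines its denominator; person-years is the standard
  choice). Strata are the age bands 50–59/60–69/70–79/80+ crossed with
  sex; arms are combined with Mantel–Haenszel person-time weights
  w = Y₁Y₀/(Y₁+Y₀), confidence intervals use the normal approximation on
  the log rate, and the comparison p-value comes from the MH-weighted rate
  difference.
* **Screening.** Each candidate confounder is screened in an
  age/sex-adjusted Cox model at p < 0.05; selection additionally requires
  completeness (no missing values — this excludes the deprivation quintile
  and the diabetes-duration band) and membership of a configured
  clinically-eligible allow-list, because "potential clinical impact" is
  not computable from data. No multiplicity adjustment is applied and all
  p-values are two-sided.
* **IPW.** The propensity model is a logistic regression of arm on the
  screened covariates; weights are the inverse probability of the
  *received* treatment, stabilised by the marginal arm probability by
  default, applied as case weights in the (time-split) Cox model with a
  robust sandwich variance clustered on subject. Describing the weight as
  "a covariate in the Cox model" — as the procedure's source does — would
  not produce a marginal estimand; the standard weighting of the IPW
  literature is implemented instead. Estimated propensities below 0.01 or
  above 0.99 are flagged and weights can be truncated at a configurable
  quantile.

## What the generator emulates — and what it does not

The synthetic generator reproduces the *structure* of a nationwide
claims-based initiator cohort: covariate prevalences matching the published
baseline table (≈ 47.6% women; metformin 64%, insulin 7.7%, depression
11%, …), a 12.8% fibrate share with the propensity-model intercept
calibrated numerically to that target, confounded treatment choice with the
published imbalance directions, staggered entry over 550 days,
administrative censoring at day 913, missing deprivation quintile (9%,
missing completely at random) and an unknown diabetes-duration band (30%),
and event times drawn by exact closed-form inversion of the
piecewise-exponential cumulative hazard with the default treatment schedule
log HR = log 0.95 on [0, 540) and log 1.73 on [540, ∞). The default
baseline hazard (2.7 × 10⁻⁵ per person-day) was calibrated once so the
statin-arm event rate is ≈ 2.1–2.2 per 100 person-years, matching the
published adjusted rates; no random loss to follow-up is generated by
default because the source reports none.

It does **not** emulate real coding systems (ICD-10/ATC dictionaries,
procedure codes), the construction of the deprivation index, per-molecule
differences within a drug class, calendar seasonality, or informative
censoring. Event times are rounded up to whole days, which creates the tie
patterns typical of day-granular claims. Within the claims stream, drug
persistence follows a simple geometric refill model, so the
persistence-censored sensitivity analysis truncates more heavily than in
the published cohort. Diabetes-duration bands beyond ~2.5 years are not
derivable from a 913-day extract; the claims-built path therefore labels
left-truncated first records "unknown", while the directly generated
analysis table carries the full band distribution. Passing tests on this
generator demonstrate that the *machinery* is correct under known truth —
not that any particular real-world dataset satisfies the model's
assumptions.

## Validation design and problem sizes

The suite validates each stage against an independent oracle: exhaustive
grid maximisation of the Breslow likelihood for the Cox core (6-subject
printed fixture, 1e-4); refinement invariance (1e-8) and exact
person-time/event conservation (1,000 random cohorts) for the time-split;
a hand-enumerated 10-subject claims fixture for every inclusion, exclusion
and censoring rule; closed-form hand computation for the Mantel–Haenszel
combination (1e-10); and simulation studies at the cohort scale of the
emulated study — 20,000 subjects for change-point recovery (20 replicates,
B = 100), two-period hazard-ratio recovery (50 replicates) and IPW bias
removal (50 replicates), and 2,000 subjects × 500 replicates for the
proportional-hazards test's type-I error.

## Known limitations

* **Cut-off localisation precision.** Under the emulated study conditions
  (≈ 2 per 100 person-years, ~750–1,100 events, staggered entry) the split
  log-likelihood profile across monthly candidates is shallow — a few
  log-likelihood units between the best and worst candidate — because a
  one-month misplacement reallocates only a handful of events. The
  bootstrap-median selection is unbiased but widely dispersed at this
  information level (the recovery simulations in the test suite quantify
  this); monthly precision should not be over-interpreted scientifically,
  a caveat the source study itself raises about its own cut-off. Sharply
  identified designs (larger effect reversals, uniform follow-up) localise
  to within one month reliably.
* **Two-period hazard-ratio precision.** The after-cut-off hazard ratio
  rests on the minority arm's late events (a few dozen at these rates), so
  its sampling error is substantial: SE(log HR_after) ≈ 0.2 at 20,000
  subjects. The estimator is unbiased in the recovery simulations, but
  point estimates at this scale carry wide intervals.
* The three-interval search is exercised only as a fallback; no more than
  three intervals are supported, matching the procedure's scope.
* Frailty, stratified baselines, competing risks, and time-varying
  covariates other than the treatment's interval copies are out of scope.
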