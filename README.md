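# coxcpt

Change-point Cox models for new-user claims cohorts.

## The problem

In comparative-effectiveness studies built from administrative claims — for
example, fibrate versus statin monotherapy initiators among diabetic
patients at high cardiovascular risk — the treatment effect on the hazard of
a composite endpoint (all-cause death, ischemic stroke, myocardial
infarction, above-the-ankle amputation) is often not proportional over
follow-up: survival curves overlap for a year or more and separate late. A
single Cox hazard ratio is then misleading. `coxcpt` implements the full
analysis chain for this situation, aimed at pharmacoepidemiologists working
with claims-like data (reimbursement, hospital-discharge and death records):

1. **New-user, active-comparator cohort construction** —
   `build_cohort()`: initiation defined by two consecutive same-class
   GP-prescribed reimbursements, a 30-month (913-day) lipid-lowering
   washout, treated-disease inclusion rules (≥ 3 reimbursements of a class
   within a rolling year), age/sex thresholds, exclusion for prior
   cardiovascular events, baseline covariates from the year before index,
   and three follow-up regimes (intention-to-treat, persistence-censored,
   switch-censored).
2. **Change-point detection** — `bootstrap_select()`: the treatment
   indicator X is decomposed into interval-specific copies
   X = Σₖ Xₖ(t), with Xₖ(t) = X for t ∈ Pₖ and 0 otherwise, where the
   intervals Pₖ partition follow-up at a candidate cut-off. For every
   monthly candidate the univariate time-split Cox partial likelihood is
   maximised; B = 500 bootstrap resamples (stratified by arm, preserving
   the cohort's size and treatment proportion) are drawn, and the selected
   cut-off maximises the **median of the B bootstrap log-likelihoods**
   among candidates that satisfy the proportional-hazards assumption
   within each interval.
3. **Two-period estimation** — `cutpoint_cox()` / `fit_final_models()`:
   nested Cox models (crude; age/sex; fully adjusted after univariate
   screening at p < 0.05) with one treatment hazard ratio per period,
   HR(t < c) and HR(t > c), all other covariates constant.
4. **Corroboration** — Mantel–Haenszel age/sex-adjusted annual event rates
   (`mh_adjusted_rates()`) and an inverse-probability-of-treatment-weighted
   propensity analysis with robust variance (`ipw_cox()`).
5. **Synthetic claims generator** — `generator_config()`,
   `simulate_cohort()`, `generate_claims()`: subjects with realistic
   covariate prevalences, confounded treatment choice, and event times from
   an exactly inverted piecewise-exponential law with a configurable
   piecewise-constant treatment hazard ratio (default: HR 0.95 before day
   540, 1.73 after). Because the generating truth is known, every stage of
   the pipeline is testable without access to any restricted database.

## Worked example

```r
library(coxcpt)
a <- simulate_cohort(generator_config(n_subjects = 30000, seed = 42))$analysis
fit <- cutpoint_cox(a, B = 100, seed = 43)
print(fit)
mh_adjusted_rates(a)
```

```
Two-period Cox model, change point at 570 days (selected from 30 candidates, B = 100)
30000 subjects, 1137 events

Fully adjusted treatment hazard ratios:
           period    HR lower95 upper95     p
1   (0, 570] days 0.924   0.753   1.134 0.449
2 (570, Inf] days 1.673   1.177   2.377 0.004

Mantel-Haenszel age/sex-adjusted event rates (per 100 person-years)
      arm rate lower95 upper95
1 fibrate 2.21    1.87    2.60
2  statin 2.11    1.98    2.25
Rate difference: 0.094  p = 0.632
```

The generating truth here was a null effect (HR 0.95) before day 540 and a
harmful effect (HR 1.73) after: the search localises the change point to the
adjacent monthly mark (570 days) and the two-period hazard ratios bracket
the truth — no early difference, a significantly elevated late hazard in the
fibrate arm. The adjusted annual event rates are on the 2.1–2.2 per 100
person-year scale the cohort was calibrated to.

The full pipeline (generate → build cohort → find cut-off → estimate →
report) runs from a YAML config:

```r
run_pipeline("config.yaml", "out/")   # or inst/cli/run-pipeline.R from a shell
render_report("out/")
```

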