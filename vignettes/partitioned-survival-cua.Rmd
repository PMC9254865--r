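---
title: "A partitioned survival cost-utility model for first-line therapy in advanced renal cell carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned survival cost-utility model for first-line therapy in advanced renal cell carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

First-line treatment of advanced renal cell carcinoma (RCC) changed with the
CLEAR trial: lenvatinib plus pembrolizumab markedly prolongs progression-free
survival (PFS) over sunitinib (median 23.9 vs 9.2 months, hazard ratio 0.39)
and improves overall survival (OS, hazard ratio 0.66), while lenvatinib plus
everolimus prolongs PFS (median 14.7 months, hazard ratio 0.65) without an OS
benefit (hazard ratio 1.15). Whether those gains are worth their acquisition
cost in a health system that prices pembrolizumab at roughly 36,000 RMB per
21-day administration is a cost-utility question: discounted quality-adjusted
life-years (QALYs) and costs per strategy, incremental cost-effectiveness
ratios (ICERs), and a willingness-to-pay (WTP) threshold of one to three
times the Chinese GDP per capita (217,341 RMB in 2020, so 652,023 RMB/QALY at
the upper bound).

`psmcea` re-implements the published three-arm cost-utility analysis of this
comparison as a reusable, fully tested pipeline, from survival-curve evidence
through probabilistic sensitivity analysis.

## The partitioned survival model

The cohort occupies three states: progression-free (PF), progressed (PD) and
dead. A partitioned survival model reads state occupancy directly off the two
endpoint curves instead of modelling transitions:

* alive = $S_{OS}(t)$, so dead = $1 - S_{OS}(t)$;
* progression-free = $\min(S_{PFS}(t), S_{OS}(t))$;
* progressed = the band between the curves, $S_{OS} - \min(S_{PFS}, S_{OS})$.

The three occupancies sum to one by construction, which `build_trace()`
enforces exactly (and the tests assert to $10^{-12}$). Occupancy is evaluated
at cycle midpoints — equivalent to a half-cycle correction — on a 21-day
cycle grid over a 5-year horizon, both configurable. The 21-day cycle is the
pembrolizumab administration interval to which the per-cycle costs are keyed;
the evidence is silent on the cycle length actually used, so it is a setting
rather than a constant. Costs and utilities are discounted at 5% per year
with factors $(1+r)^{-t}$ evaluated at the same midpoints.

Where extrapolation makes the PFS curve cross above OS (possible when the two
endpoints are fitted or shifted independently), the PF share is clamped to
the OS curve with a warning; the progressed share is never negative.

## Survival evidence: from digitized curves to parametric extrapolation

The intended evidence path mirrors how such analyses are actually built from
published figures:

1. **Digitized Kaplan-Meier coordinates plus number-at-risk tables** per arm
   and endpoint (`sanitize_curve()` cleans digitization noise by a running
   minimum, origin insertion and clamping).
2. **Pseudo individual patient data** via `reconstruct_ipd()`, a
   Guyot-style inversion of the product-limit estimator: within each
   risk-table interval the censor count is iterated until the implied
   at-risk count matches the published value exactly, censor times are
   placed at equally spaced quantiles (deterministic by design), and integer
   event counts are spread across digitized steps by largest-remainder
   apportionment so interval totals are preserved. Ties between an event and
   a censoring at the same time are resolved event-first, the standard KM
   convention. Beyond the last risk entry no censoring is assumed unless a
   published total event count is supplied. The reconstruction is fully
   deterministic, reproduces the published at-risk counts exactly, and
   round-trips synthetic fixtures within a 0.02 sup-norm at $n = 300$ with a
   3-month risk grid.
3. **Parametric fitting** of six families — exponential, Weibull, Gompertz,
   generalized gamma, log-logistic, log-normal — by right-censored maximum
   likelihood (`fit_parametric()`, backed by `flexsurv`; the exponential
   rate is the closed form events/person-time), with AIC/BIC selection
   (`select_distribution()`; ties go to fewer parameters, then a fixed
   family order). Fitting works in months, the trial scale; conversion to
   engine years uses 365.25/12 days per month.

The Gompertz shape may be negative (an improper survival plateau), standard
practice in health-technology assessment; extrapolated survival is floored
at zero. The generalized gamma is evaluated through its log-normal limit for
$|Q| < 10^{-5}$ for numerical stability.

Comparator curves can also be derived from a reference arm by proportional
hazards: `apply_hazard_ratio()` returns $S(t)^{HR}$, an exact
cumulative-hazard scaling.

## The surrogate calibration

The original figures are not redistributable, so the shipped fixture
(`psm_example_config()`) encodes a surrogate calibrated to the published
summary statistics:

* sunitinib PFS: Weibull with median exactly 9.2 months. The shape (1.2) is
  a fixture default chosen so a single knob — the median — pins the curve;
  any of the six families can be substituted in the config.
* sunitinib OS: the median was never reached in the trial, so no median is
  available to calibrate against. Instead the exponential rate is
  root-solved so that the engine's own discounted life-years over the
  5-year horizon equal the published 2.83 (an anchor that is a named config
  value, not a constant). The implied OS median is about 40 months.
* comparator curves: proportional-hazards shifts of the reference by the
  published hazard ratios (PFS 0.39 / 0.65, OS 0.66 / 1.15).

Because the comparator PFS medians implied by proportional hazards
(9.2/0.39 = 23.6 months vs the reported 23.9) differ slightly from the
published ones, and because the real curves plateau where parametric
surrogates do not, base-case results reproduce the published table only
within tolerance bands, not exactly. This is the central, documented
limitation of any calibration from summary statistics.

## Costs and utilities

All costs are in RMB from a Chinese health-system perspective; only direct
medical costs are modelled. Per cycle while progression-free each strategy
accrues its first-line acquisition cost: lenvatinib 20 mg/day (540 RMB/day)
plus a pembrolizumab infusion; lenvatinib 18 mg/day (486) plus everolimus
5 mg/day (130); or sunitinib 50 mg/day (392) on a 4-weeks-on/2-weeks-off
schedule, entered as the dosed-day fraction 28/42. Oral prices are per
tablet of unstated strength in the source table, so the config requires an
explicit `units_per_day` per drug — an auditable knob rather than a silent
assumption.

**Pembrolizumab dose.** The accompanying text describes 100 mg per 21-day
cycle, but the published strategy totals (about 2.0 million RMB for the
combination over 5 years, incremental 1.25 million) are arithmetically
consistent only with roughly twice that acquisition cost — i.e. with the
200 mg flat dose the trial actually administered every 3 weeks. The shipped
fixture therefore doses 200 mg per administration
(`mg_per_administration`, a config field), favouring internal consistency
with the reported results over the stated figure.

In the progressed state, the published proportions (54.9% / 68.2% / 71%)
receive subsequent therapy billed per cycle until death, and the remainder
accrue best supportive care (353 RMB/cycle). Follow-up (474 RMB/cycle) and
hospital management (142 RMB/cycle) apply to all alive patients — the
source is ambiguous on whether management applies to both alive states; we
assume it does. Terminal care (12,721 RMB) is a one-off cost weighted by
discounted incident deaths. Grade ≥ 3 adverse events contribute a one-off
management cost and a one-off QALY loss
(disutility 0.157 × capped total incidence × 4 weeks) at model entry; the
per-event incidences are **not** published in the source input table, so the
fixture ships clearly labelled synthetic placeholders, which contribute only
a few hundred RMB and under 0.01 QALYs. The published probability of
treatment discontinuation due to adverse events is carried as a parameter
but not applied in the base case: its mechanism (a cost input? a trace
input?) is never stated, and we prefer housing the value to inventing
dynamics for it.

Utilities are 0.82 in PFS for the lenvatinib combinations, 0.73 for
sunitinib, and 0.66 in PD. QALYs are the utility-weighted discounted
occupancy; life-years use utility one.

A note on internal consistency of the published table: the reported
sunitinib QALY/LY ratio (2.13/2.83 = 0.753) exceeds the maximum possible
utility weight for that arm (0.73), so the published QALYs cannot be
reproduced exactly from the published utilities under any PFS/PD split.
Tolerance bands are therefore intrinsic to this re-implementation, not an
artefact of it.

## Sensitivity, scenario and subgroup analyses

**One-way (tornado).** Every parameter in the table is set to its low and
high bound, others held at base, and the ICER of the chosen pair recorded
(`one_way_dsa()`); bars are sorted by the ICER swing. Each table row is its
own parameter — in particular the combination-arm and sunitinib PFS
utilities vary independently, as one-way analysis implies. The range of the
table's "terminal care" row is a printing error in the source
(10,177–152,665 around a base of 12,721), as is the reversed
lenvatinib-everolimus subsequent-cost range; the fixture uses ±20% of base
and the re-ordered range respectively. On the shipped fixture the PFS
utility is the top-ranked bar, followed by the sunitinib PFS utility and
the pembrolizumab price.

**Probabilistic (PSA + CEAC).** 10,000 Monte Carlo iterations
(`run_psa()`) sample costs from gamma and bounded quantities from beta
distributions, moment-matched by reading each range as a 95% interval
(`sd = (high - low)/3.92`); the discount rate is fixed in PSA. Survival
curves stay at the base calibration — the sampled quantities are the cost
and utility parameters, so the traces are constant and each iteration is
closed-form arithmetic on the discounted occupancy aggregates. A test
verifies this fast path against the full valuation route draw-by-draw. The
cost-effectiveness acceptability curve is the fraction of iterations in
which a strategy has maximal net monetary benefit, on a WTP grid from 0 to
1,000,000 RMB/QALY in 10,000-RMB steps (covering both the 3×GDP threshold
and the region where the everolimus combination's pairwise curve
approaches 50%).

**Scenarios.** Horizons of 5, 10 and 20 years (curves fixed; the OS anchor
is a data-generating choice made once at the base discount rate and not
re-solved per scenario), reporting for the longer horizons the share of
discounted cost accrued in the first 5 years; and pembrolizumab price
reductions of 0–100% in steps, under which the ICER is affine in the price
to machine precision because only the comparator's first-line cost depends
on it.

**Subgroups.** All subgroups share the reference-arm baseline; the
comparator's curves are the reference curves raised to subgroup-specific
hazard ratios. Trial subgroup hazard ratios are not published in the source
input table, so the shipped entries are synthetic demonstrations and are
labelled as such.

## The synthetic trial generator

`simulate_arm_ipd()` stands in for trial patient data: inverse-transform
draws from true parametric curves, with one uniform draw per patient
feeding both endpoints (comonotone coupling) and PFS clipped to OS, so the
partitioned-survival constraint holds in the truth data; administrative
censoring at maximum follow-up (36 months) minus a uniform accrual offset
(12 months), with 355 patients per arm as the trial-like default.
`emit_km_artifacts()` then produces exactly the artifacts the
reconstruction consumes: the product-limit curve at its step times and
at-risk counts on a 3-month grid.

What the generator does **not** emulate: the trial's actual censoring
pattern, stratification or covariates; dependence structures other than
comonotone PFS/OS coupling; and digitization error (the emitted curve is
exact). A passing round-trip therefore shows the reconstruction inverts the
product-limit estimator faithfully, not that it is robust to sloppy
digitization — `sanitize_curve()` exists for that, and its behaviour is
tested separately.

## Numerical choices and problem sizes

* Cycle grid: `ceiling(horizon/cycle)` cycles, so the last boundary may
  overshoot the horizon by up to one cycle (5.002 years at the defaults);
  87 cycles at 5 years.
* Calibration roots are solved to `tol = 1e-10` on the engine's own grid,
  so anchors are exact under the same discretization used for valuation.
* Reconstruction: censor-count iteration is capped at 10,000 per interval;
  event rounding never loses interval totals (largest remainder).
* Fitting: `flexsurvreg` with up to three jittered restarts; convergence is
  a flag on the result, and only converged fits enter selection.
* PSA: a single user seed drives fixed substreams for simulation and PSA,
  so every artifact is bit-reproducible from one flag. Iterations with
  non-finite draws would be dropped and counted, with more than 1% failures
  an error (with gamma/beta sampling none occur).
* Test problem sizes: parameter recovery at n = 1000, the round-trip at
  n = 300, large-sample checks at n = 2000–5000, and the full 10,000-draw
  PSA — sizes chosen to make Monte Carlo assertions sharp at interactive
  runtimes.

## Known limitations

* Proportional-hazards comparator curves and single-family extrapolation
  cannot reproduce plateaus in the real curves; base-case agreement with
  the published table is band-limited by construction (the incremental
  results against sunitinib land within about 10–20%; the
  lenvatinib-everolimus ICER, a small-denominator ratio, is the most
  displaced).
* The one-way ICER interval on the fixture is wider than the published one;
  the published interval is arithmetically inconsistent with the published
  utility ranges (see the consistency note above), so it cannot be matched
  from the printed inputs.
* No vial sharing, dose reductions, reimbursement shares, tunnel states or
  background general-population mortality; none are used by the original
  analysis either.
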