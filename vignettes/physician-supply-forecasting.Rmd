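---
title: "Forecasting physician supply with a stock-and-flow model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting physician supply with a stock-and-flow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physupply)
```

## The model and its assumptions

`physupply` treats the physician workforce as a system of stocks and flows
advanced in annual steps,

$$\frac{d\,\mathrm{stock}}{dt} = \mathrm{inflow}(t) - \mathrm{outflow}(t),$$

integrated with an explicit Euler scheme at $dt = 1$ year. The choice of
annual explicit Euler is a modelling decision of this package: the source
census data are annual, every rate in the model is an annual headcount rate,
and at the workforce's scale (hundreds of thousands against per-capita
hazards near 1%) finer steps change trajectories by far less than the input
uncertainty. `dt` stays configurable on `sim_clock()` for stocks-only models;
the career-path wiring requires `dt = 1` because its conveyors are annual.

The Japanese career path is wired as six sectors
(`build_career_model()`):

1. **Enrolment** — admissions equal the government quota; domestic students
   only, and no attrition during school, so graduates in year $t$ equal the
   quota in year $t - 6$.
2. **Medical school** — a 6-year conveyor delay chain.
3. **National examination** — a gate passing a fraction $p$ (default 0.9,
   the long-run Japanese pass level). By default failures leave the system
   (*one-shot*); an optional retake pool re-sits them annually with the same
   rate. With $p \approx 0.9$ the two policies differ by well under 1% of
   inflow, which is why one-shot is the default and the toggle exists mainly
   to make the assumption testable.
4. **Clinical training** — a 2-year conveyor. The examination gate sits
   *before* training: trainees are licensed physicians. Where exactly the
   source model placed the gate is not documented; this package fixes the
   convention and records it here.
5. **Speciality choice** — applied once, at training completion, as
   fractions summing to 1. Mid-career speciality changes are folded into the
   retirement constant.
6. **Retirement** — one constant per-capita hazard per practice stock,
   aggregating retirement, death and speciality movement over the age-sex
   pyramid. Rates are assumed constant over the horizon.

**What counts as "total clinical physicians".** The aggregate reported by
`forecast_headcounts()` is the training-conveyor occupancy plus all practice
stocks, because the census that anchors the 2008 baseline (271 897) counts
licensed residents as practising physicians. Per-speciality headcounts are
practice stocks only, since speciality choice has not yet happened for
trainees. A consequence worth knowing: quota perturbations reach the *total*
after the 6-year school delay, but reach any *speciality* only after the full
8-year pipeline.

The school and training durations (6 and 2 years) describe the Japanese
system but are config-exposed on `parameter_set()`, as the source study never
printed them.

## Numerical conventions

* **Synchronous update.** All flow rates in a step are evaluated against the
  start-of-step state, then applied together. Results are therefore
  independent of flow declaration order, and runs are fully deterministic —
  the engine contains no randomness at all.
* **Non-negativity.** Outflows drawn from a stock are capped at the level
  that would empty it within the step, scaled proportionally when several
  outflows compete. Headcounts cannot go negative; in the calibrated fixture
  no stock ever approaches zero, so the clamp never binds there.
* **Conveyor initialisation.** At the base year the school conveyor is
  back-filled with the previous six admission cohorts and the training
  conveyor with the previous two graduation cohorts times the pass rate.
  Without this the first `duration` years of any run show a spurious
  ramp-up. It is also why the quota series must reach back
  `school + training` years before the base year; `run_simulation()` errors
  naming any missing years.
* **Ties and boundaries.** The sufficiency boundary is closed
  (level $\ge 1$ is *sufficient*), `crossing_year()` uses the same closed
  rule, and `rank_impacts()` breaks ties alphabetically by scenario name so
  rankings are reproducible.

## The sufficiency criterion

$$\mathrm{sufficiency}(t) =
  \frac{\mathrm{forecast}(t)}
       {\mathrm{required\ hospital\ number} \times \mathrm{corrective\ coefficient}}$$

The required number comes from a hospital-administrator survey and covers
hospitals only; the corrective coefficient corrects for the missing clinic
workforce. Two readings of where that coefficient sits are arithmetically
equivalent up to its value; this package fixes the **denominator-scaling
convention**: the effective requirement is the hospital requirement times the
coefficient, with a coefficient above 1 (the census ratio of all physicians
to hospital physicians, $1/0.615 \approx 1.63$ at the fixture's hospital
share). Keeping the coefficient as explicit data means either reading can be
expressed by supplying the matching value.

The criterion is constant over the horizon by default — it derives from a
single survey wave and cannot track changing need; `time_varying = TRUE`
exists as a hook for scenario work. A useful identity follows from
homogeneity: under a constant criterion the percentage growth of the
sufficiency level equals the percentage growth of the headcount, which is how
the growth figures in `scripts/acceptance.R` are recomputed from the two
printed anchor headcounts alone.

**Backed-out requirement constants.** The source study never printed its
required numbers or coefficient. `fixture_criteria()` therefore pins the
all-clinicians effective requirement at 341 000 — just below the calibrated
2026 forecast headcount, so the sufficiency level first reaches 1 in the
reported crossing year — and the OB/GYN effective requirement at 14 500,
which puts the 2030 OB/GYN level near 0.93, below 1 throughout the horizon
with roughly 30% growth, as reported. These constants encode the study's
*printed behaviour*, not its unpublished inputs.

## Validation statistics

Backcast fit uses per-year relative errors $e_t = |\hat y_t - y_t| / y_t$.
The aggregate "mean squared error" is ambiguous in this literature: the
literal mean of $e_t^2$ on the six published comparison pairs is about
$5.1 \times 10^{-5}$, while the published summary value 0.007 equals both the
plain mean and the root-mean-square of the $e_t$ at three decimals.
`aggregate_errors()` therefore reports all three (`mse_literal`, `rmse`,
`mean_relative_error`) instead of silently resolving the ambiguity, and
`validation_passes()` applies the customary <10% reasonableness bound to the
RMS by default. Reported error cells use R's round-half-even at 3 decimals,
matching the published presentation. Headcounts in the fixture's comparison
table are stored in thousands; relative errors are unit-free, so this is
purely presentational.

## Calibration

The study's rate inputs are unpublished, so the fixture's two behavioural
constants were fitted once, inside the package, to printed anchors:

* **Retirement hazard** (0.01382/yr): golden-section search
  (`stats::optimize`, a bounded deterministic method chosen for
  reproducibility over speed) minimising the RMS relative error of the
  1998–2008 backcast against the historic census row, with the 1998 level as
  the initial condition.
* **OB/GYN selection fraction** (0.0389): root-finding on the 2030 OB/GYN
  anchor under that hazard.

`calibrate()` exposes the same machinery generally (free parameters:
retirement rate, pass rate, an initial-stock scale; multi-parameter fits use
L-BFGS-B from the box midpoint). On synthetic worlds with known rates it
recovers a 0.025 retirement hazard to within ±0.001 even with 0.05%
multiplicative observation noise on the historic series.

One honest consequence of using a single backcast-consistent hazard: the
forward total reaches about 357 000 by 2030, a few percent below the study's
printed 370 345. No tuning was done to close that gap — the growth-identity
figures are computed from the printed anchors, and the trajectory-shape
checks (crossing window, OB/GYN shortage, scenario orderings) are robust to
it.

## The quota series

Only two quota values are printed in the source material (8 280 in 1984,
7 625 in 2007). `fixture_quota_series()` emulates the public
admission-capacity series around those anchors: flat before 1985, a linear
decline through the quota-reduction era to 2007, the post-2008 policy
increases stepping up to 9 420 by 2017, flat afterwards. The post-2008 rise
matters: it is what accelerates supply growth from the mid-2010s and gives
the ±15% quota scenarios their leverage.

## Scenarios

`scenario()` perturbs the quota multiplicatively from a start year (default:
the simulation base year — the source states no phase-in) and shifts one
speciality's selection fraction, renormalising the others proportionally.
The "±1%" speciality-choice scenario is read as ±1 **percentage point** on
the OB/GYN fraction (0.039 → 0.049), not a relative 1%, because the
companion "−2%" scenario label in the same family reads naturally as points;
`delta_mode = "relative"` expresses the other reading. Quota changes never
apply retroactively to cohorts already admitted, so their effect is delayed
by the pipeline. Scenario application is idempotent for the identity
scenario and quota multipliers compose multiplicatively.

## The synthetic-data generators

`synthetic_config()` fixes a world of the same order as the 2008 Japanese
baseline: 271 897 physicians, an OB/GYN share near 4%, a quota near 8 000
with a geometric trend, pass rate 0.9, a 61.5% hospital share, a population
of 127.7 million declining ~0.4%/yr, and a required-to-supply ratio of 1.
The census generator draws a piecewise-linear age pyramid peaking at ages
35–54 with seeded ±5% noise, then rescales each speciality-by-workplace
block so the totals and the hospital/clinic split are *exact* — the noise
shapes only the age-sex composition. All generators are pure functions of
the config and its seed, and they restore the caller's RNG state.

What the synthetic world deliberately does **not** emulate: age-specific
retirement (the aggregate hazard stands in for the whole pyramid), regional
structure and inter-regional transfers, foreign-trained physicians, demand
dynamics (morbidity, fertility), and gender-specific need. Passing tests on
synthetic data therefore demonstrate the *mechanics* — conservation, lags,
calibration recovery, criterion logic — not that real workforces follow
constant rates.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the study's
natural scale: 22-year forecasts, 10-year backcasts, a 30-year engine-audit
run, 20 calibration-recovery replicates. Everything is seconds on one CPU —
the model is six sectors, not a bottleneck.

## Known limitations

* Constant rates: the model extrapolates the calibrated hazard and the
  surveyed need unchanged to 2030; both are acknowledged simplifications.
* The criterion inherits the survey's subjectivity — administrators' claimed
  need, not a morbidity-based demand model.
* No regional dimension: shortage and maldistribution between regions are
  out of scope (a physician-transfer sector could be added to the wiring).
* The paper-internal inconsistencies noted in `?study_fixture` (the 2008
  census entry of the comparison table vs the 2008 clinical baseline; the
  printed 2008 per-capita value) are stored verbatim, not reconciled.
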