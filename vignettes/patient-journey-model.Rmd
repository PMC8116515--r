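---
title: "The T2DM patient-journey model: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The T2DM patient-journey model: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2djourney)
```

## The model

`t2djourney` is a System Dynamics (stock-and-flow) simulator of the Dutch
type 2 diabetes (T2DM) patient journey. Five population stocks are linked by
first-order flows:

* **normoglycemic** — everyone able to develop T2DM;
* **undiagnosed / diagnosed pre-diabetic** — elevated glucose below the
  diagnostic threshold, split by whether an IFG/IGT diagnosis was received;
* **t2dm** — the type 2 diabetic population;
* **no medicine necessary** — patients whose reversal programme succeeded,
  at risk of relapse.

Every inter-stock flow has the form

$$\text{rate} = \text{stock} \times \frac{\text{fraction}}{\text{average
time}},$$

with the `(fraction, avg_time)` pairs of `default_transitions()`: e.g.
diagnosed pre-diabetics progress to T2DM with fraction 0.70 over 4 years,
and 33% of the overweight normoglycemic compartment (51% of adults) starts
the journey over 3 years while only 1% of the non-overweight do so over
2 years. Mortality is a per-capita outflow at rate one over the remaining
life expectancy: 81.7 years healthy, shortened by 10 / 8 / 9 years for
undiagnosed pre-diabetes, diagnosed pre-diabetes and T2DM. A demographic
replenishment flow into the normoglycemic stock keeps the total population
exactly on the exogenous Dutch population trend; it represents births and
net migration and also replaces modelled deaths, because the exogenous trend
already nets out background mortality.

Intervention programmes add flows: a T2DM-targeted programme recruits
`min(eligible × fraction(t), capacity) / 12` persons per month (the MIN
structure of the programme submodule) and moves the successful share to the
no-medicine stock, from which 65% relapse over 2 years (5% over 10 years
after bariatric surgery) and the remainder exit to normoglycemic.
Prevention programmes recruit from the *diagnosed* pre-diabetic stock only —
undiagnosed individuals cannot be enrolled — and route successes straight to
normoglycemic without a reversal stage.

## Integration scheme

The published model was built in a visual SD environment with monthly time
steps; this package reproduces that behaviour class rather than improving
on it. Integration is fixed-step forward Euler with `dt = 1` month
(`sim_clock()`), stocks clamped at zero with every clamping event logged
(none occurs under the default parameterisation). The engine tests verify
first-order convergence against closed-form oracles (exponential decay,
two-stock transfer, logistic growth) at `dt` = 1, 0.5 and 0.25 months, and
cross-check the stepping against an independent fixed-step implementation.

**Calendar convention.** Time zero is January of the start year; yearly
outputs are the 1-January census of each calendar year, matching how
national prevalence statistics are reported. The default 1990–2035 clock
therefore takes 540 monthly steps and reports 46 yearly values, with the
1990 row equal to the initial state. Annual costs for year *y* are computed
from the census entering *y* plus programme spending committed during *y*;
this makes the activation-year economics come out right — a newly activated
programme always shows up first as an extra cost, with care savings
following in later years — which is the behaviour reported for the original
model and which an end-of-year stock basis would mask.

## Initial conditions

National statistics provide diabetes counts only from recent decades; the
run is anchored at 1990 with 160,000 DM patients, of whom 9 in 10 have type
2, so the initial T2DM stock is 144,000. (The alternative anchoring on 2011
prevalence — `initial_t2dm_fraction = 0.049 * 0.9` — is available and
documented in `journey_parameters()`.) The two pre-diabetic stocks are
seeded at the values consistent with the initial onset flow (a linear fixed
point, so the model starts without a multi-year filling transient), and the
normoglycemic stock takes the remainder: the five stocks sum exactly to the
population trend at the start year.

The default population trend interpolates the levels implied by the printed
prevalence figures — 16.0 M in 1990 (160,000 = 1%), 16.94 M in 2011
(830,000 ≈ 4.9%), 18.2 M in 2019 (1.2 M = 6.6%) — and is held flat to 2035.

## Calibrated placeholders

The original model's full parameter listing (its supplementary material) is
not publicly available. Three groups of values are therefore explicit,
tagged placeholders in the configuration (`default_config()$provenance`):

* **`fraction_developing_prediabetes` (default 0.057).** Applying the
  transition table's onset rows to the 51% overweight split would send
  ~5.9% of the normoglycemic stock into pre-diabetes per year and drive the
  T2DM stock to many millions by 2011 — an order of magnitude above the
  observed counts. The original model carries additional exogenous onset
  incidence variables (the ones its sensitivity analysis perturbs) whose
  values are in the unavailable supplement; this multiplier stands in for
  them. It was calibrated once against the five reference anchors of the
  no-intervention run — choosing the value that maximises the number of
  anchors reproduced within 20% and, among those, minimises the worst
  error — and frozen.
* **IFG/IGT incidence fractions (0.25 each).** Only their sum is
  behaviourally visible at first order; the default splits new
  pre-diabetics 50:50 into diagnosed and undiagnosed.
* **Unit costs.** Realistic Dutch orders of magnitude per component,
  scaled once so the default no-intervention run reaches ≈13 billion euros
  total annual societal cost in 2035, the headline level reported for the
  original model (treated as an *annual* figure; reading it as cumulative
  would imply implausibly small per-patient costs). The standard programme
  cost (€1,000/participant/year) is pinned by the published bariatric
  band: 17 × standard must fall within €15,000–20,000.

## Validation results and their limits

`extreme_condition_test()` reproduces the documented extremes: an emptied
system yields exactly zero T2DM-attributable cost at every year, and a
100-million-patient stock stays finite, non-negative, costs on the order of
a trillion euros annually and scales costs exactly linearly.

`sensitivity_analysis()` perturbs parameters one at a time (±10% by
default; the original perturbation size is unstated) and reports per-stock
elasticities. Under the defaults the overweight-onset fraction has by far
the largest influence on the T2DM stock (mean |elasticity| ≈ 0.86),
consistent with the original model's finding that the overweight/obesity
onset fraction dominates.

`behavior_reproduction()` compares the no-intervention run with the
text-printed anchors, mapping count anchors to the simulated T2DM stock
divided by 0.9 (the anchors count all diabetes). With the default
calibration the 1990, 2011, 2014 and 2019 anchors are reproduced within
20% (MAPE ≈ 13%); the 2018 count anchor misses at −21.7%. This residual is
structural, not a calibration shortfall: the 2018 count (1.2 M DM ⇒ T2DM ≥
864k at −20%) and the 2019 prevalence (4.0% ⇒ T2DM ≤ ~874k at +20%) can
only both be met if the stock is essentially flat across 2018–2019, while
clearing the 2014 prevalence cap requires growth of ~20k/yr up to 2018.
With constant exogenous drivers a first-order model grows near-linearly,
so the minimum attainable worst-case anchor error is ~21% — the two
anchors describe different statistical definitions and are mutually
inconsistent at this tolerance.

## Scenario experiments

`load_preset()` returns the published policy experiments verbatim
(activation January 2020): bariatric surgery (28% recruited yearly, 95%
success, 17× cost, 5%/10 y relapse), ReverseDiabetes2Now (0.002 recruited
ramping linearly to 0.30 over 10 years, 28% success), and three
hypothetical T2DM/pre-diabetes programme combinations. Where the source's
running text and its policy table disagree (policy 4's success rate,
policy 5's multiplier) the table is authoritative and the text variants
ship as `policy4_narrative` / `policy5_narrative`. The pre-diabetes
programmes of policies 4–5 use step activation; a ramp was described only
for ReverseDiabetes2Now.

Two qualitative findings of the original study reproduce robustly: every
activated programme weakly lowers the T2DM trajectory from activation
onwards while incurring an extra cost in its activation year, and raising
the relapse fraction from 0.05 to 0.65 weakly raises the T2DM stock
throughout. One does not: in this parameterisation the bariatric scenario —
recruiting 28% of the *entire* T2DM stock every year at 95% success and 5%
relapse — ends 2035 with the lowest stock and cost, below the combined
lifestyle programmes (policies 4–5) that the original study ranks most
effective. With programme costs pinned near €1–3k/recruit by the bariatric
band and care costs near €11k/patient-year by the 13 B€ calibration,
annual care savings dominate programme spending for any high-throughput
programme; recovering the original ranking would require the unavailable
cost parameterisation (or an eligibility model in which only the BMI > 35
subgroup can ever be recruited). The discrepancy is asserted, not hidden,
in the test suite.

## Numerical choices and degenerate inputs

* All rates are per month; year-denominated parameters are divided by 12
  at the point of use.
* The "total persons becoming pre-diabetic" junction is instantaneous: the
  onset flow splits into diagnosed/undiagnosed in the same step, keeping
  the transition table's delays authoritative.
* Recruitment is additionally capped at the eligible stock, so a step can
  never drain more than a stock holds; relapse parameters for the shared
  no-medicine stock come from the single active T2DM-targeted programme,
  and configurations with conflicting relapse parameters are rejected.
* Deaths from the no-medicine stock use the healthy life expectancy (the
  source assigns shortenings only to the three disease states).
* Recovered individuals re-enter the normoglycemic pool
  indistinguishably and can be recruited again immediately.
* An infinite `healthy_life_expectancy` disables mortality (used by the
  closed-world oracle tests); a zero population trend yields an exactly
  empty, zero-cost system.
* Population conservation — stocks + cumulative deaths − cumulative
  demographic inflow — holds to ~10⁻⁸ persons over the 45-year run at
  18-million scale (double precision; no clamping under defaults).

## Problem sizes

Default runs integrate 5 stocks over 540 monthly steps; the full test
suite, including every preset, the sensitivity sweeps and the convergence
studies, executes a few dozen such runs. Those sizes were chosen because
the published study horizon (1990–2035, monthly) *is* the production
problem size — there is nothing to scale up.

## Known limitations

No age/sex/education stratification (the source model also excludes it),
no complicated/uncomplicated T2DM split, no discounting or QALYs, no
stakeholder budget constraints, exponential residence times rather than
explicit aging chains, and full employment of all patients is assumed in
the cost submodule. The synthetic demographic series hold the overweight,
obese and elderly fractions constant; real series drift, which the
behaviour-reproduction analysis above suggests is one reason the late-2010s
anchors cannot all be matched by a constant-driver model.
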