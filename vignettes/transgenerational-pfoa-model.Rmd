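---
title: "A transgenerational toxicokinetic model for PFOA water guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A transgenerational toxicokinetic model for PFOA water guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfastk)
```

## The model and its assumptions

`pfastk` simulates serum concentrations of perfluorooctanoate (PFOA) in a
mother–infant pair exposed through drinking water, with a one-compartment
model stepped daily. The compartment is extracellular fluid: serum
concentration `C` (mg/L) over a volume `Vd × BW`, with `Vd = 0.17` L/kg.
Elimination is first order, `k = ln(2) / t½`. Each simulated day the
intake mass is added to the compartment and elimination is then applied:

`C(t) = [C(t−1) + intake_mg / (Vd_eff × BW)] · exp(−k)`.

This intake-then-eliminate order is the literal reading of the daily
update formula; its discrete steady state under constant dosing differs
from the continuous closed form `dose / (Vd·k)` by about `k/2` (0.04% at
the default half-life), which is why the simulator-versus-closed-form
tests use a 0.5% tolerance.

Assumptions inherited from the model design:

* The mother has been exposed since before pregnancy long enough to be at
  steady state at delivery. Her pre-delivery serum is the closed-form
  steady state of her lifetime-average water intake.
* Placental transfer is instantaneous at birth: the infant starts at the
  maternal serum times the placental factor (0.87 central, 1.69 upper).
* Breastmilk concentration is proportional to the *start-of-day* maternal
  serum (milk:serum factor 0.052 central, 0.12 upper). Which end of the
  day the original spreadsheet used is not documented; the start-of-day
  choice is marginally conservative (milk is computed before that day's
  maternal depletion) and is pinned by the cross-implementation oracle
  tests.
* Mass balance: the milk-borne mass the infant ingests on a day is debited
  from the maternal compartment the same day, so milk concentration
  declines over lactation.
* Maternal exposure during lactation continues unchanged from before
  delivery. Operationally her daily dose is her current serum times the
  clearance rate (times body weight) — the dose that would exactly sustain
  a steady state — so her serum declines only through the mass exported in
  milk. The alternative reading (dose frozen at the delivery-day value)
  yields six-month milk-concentration declines of about 37% and 49% for
  the mean and upper intake tiers where the current-serum reading yields
  about 39% and 53%; the latter pair matches the declines the model is
  documented to produce (40% and 52%), so the current-serum form is used.
* One half-life across all life stages; no renal-maturation scaling, no
  enterohepatic recirculation, single offspring, no second pregnancy.

## Parameters

All defaults live in `default_parameter_library()` in two tiers, central
(mean) and upper (~95th percentile):

| parameter | units | central | upper |
|---|---|---|---|
| half-life `t½` | days | 840 | 1679 |
| volume of distribution `Vd` | L/kg | 0.17 | (same) |
| placental transfer | infant:maternal serum | 0.87 | 1.69 |
| breastmilk transfer | milk:maternal serum | 0.052 | 0.12 |
| breastmilk intake | mL/kg/day by age | 150–83 | 220–130 |
| water intake | mL/kg/day by age | 137–16 | 238–42 |
| breastfeeding duration | — | 6 mo + phase-out to 12 | 12 mo exclusive |
| maternal body weight | kg | 76.7 | 73.6 |

The `Vd` age-adjustment factor (2.4 at birth declining to 1.0 by age 10)
multiplies `Vd` in the intake term, reflecting the higher body-water
fraction of infants; it is defined in a single (central) series.

Age schedules are piecewise linear with anchors at the arithmetic midpoint
of each published age group, constant beyond the first and last anchors.
Midpoint anchoring follows the documented convention of the source tables;
the exact anchor days are not published, so two low-level conventions had
to be fixed once: a month is 365.25/12 = 30.4375 days and a year 365.25
days, and open-ended groups (">21 years", ">10 years") are anchored at
their lower bound. The milk-tier body-weight series starts at the 3.38 kg
mean singleton birth weight.

The maternal steady state uses the time-weighted average of the water
intake schedule from birth to age 30 — the documented averaging window is
"30–35 years of age" without a fixed endpoint, and the start of that range
matches a mother at typical childbearing age while being the (slightly)
more conservative choice. The schedule integrals reproduce the reported
rounded averages of 18 and 47 mL/kg/day; the simulator uses the unrounded
integral (18.28 / 48.06).

Maternal body weight is the adult (">21 years") value of the water-intake
table for the matching tier; no separate maternal weight is published.

## Scenarios

`rme_formula()` and `rme_breastfed()` are the reasonable-maximum-exposure
scenarios (upper intake and duration, central chemistry). Formula-fed
infants drink formula reconstituted with tap water from day 1, at the
water-intake schedule; there is no separate formula-powder term. In the
central duration tier, milk intake ramps linearly to zero between months 6
and 12 while water intake ramps in complementarily (the published
description says "phased out ... phased in" without a functional form;
linear is the minimal choice). Body weight blends from the milk-based to
the water-based series with the same ramp. In the upper tier breastfeeding
is exclusive through day 365 and water begins the following day.

`alternative_scenarios()` carries the three published alternative tier
combinations. A caveat this package makes explicit: binding the tier
selections consistently to both mother and infant means an upper-tier
half-life halves the clearance and therefore doubles the maternal steady
state, so alternatives combining an upper half-life with upper intake
exceed the RME peak rather than falling below it. The published
sensitivity comparison evidently configured its runs differently (in a way
not recoverable from the published description); the acceptance tests
compute and document this divergence rather than masking it.

## Guidance derivation

The chain is: point-of-departure serum 38 mg/L ÷ uncertainty factor 300 →
reference serum 0.13 mg/L (2 significant figures); × 0.8 decision-tree
ceiling − 0.00557 mg/L biomonitored background → residual 0.0984 mg/L
(~75% of reference), supporting a relative source contribution band of
50–80%, of which the conservative floor 0.5 is selected → 0.065 mg/L
allocated to water. `solve_hbgv()` exploits the exact linearity of the
kinetics in the water concentration — the solution is
`target / peak(1 µg/L)` — and verifies it by bisection on the full
simulator (tolerance 1e-6 µg/L, far below reporting precision). Reported
guidance values are rounded *down* to two significant figures, applied
only at the reporting boundary, so the rounded concentration still meets
the serum target; whether rounding preceded the protectiveness check in
the original derivation is undocumented, and rounding down is the
conservative resolution.

## Evaluation workflows and the fixture generator

`predict_infant_serum()` and `predict_from_birth_serum()` reproduce the
cohort-comparison setup: maternal serum at delivery is taken as measured
(or back-calculated from infant cord serum via the placental factor), the
coupled lactation simulation runs with no water term, and infant serum is
read at the follow-up age. Following the documented individual-evaluation
protocol, the upper-percentile milk intake schedule is the default for
birth-serum-initialised predictions and is used for the whole period.

Digitised per-infant values from the published cohort figures are *not*
bundled — figure digitisation is not reproducible input. Instead
`generate_fixture()` produces synthetic paired tables: lognormal maternal
serum, model-predicted six-month infant serum, multiplicative lognormal
measurement noise (default CV 0.3, geometric SD 1.8 for mothers, n of
order 14, mimicking the scale of the real paired cohorts). What passing
fixture-based tests show is that the regression-agreement machinery
recovers known truth under realistic noise — not that the model fits any
particular real cohort; the package's cohort-level checks are the
population-mean predictions, which run ~10% above the originally reported
values under the midpoint-anchor convention (the predicted
mean:95th-percentile *ratio* matches to 0.1%, so the residual is a single
common scale factor attributable to unpublished schedule-anchor details).

## Numerical choices and problem sizes

* Internal units mg, L, kg, day; water µg/L is converted once on entry.
* Lifetime horizon 20,000 days (~55 years), long enough that the terminal
  serum sits within 0.1% of the adult plateau; evaluation runs use
  month-scale horizons (serum is read mid-lactation, so a short horizon
  simply truncates the breastfeeding window).
* The maternal series is computed in closed form as a cumulative product
  (her dynamics are autonomous), and the infant recurrence as a linear
  recursive filter; both are algebraically identical to the day-loop and
  are cross-checked against an independent row-by-row implementation to
  1e-9.
* Degenerate inputs: zero water and zero maternal burden give an exactly
  zero system; zero breastfeeding duration makes the breastfed and
  formula-fed scenarios identical; a zero milk-transfer factor makes the
  milk-decline metric undefined and raises an error rather than returning
  0/0.

## Known limitations

* Single compartment, one half-life for all ages; no probabilistic tier
  sampling; linear phase-out only.
* The alternative-scenario tier semantics diverge from the unpublished
  original configuration (see above).
* Population-level cohort predictions carry the ~10% anchor-convention
  uncertainty described above.
* Only PFOA parameter values are shipped; the structures accept other
  bioaccumulative PFAS but no defaults are provided for them.
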