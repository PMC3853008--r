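---
title: "Projecting diabetes prevalence under prevention policies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting diabetes prevalence under prevention policies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucostate)
```

## The model

`glucostate` projects the US adult diabetes epidemic with a discrete-time
multistate model.  The population is partitioned into five glucose-tolerance
states — normal glycaemia, IFG without IGT, combined IFG and IGT,
undiagnosed diabetes, diagnosed diabetes — and advanced annually by

$$N(t) = N(t-1)\,P(t) + B(t) + M(t),$$

where $N(t)$ is the row vector of state counts (millions) at the start of
year $t$, $P(t)$ the one-year transition matrix, $B(t)$ the inflow of new
adults and $M(t)$ net migration.  Three structural assumptions shape
$P(t)$:

1. **No remission.**  No transition leaves a diabetes state except death,
   and diagnosed diabetes is absorbing up to death.
2. **Constant mortality relative risks.**  Each state's annual death
   probability is a common base rate times $(1, 1, 1, 1.77, 2.11)$; each
   row of $P(t)$ sums to one minus that state's death probability.
3. **Time-constant rate ratios.**  The incidence, progression and
   detection probabilities are constant over time (up to the optional
   background trend and the intervention multipliers), so the
   diabetes-entry probabilities remain constant multiples of the
   undiagnosed-to-diagnosed detection probability.

The non-zero flows are: progression NORMAL → IFG-only and IFG-only →
IFG+IGT; diabetes incidence out of each non-diabetic state, split between
the undiagnosed and diagnosed states by the diagnosed-at-onset fraction;
and detection of undiagnosed diabetes.  Regression transitions (IFG+IGT →
IFG-only, IFG-only → NORMAL) are not modelled: they are not needed to
reproduce the anchor trajectories, and including them would add
unidentifiable parameters.

Reported quantities follow a fixed timing convention: the state vector is
recorded at the start of each calendar year, and incident cases "in year
y" are the diabetes inflow of the transition $N(y) \to N(y+1)$.  The
cumulative incidence reported for year $y$ therefore sums transition years
from the model start through $y$ inclusive, which matches how the anchor
tables pair a non-zero first-year cumulative incidence with an unchanged
first-year prevalence.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `lambda_normal` | diabetes incidence from NORMAL | 0.003 | /yr |
| `lambda_ifg` | diabetes incidence from IFG-only | 0.024 | /yr |
| `lambda_ifgigt` | diabetes incidence from IFG+IGT | 0.039 | /yr |
| `rr_undiag`, `rr_diag` | mortality RR vs no diabetes | 1.77, 2.11 | — |
| `detection_rate` | undiagnosed → diagnosed | solved | /yr |
| `diagnosed_at_onset_fraction` | incident cases entering DIAG directly | solved | — |
| `prog_normal_to_ifg`, `prog_ifg_to_ifgigt` | prediabetes progression | solved | /yr |
| `incidence_growth` | background trend multiplier | 1.0 | /yr |

The incidence and mortality values are survey- and literature-based point
estimates; the "solved" rates are not observed and are derived by
calibration (next section).  The published population-average incidence of
1.22%/yr is treated as a validation check only: the weighted average of
the stratum rates over the starting prevalences is about 1.09%/yr, and no
weighting of the printed inputs reproduces 1.22% exactly, so fitting to it
would distort the stratum rates that *are* printed.  The calibrated model
is required only to start within the bracket 1.0–1.3%/yr.

## Calibration

Everything the published record leaves implicit is derived from printed
quantities, in five steps (`calibrate_model()`):

1. **Population targets.**  Census-consistent totals are back-derived at
   six anchor years as prevalent count ÷ prevalence rate (e.g. 27.8/0.129
   = 215.5M in 2007, 60.7/0.227 = 267.4M in 2030), with geometric
   interpolation between anchors.
2. **Initial state.**  The 2007 prevalences (diabetes 12.9%, IFG any
   26.7%, IFG+IGT 8.3%) allocate the 2007 total; total diabetes is split
   diagnosed/undiagnosed by a configurable share, default 0.718 — the
   ratio implied by the projected 2030 diagnosed (16.3%) and total (22.7%)
   rates, which the model holds approximately stable, making it the best
   available estimate for 2007, where the split is not printed.
3. **Detection and onset.**  The detection rate and diagnosed-at-onset
   fraction are chosen so the diagnosed share of total diabetes stays
   within ±0.02 of its target across the horizon.  These two rates trade
   off along a near-stationary ridge (a higher onset fraction can
   substitute for faster detection); the solver minimises the summed
   squared deviation of the share trajectory with `optim` (L-BFGS-B, fixed
   start), which selects one ridge point deterministically.  Any point on
   the ridge yields the same projected totals to well within reporting
   precision.
4. **Progression.**  The two progression probabilities are solved so the
   IFG-only and IFG+IGT shares of the non-diabetic population drift as
   little as possible (quasi-stationarity, enforced at under 10% relative
   drift).  This encodes the assumption that the prediabetes risk-stratum
   mix was approximately in equilibrium at baseline.
5. **Base mortality.**  Entrant flows are exogenous: 4.2M new adults per
   year (approximately the number of US residents turning 20 over the
   horizon), entering the NORMAL state, plus 1.0M/yr net migration
   allocated proportionally to the current state mix.  Given those flows,
   the base death rate of each transition year is solved in closed form so
   the no-intervention totals hit the targets exactly:
   $b(y) = \big(\mathrm{total}(y) + B(y) + M(y) - \mathrm{target}(y+1)\big)
   / \sum_s N_s(y)\,rr_s.$
   The solved rates come out at 0.96–1.13%/yr, consistent with US adult
   crude mortality, which is an independent plausibility check on the
   entrant-flow choice.

Steps 3–4 are weakly coupled and iterated to a joint fixed point
(tolerance $10^{-6}$ on the solved rates; convergence takes 2–3 sweeps).
The census constraint binds the no-intervention run only: intervention
runs reuse the baseline's solved mortality schedule and entrant flows, so
their totals float slightly upward as deaths are averted — the behaviour
implied by the anchor tables themselves, where the intervention runs'
count/rate ratios exceed the baseline total.

## Scenarios and comparison metrics

Interventions act multiplicatively on the incidence probabilities from the
first projected transition onward: $(1-e_T)$ in the targeted states for
the lifestyle strategies ($e_T = 0.125$ by default, the rule-of-halves
product $0.5^3$), $(1-e_P)$ in every non-diabetic state for the
population-wide strategy ($e_P = 0.02$), and both multipliers composed for
the combined strategy.  Probability mass freed by an intervention returns
to the diagonal — people who do not convert stay in their current state
and remain at risk, which is why long-run prevented cases are smaller than
the naive sum of annual incidence reductions.  Prevented incident cases
are differences in cumulative incidence at the horizon; prevented
prevalent cases are differences in the horizon-year diabetes stock;
relative attenuation is $100(\Delta_{none}-\Delta_{s})/\Delta_{none}$
applied to the 2007–2030 change in prevalence rate (headline) or count.

The increasing-incidence background scenario uses a constant annual
multiplicative trend on all incidence probabilities, calibrated by
root-finding so the no-intervention horizon prevalence rate rises 3.5
percentage points (the midpoint of the stated three-to-four-point range)
above the flat-trend projection, with base mortality re-solved against the
same population targets.  The structural rates from the flat calibration
are retained.

## Uncertainty propagation

A full Monte-Carlo sweep of the projection under parameter uncertainty is
deliberately out of scope; instead the package emulates the model.
`design_runs()` executes the projection over a design of effectiveness
values — five log-spaced points spanning half to double the base case per
active predictor, crossed factorially for the combined family — recording
the horizon prevalence reduction $y$.  `fit_emulator()` fits
$y = \beta_0 + \beta_1 \ln x_1 + \beta_2 \ln x_2$ by OLS; on the default
designs the surface explains over 95% of run variance, comfortably above
the 0.85 the method needs to be credible.  `propagate()` then draws the
effectiveness values from subjective distributions — by default lognormal
with median at the base case and 2.5th/97.5th percentiles at half and
double, mirroring the sensitivity-analysis bounds — adds residual noise
(so the interval covers the model output, not merely its conditional
mean), and reports empirical 2.5/97.5 percentiles truncated below at zero,
since an intervention is not allowed to be reported as increasing
prevalence.  Sampling is seeded and bit-reproducible.

## Synthetic data

The generators in `synthetic_spec()` stand in for the census and survey
inputs during testing: geometric population growth with multiplicative
lognormal noise (positive support, scale-free — the natural noise model
for counts), entrant flows consistent with the totals at a nominal crude
death rate, and multiplicative jitter on parameters (with the incidence
ordering enforced by rejection) and starting shares.  They emulate the
*aggregate* inputs only: no age structure, no survey microdata, no
sampling design.  Passing the recovery tests therefore shows that the
calibration solvers invert the model's own dynamics reliably, not that the
model is correctly specified for real surveillance data.

## Numerical choices

* Population conservation holds to $10^{-9}$ relative by construction and
  is asserted in tests.
* Transition-matrix diagonals within $10^{-12}$ of zero are clipped to
  zero; genuinely negative diagonals (over-specified outflow) raise an
  error rather than being renormalised.
* The base death rate must stay in $[0, 0.1]$; demography implying rates
  outside that range is rejected as infeasible.
* Calibration solvers use `optim` (L-BFGS-B) from fixed starting values
  and `uniroot` to $10^{-8}$; no randomness enters calibration, so
  calibrated models are bitwise reproducible.
* Problem sizes: a 24-year, five-state annual recursion (milliseconds per
  run); 5–25 runs per emulator design; 10,000 Monte-Carlo draws per
  credibility interval.  The full test suite runs in about a minute on one
  CPU.

## Known limitations

* No age, sex or race/ethnicity stratification: a single homogeneous adult
  population, so cohort-driven effects (e.g. ageing of high-incidence
  cohorts) enter only through the calibrated anchors.
* Mortality relative risks and (in the flat scenario) incidence rates are
  constant; declining diabetes mortality would raise prevalence above
  these projections.
* Intervention effectiveness is a constant multiplier with no uptake
  dynamics, waning, or cost dimension.
* The entrant-flow split (births vs migration) is a modelling choice
  constrained only by totals and plausibility; it shifts the solved base
  mortality within a narrow band but leaves the headline projections
  essentially unchanged.
* The diagnosed/undiagnosed split of the 2007 diabetes pool is inferred,
  not observed; it is exposed as a configuration knob
  (`diagnosed_share_of_dm`).
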