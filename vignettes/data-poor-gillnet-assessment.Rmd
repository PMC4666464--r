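---
title: "Methods: from derelict gear to overexploitation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from derelict gear to overexploitation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gillnetr)
```

`gillnetr` quantifies an illegal gillnet fishery from three kinds of
evidence — derelict gear on shorelines, a small multi-mesh gillnet
monitoring program, and life-history parameters — and chains them into a
data-poor assessment of whether plausible local effort could overexploit
the target stock. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was open.

## Derelict-gear densities

Transect widths vary with beach morphology, so densities are linear: items
per km and grams per km of censused shoreline. `pooled_density()` weights
per-transect densities by transect length, which is algebraically identical
to total items over total kilometres; the identity is exercised as a
property-based test over random transect splits. Items that could be
ordinary litter (bottles, string/rope, stakes) count as fishing gear only
when they carry mesh, floats, weights, or line (`classify_gear()`); items
without a weighed mass contribute to count densities and are excluded from
weight densities with a logged count. Mesh composition uses half-open 1-cm
bins spanning 2–8 cm by default, the range over which gillnet mesh is
observed in this kind of fishery; edges are configurable.

Re-accumulation (`accumulation_change()`) compares per-site densities
between a cleanup survey and a resurvey. A ratio with a zero baseline is
reported as a flagged missing value, never infinity, so one empty site
cannot poison a summary. Because the surveys do not control for habitat or
exposure covariates of stranding, re-accumulation is an index of continued
fishing, not an absolute deposition rate.

## CPUE and mixed-model trends

Effort is counted in net-nights: an overnight soak of 8.5–10.5 hr is one
night, because nets fish mostly while fish are active and soak-hour
differences of this size are noise. Panel CPUE is standardized to 10 m of
net per night; set CPUE is the total across the five panels per net-night.
Zero-catch panels and sets are retained as zeros — dropping them would bias
both mesh comparisons and trends. `optimal_mesh()` averages panel CPUE by
mesh and breaks exact ties toward the smaller (cheaper, more commonly used)
mesh.

Missing fish weights are imputed from the species' fitted allometry
`w = a·l^b` (`fit_length_weight()`, a log-log least-squares fit requiring
at least three weighed fish). Imputed weights enter biomass CPUE but are
excluded, via their flag, from body-size trend input by default: testing a
body-size trend on weights predicted from lengths would partly recycle the
allometric fit.

Trends are linear mixed models fit by maximum likelihood with `lme4`:
`response ~ year + (1 | site)` against the null `response ~ 1 + (1 | site)`,
compared by a likelihood-ratio test on 1 df. Full ML (not REML) is used
because the fixed effects differ between the nested models. Year is centred
at the first survey year for conditioning; the slope and p-value are
invariant to this. The same machinery serves abundance (set CPUE as the
response, on the raw scale on which such data are plotted; a `log1p` option
exists for robustness checks) and body size (individual lengths or
weights). With a single site the model degrades to a fixed-intercept fit
with a warning. A constant response short-circuits to slope 0, LR 0, p = 1
rather than asking the optimizer to fit a zero-variance model. Simulation
under the default design (7 sites × 4 years × 2 nets, Poisson counts)
puts the LR test's type-I error near 0.06 at α = 0.05 — the small-sample
anticonservatism expected of 1-df LR tests on 56 observations — and
slope confidence intervals achieve close to nominal coverage.

## The assessment chain

Growth is von Bertalanffy, `L(t) = L∞(1 − e^(−K(t−t₀)))`, fit by
Levenberg–Marquardt nonlinear least squares; `anchor_origin = TRUE` fixes
`t₀ = 0` so the curve passes through the origin, the convention when ageing
data lack small fish. Lengths are mm for fish and cm for `L∞`; converters
are explicit and logged, never silent, because the Pauly-type mortality
formula is calibrated in cm.

Total mortality comes from a length-converted catch curve: lengths are
binned (10 mm default), bin midpoints converted to relative ages by
inverting the growth curve, and `ln(count/Δt)` regressed on age over the
trailing arm. The `Δt` divisor corrects for a fixed length bin spanning
more time at old ages. The trailing arm is defined as bins strictly after
the modal bin, excluding empty bins and — when a maximum age is known —
bins whose midpoint age exceeds `0.95·t_max`, where the near-asymptotic
conversion is unstable; lengths at or above `L∞` have no defined age and
are dropped with a message. On exactly exponential bins the estimator
returns Z to machine precision; composed with the population simulator at
Z = 0.42 and n = 5,000 it is unbiased to within 0.02 across seeds.

Natural mortality uses three life-history invariants (longevity, growth,
and reproductive investment): `M = 4.899·t_max^−0.916`,
`M = 4.118·K^0.73·L∞^−0.33` (L∞ in cm), and `M = 1.79·GSI`. Then
`F = Z − M` (negative values flagged, not truncated),
`F_MSY = 0.87·M`, `MSY = (1 − e^(−F_MSY))·B` with `B` the product of areal
biomass density and habitat area, and the effort columns follow by
division: nights = MSY / catch-per-night, fishers = nights / nights per
fisher-year, percent of families = 100 · fishers / (population / household
size). These are static, equilibrium approximations: no recruitment
dynamics, no selectivity in the yield calculation, no propagation of the
biomass estimate's uncertainty. They bound the problem; they do not replace
an age-structured assessment.

All chained computations keep full precision; display rounding
(`format_assessment()`: rates to 2 decimals, yields and nights to whole
numbers, fishers and percentages to 1 decimal, half-up) happens only at
report time. This matters: rounding M to two decimals before the chain
shifts MSY by about a percent, so a table recomputed from printed
2-decimal rates will reproduce printed effort columns only when each row's
published yield is taken as the input — the package supports both routes
and the tests treat the rounded-input route as approximate. Families are
carried unrounded (population/household, e.g. 1511.1) through the percent
computation; both conventions agree at display precision.

The spawning-run calculator (`spawning_run_removal()`) is deliberately
plain arithmetic over a reported period structure (days × daily removals
per period) and reports a low–high envelope plus a chosen point; it never
asserts a headline figure the arithmetic cannot produce.

## What the simulators emulate

`simulate_population()` draws ages from the truncated exponential implied
by constant total mortality on `[recruit_age, t_max]` and lengths as the
growth-curve mean times lognormal noise. Defaults describe the package's
illustrative grayling: `L∞` = 40 cm, K = 0.127/yr, t₀ = 0, t_max = 17 yr,
GSI = 0.1676, recruitment at age 2, and a length-at-age CV of 0.08 —
mid-range for salmonids. `simulate_catch_survey()` layers a log-linear
abundance model (intercept, year slope, Gaussian site intercepts) over a
sequential-mesh design (2 nets × 7 sites × 4 years, five 4-m panels of
2.54–7.62 cm mesh), allocates expected catch across panels by a lognormal
selectivity curve peaking at `sel_mult` × mesh (110 mm/cm by default, so
the smallest mesh peaks near the simulated modal length of 280 mm — the
standard unimodal gillnet selectivity shape), and draws counts as Poisson
(negative binomial optional for overdispersion). `simulate_debris()` is
Poisson in transect length with a categorical mesh mixture.

What they do not emulate: spatial structure within sites, movement,
recruitment variability, multi-year feedback of fishing on the population,
saturation of nets, or habitat-driven debris stranding. Passing tests on
synthetic data therefore demonstrate that the estimators recover the
parameters of their own assumed data-generating process — a necessary
check, not evidence about any particular lake.

Seeds are explicit arguments everywhere and never touch the caller's RNG
state; a fixed seed fixes every emitted table exactly.

## Problem sizes and numerical choices

The test suite uses n = 10⁵ draws for distributional checks of the
simulators, 200 replicates for estimator-recovery and coverage checks,
1,000 replicates for the trend test's null calibration, and 100 random
cases for the pooled-density property; `scripts/acceptance.R` uses 100
populations of 5,000 fish for the total-mortality recovery. These sizes
give Monte Carlo standard errors comfortably inside the asserted
tolerances. Ties in `optimal_mesh()` and the modal bin of the catch curve
resolve to the first (smallest) candidate; `round_half_up()` adds a
half-ulp guard so values like 186.35 stored just below the half round up as
intended.
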