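---
title: "Methods: demographic forecasting, pandemic jumps and the PAYG balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic forecasting, pandemic jumps and the PAYG balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paygsim)
```

## Scope and data model

`paygsim` projects the annual balance of a pay-as-you-go pension scheme —
contribution income minus pension expenditure — over an 80-year horizon,
with and without recurrent pandemic mortality shocks. Everything runs on
one fixed age classification: 24 groups (0, 1–4, 5–9, ..., 105–109,
110+), indexed 1..24, with fertility defined on groups 5..11 (ages
~16–50), workers on groups 6..14 (20–64) and pensioners on groups 15..24
(65+). Group midpoints (0, 2.5, 7, ..., 107, 110) serve as the age grid
wherever a continuous age axis is needed. Migration is deliberately out of
scope: flows are volatile, hard to forecast, and excluded from the
projection model.

## The functional demographic model

Observed log rates are modelled as a smooth age curve plus observational
noise, and the smooth curves as a mean plus a low-rank expansion:

$$y_t(x) = f_t(x) + \sigma_t(x)\,\varepsilon_{t,x}, \qquad
  f_t(x) = \mu(x) + \sum_{k=1}^{K} \beta_{t,k}\,\phi_k(x) + e_t(x).$$

Design choices, in the order the pipeline applies them:

* **Smoothing** (`smooth_surface()`): a weighted penalized cubic smoothing
  spline per year over the group midpoints, penalty chosen by generalized
  cross-validation (`stats::smooth.spline`). Weights default to uniform
  and can be set to exposures. A numeric `smoothness` overrides GCV; `0`
  interpolates, which the tests use to feed exact surfaces through the
  pipeline. $\sigma_t(x)$ is estimated from the degrees-of-freedom
  corrected residual spread per year.
* **Zeros**: fertility rates at the extreme groups can be 0; log rates are
  computed as $\log(r + \delta)$ with $\delta$ = half the smallest
  positive observed rate (0 when all rates are positive). An all-zero row
  is an error rather than a silent fill.
* **Decomposition** (`fit_functional_model()`): $\mu(x)$ is the per-group
  mean of the smoothed curves; $\phi_k$ and $\beta_{t,k}$ come from the
  singular value decomposition of the centered surface, so the basis is
  exactly orthonormal, the scores have zero mean, and
  `var_explained[k]` is the normalized squared singular value. The SVD's
  sign ambiguity is resolved by making each $\phi_k$'s
  largest-magnitude element positive — repeated fits are bit-identical.
  K = 4 for mortality and K = 3 for fertility by default; both kinds run
  through the identical code path.
* **Score forecasting** (`forecast_scores()`): random walk with drift per
  component by default — drift = mean increment, step-h forecast variance
  $s^2 h (1 + h/(n-1))$ — which reproduces the dominant declining first
  score of both mortality and fertility. A mean model and a small
  AIC-selected ARIMA grid are available; the chosen model is recorded per
  component.
* **Intervals** (`forecast_rates()`): 90% bounds on the log scale combine
  the score forecast-error variance through $\phi_k^2$, the basis residual
  variance $v(x)$, and — switchable, on by default — the observational
  noise $\sigma^2(x)$; whether observational noise belongs in the
  prediction interval is genuinely ambiguous, hence the
  `include_obs_noise` flag. Mortality forecasts are capped just below 1
  after back-transform so they remain probabilities.

## Pandemic mortality jumps

A pandemic is a deterministic 2-year multiplicative shock to deaths.
Calibration (`calibrate_jumps()`) divides the reference event's death
counts in pandemic years 1 and 2 by the average death count over the four
preceding years ("smoothed" baseline; the plain mean is the minimal
reading, switchable by supplying a different window). The per-group,
per-gender ratios are applied to projected rates as
$q^* = \min(q \cdot r, 0.99)$: multiplying the death probability by the
death-count ratio assumes the within-year exposed population is unchanged
to first order, which is the simplest faithful rate-space translation of a
death-count adjustment. Two conventions are worth flagging:

* the year-2 ratio divides by the same pre-pandemic baseline as year 1
  (not by a re-smoothed year-1 level) — followed literally;
* the cap binds only the jump: an unjumped rate is never pulled down to
  0.99, so a size-0 scenario is bit-identical to the no-pandemic run
  (a property the acceptance tests check).

Jump sizes scale through the *excess*: $r_s = 1 + s(r - 1)$, floored at a
small positive value, so "doubled jumps" means doubled excess mortality,
$s = 0$ means no pandemic. The calendar defaults to onsets every 20 years
(2041, 2061, 2081). A constant annual jump probability of 0.0436 from the
actuarial literature motivates the 20-year recurrence; the package
implements the deterministic calendar, not a stochastic process.

## Population projection

Projection advances single ages yearly inside 5-year steps
(`advance_population()`). With $m = -\ln(1 - q)$ the central death rate of
a group, a cohort at age $a$ survives the year with factor $(1 - m)$ of
the group containing $a$. Note $(1-m) \neq e^{-m}$: the package defaults
to the $(1-m)$ factor of the grouped cohort-component formulation it
implements, and `survival = "exact"` switches to $e^{-m}$; the two agree
to first order in $m$. Under the default, groups
with $q > 1 - 1/e$ (only the very oldest) get negative factors that are
clipped to 0 with a warning — effectively the 110+ groups empty within a
step at high q.

Newborns: each year, births $B = \sum_{j=5}^{11} F(j)\,L^{(f)}(j)$ —
age-specific fertility (births per woman-year) times the women in the
group, evaluated on the start-of-year population — split between genders
by $k^{(f)} = \mathrm{SRB}/(1+\mathrm{SRB})$ with SRB = 1.07. Note this
default assigns the larger share to girls, whereas a male-biased SRB
conventionally implies the opposite split; `k_f` is an explicit argument
for users who want $1/(1+\mathrm{SRB})$.

Group populations aggregate single ages by the trapezoid rule (mortality
approximately uniform within a band): $L(1)=\hat L_0$,
$L(2)=2(\hat L_1 + \hat L_4)$, $L(j)=2.5(\hat L_{5j-10} + \hat L_{5j-6})$
for $j=3..23$, $L(24)=\hat L_{110}$. The 24x24 Leslie matrix is built
*from the realized step* (`build_leslie()`): survivorship ratios
$L_{t+5}(j{+}1)/L_t(j)$ on the subdiagonal — the last ratio lumps
survivors entering 110+ with the bucket's retained occupants — and
first-row fertility entries $k^{(g)} b_j / L^{(g)}_t(j{-}1)$, where $b_j$
is the final year's realized birth contribution of fertile group $j$. The
fertility-row denominator is deliberately the *own-gender* population: a
male matrix normalized by female populations could not reproduce the male
recursion. With these definitions $P\,N_t = N_{t+5}$ holds exactly, the
invariant the test suite verifies on random configurations to 1e−9
relative.

Pyramids are kept every 5 years; the annual balance engine linearly
interpolates group populations at intermediate years
(`annual_population()`). Dependency ratios divide groups 15..24 by groups
6..14, per gender or total.

## The balance engine

Economic assumptions are deliberately spartan: a per-group salary
schedule and a single average pension, both growing at a constant 2% per
year (the salary structure is an explicit input — no hidden constant —
and the synthetic module ships a plausible hump-shaped default peaking
near ages 45–54); every person 65+ receives the average pension;
contributions are paid by employed members of groups 6..14 — ages 16–19
have unemployment data but are excluded from the contribution base so the
worker definition matches the dependency ratio's denominator. Employment
is $1 - u/100$ with $u$ the unemployment rate in percent, held constant
after the last projected year. During each pandemic window the observed
reference-pandemic rates replace the baseline (year 1 and year 2 blocks),
and employment reverts afterwards. Scenario multipliers scale $u$ either
throughout the horizon or only inside pandemic windows; factors floor
at 0.

The contribution rate is calibrated once, as the rate equating income and
expenditure in the base year, and then held fixed — so the base-year
balance is zero by construction (asserted to machine precision in the
tests) and every later deficit is a statement about demography and
composition, not about the money unit: balances are homogeneous of degree
one in (salaries, pension).

On the package's reference conditions the pandemic's two channels
decompose almost additively (the interaction is second-order; the tests
bound it at 5% of the larger channel). The mortality channel's
expenditure cut persists for decades — the pensioners who died in the
window stay dead — while the employment channel's income cut lasts only
the 2-year window; the tests therefore measure "which channel drives
sustainability" cumulatively over a 20-year pandemic cycle, not just
inside the window, matching the persistent-vs-transient structure of the
two shocks.

## The synthetic-data generator

`spain_like_inputs()` fixes the reference study conditions: 51 years of
mortality history (1971–2021, both genders) and fertility history, an
initial pyramid of 47 million with a realistic middle-age hump and
old-age attrition, the reference unemployment table (2019 baseline / 2020
pandemic override, in percent), a hump-shaped salary schedule (16–30
thousand per year across working groups, women at 93%), an average
pension of 15,000 per year, and a COVID-like pandemic template: no excess
below age 50 rising to ~30% year-1 excess at the oldest female groups,
male excess 25% larger, year-2 excess 40% of year 1. Death-count surfaces
for 2016–2021 are generated so the jump calibration path recovers the
template exactly.

Generated log rates follow exactly the functional model the fitter
assumes — Gompertz-like mortality mean with an infant peak and an old-age
improvement taper, unimodal fertility mean, orthonormalized smooth
loadings, drifting random-walk scores, 0.05 observational noise on the
log scale — and every generator returns its ground truth, enabling
parameter-recovery tests (drift within 3 standard errors; basis-span
principal angles below 5 degrees; mean absolute drift error below 25% of
the truth across 20 seeds). The fertility first component follows a
flattening trend path (steep decline early, levelling off late), the
documented historical shape; mortality keeps a constant drift.

What passing these tests does *not* show: real rate surfaces are not
exactly low-rank, their noise is not Gaussian or homoscedastic, unemployment
and salaries interact with cohort size, and levels here are
shape-realistic rather than calibrated to any official series — so
absolute quantities (the equilibrium rate, currency balances) are
demonstration values, while structural results (directions, orderings,
identities, decompositions) are the tested claims. Real national tables
can be substituted through `read_bundle()`/`reproduce_spain()`; quantities
that depend on the unpublished salary structure then still reproduce only
in shape.

## Numerical and policy choices collected

* Age grid: group midpoints; 1-based group indices everywhere.
* SVD sign convention: largest-|element| of each basis function positive;
  fits are deterministic and repeatable bit-for-bit.
* Rank guard: requesting K above the attained rank of the centered
  surface is an error reporting that rank.
* Mortality cap 0.99 inside jump windows; forecast back-transform capped
  below 1; survival factors clipped at 0 with an aggregated warning.
* Projection horizon must be a multiple of 5; jump windows must lie
  inside the forecast and may not overlap.
* The balance base year defaults to the first trajectory year (2021 in
  the reference conditions) so the reported 20-year marks (2041, 2061,
  2081, 2101) are step endpoints.
* Unemployment for ages 60–64, absent from the standard labour-force
  table, copies the 55–59 rate; groups outside 16–64 have no
  unemployment concept.
* All CSV I/O uses one dialect: comma-separated, header row, UTF-8, "."
  decimal, years as columns; tidy exports carry full (17 significant
  digit) precision so write/read round-trips exactly.

## Known limitations

No migration; no stochastic jump occurrence or size; no benefit formulas,
contribution ceilings, retirement-age or indexation policy beyond the
constant 2% growth; no macroeconomic feedback from inflation or interest
rates; full-time employment equivalence (no partial employment). Genders
are modelled independently (no coherent joint fit). The problem sizes
used throughout — 24 groups, 51 history years, 80-year horizon, three
jumps — run the full pipeline in well under a minute on one CPU.
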