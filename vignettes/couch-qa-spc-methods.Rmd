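---
title: "Statistical methods for couch-positioning QA monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for couch-positioning QA monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couchspc)
```

## The monitoring problem

A tomotherapy couch reports its IEC X (lateral), Y (longitudinal) and Z
(vertical) offsets from baseline at every QA session, giving one scalar
measurement per axis per session over years of operation. Two failure modes
must be distinguished:

* **setup errors** — isolated positioning mistakes producing single outlier
  points, typically beyond 1 mm, with no memory;
* **systematic faults** — a miscalibrated or degrading encoder producing a
  sustained step or drift of the whole process mean.

Clinical action limits (±2 mm here, ±1 mm as a stricter candidate) answer
"is this measurement usable?", not "is the machine changing?". The package
answers the second question with statistical process control and then uses
capability indices to ask whether the chosen action limits are realistic
for the machine's actual dispersion.

## Individuals chart model

Each (unit, axis) series $x_1,\dots,x_n$ is modelled, while in control, as
independent draws from a stationary distribution with mean $\mu$ and
short-term dispersion $\sigma$. Because there is one observation per
session, dispersion is estimated from moving ranges
$mR_i = |x_i - x_{i-1}|$:

$$\widehat\sigma_\text{within} = \bar{mR}/d_2, \qquad
  UCL/LCL = \bar x \pm 3\,\bar{mR}/(d_2\sqrt n_\text{sub}),\qquad
  n_\text{sub}=1 .$$

$d_2$ is the expected range of a subgroup of standard normals. For the
moving-range span of two, `d2_constant(2)` returns the closed form
$2/\sqrt\pi = 1.12838\ldots$ (the familiar tabulated 1.128 is its 3-dp
rounding); we use the full-precision value in the limits, which moves a
typical UCL by well under a micrometre relative to the rounded constant.
Other subgroup sizes integrate
$E[\text{range}] = \int 1-\Phi(x)^m-\Phi(-x)^m\,dx$ numerically
(`rel.tol = 1e-12`).

Assumptions and conventions:

* Only the classical Rule 1 (a point beyond the 3σ limits) flags a point;
  run rules (e.g. eight-in-a-row) are deliberately not applied. Sustained
  shifts are instead surfaced by the windowed analysis below, which keeps
  each rule's false-alarm behaviour easy to reason about.
* A point **exactly on** a limit is in control: violations are strict
  inequalities. Some convention is required for testability; strictness is
  the conservative choice for flag counts.
* Limits are estimated retrospectively from the whole supplied series
  (phase I). A `baseline` argument supports phase-II monitoring — judging
  new data against limits from a reference period, as in pre/post
  recalibration comparisons. Out-of-control points are *not* purged before
  re-estimation; a retrospective QA review should see the data as logged.
* A constant series collapses UCL = CL = LCL with a warning rather than an
  error: it is a legitimate (if suspicious) log.

Under normality the two-sided 3σ coverage is 99.73%; the suite verifies
~99.7% coverage on 10,000 simulated in-control points against
independently estimated limits.

## Normality testing

Control limits presuppose approximate normality, and the QA logs often
fail it globally (regime changes, faults) while passing locally
(three-monthly windows). We use the Anderson–Darling statistic

$$A^2 = -n - \tfrac1n\sum_{i=1}^n (2i-1)\left[\ln F(X_{(i)}) +
   \ln\bigl(1-F(X_{(n+1-i)})\bigr)\right]$$

because its tail weighting matches the failure mode of interest (outliers
and shifted segments live in the tails). Both parameters are estimated
from the sample — the composite case, matching how the test is applied to
raw QA data — so the statistic receives Stephens' modification
$A^{*2}=A^2(1+0.75/n+2.25/n^2)$ and the D'Agostino–Stephens
piecewise-exponential p-value. Numerical choices:

* CDF values are clamped to $[10^{-16}, 1-10^{-16}]$ before the
  logarithms; an extreme order statistic otherwise produces $-\infty$. The
  clamp's effect is far below test tolerances.
* Ties (offsets are rounded in practice) are kept and the sum evaluated as
  written over the stably sorted sample.
* $n \ge 8$ is required; below that the p-value approximation is not
  trustworthy and the package refuses rather than guesses.
* The minimum significance returned is $3.7\times10^{-24}$, the floor of
  the published approximation.

The implementation is cross-checked in the test suite against an
independent reference implementation (`nortest::ad.test`) to $10^{-12}$
and against a literal term-by-term evaluation of the sum to $10^{-10}$.
Its empirical type-I error over 2,000 normal samples of $n = 90$ is
verified to sit at 5% ± 1%.

## Capability and acceptability

Against user-specified limits (USL/LSL):

$$c_p = \frac{USL-LSL}{6\sigma},\qquad
  c_{pk} = \min\!\left(\frac{USL-\bar x}{3\sigma},
                       \frac{\bar x - LSL}{3\sigma}\right).$$

$\sigma$ here is the **overall sample SD** (n−1 denominator) of the
window, not the within-subgroup estimate $\bar{mR}/d_2$: the indices
describe the data distribution actually delivered to the clinic, faults
and all. Both estimates are exposed (`summary.spc_chart()` reports both),
and with the overall SD these are what the capability literature calls
performance indices (Pp/Ppk); we keep the cp/cpk names used in machine-QA
practice. Acceptability requires **both** indices ≥ 1 — the only threshold
drawn. No confidence intervals are attached: the indices are reported as
point summaries of a specific window, and their seed-to-seed scatter is
what the property tests exercise.

Capability (and normality) are computed per analysis window, not pooled:
the three-monthly window is the decision unit of the monitoring
recommendation.

## Windowed trend analysis and phase comparison

`partition_windows()` slices by observation count (default 90 ≈ three
months at a daily cadence), not by calendar date: the window size then
fixes the statistical properties (SD of a window mean is
$\sigma/\sqrt{90}$) regardless of gaps in the log. A trailing partial
window is reported for completeness but excluded from normality and
capability, which are unstable at reduced n. The baseline reference for
mean variation defaults to 0 mm because offsets are deviations from
baseline by construction.

`compare_phases()` estimates limits on the *before* phase and judges the
*after* phase against them. The verdict is `systematic_shift` when

* at least `shift_min_points = 2` after-phase points fall outside the
  before-phase limits, **or**
* the center line moved by more than `drift_threshold_mm = 0.5` (the
  magnitude of gradual baseline drift observed over three-monthly
  periods; explicitly a tunable, not a claim).

The 2-point minimum is a deliberate design choice. With 90-observation
phases, the chance that *at least one* in-control point strays beyond
estimated 3σ limits is roughly a quarter — direct simulation in the test
suite puts the any-single-point rule's false-alarm rate near 26% — which
would swamp the review process with false "systematic" calls. Requiring
two points (or a mean drift) keeps the simulated false-flag rate below
10% while a genuine 1.0 mm step at σ = 0.3 mm is still flagged in
essentially every run, and it encodes the physical distinction that a
lone excursion is a setup error, not a fault. The literal
all-points-inside indicator is still reported (`limits_respected_in_b`)
for users who want the stricter reading.

## Applied-vs-detected offset analysis

The experiment applies shifts of ±0.5, ±1, ±2, ±5 mm along each axis,
three replicates each, and records the detected offset on all three axes.
Replicates are averaged before any comparison; the analysis reports, per
applied axis, the maximum |detected − applied| over the grid and its
verdict against the tolerance (default 2 mm).

Cross-axis coupling (the cobra motion: raising the couch moves it toward
the gantry, so Z shifts bleed into the Y reading) is screened with two
gates: only applied magnitudes ≥ `coupling_floor_mm = 2` are considered
(smaller couplings are geometrically below the detector's resolving
power), and the mean off-axis magnitude must exceed
3 × `reproducibility_mm = 0.2` — three times the replicate-level
reproducibility — to count as detected rather than noise. This formalizes
a detectability threshold minimally; it is a screen, not a hypothesis
test. `cross_axis_matrix()` gives the complementary continuous view: the
3×3 matrix of OLS slopes of each detected coordinate per mm applied on
each axis (identity for a faithful system).

Linearity fits are ordinary least squares through `stats::lm`, with
$R^2 = 1 - SS_{res}/SS_{tot}$; a constant response is reported as
$R^2 = 0$ and a design with fewer than three distinct applied values is
refused as degenerate.

## The synthetic generator

`generate_series()` draws, from a named seedable RNG (R's default
Mersenne-Twister via `set.seed()`, with the caller's RNG state restored),
in this order: iid $N(\mu,\sigma^2)$ base points; setup-error outliers
replacing points at a given rate with sign-random magnitudes
$U(s, s+1)$ mm, $s > 1$ mm so every outlier is a genuine action-level
event for tight processes; optional 20% uniform-mixture contamination
$U(\mu-3\sigma,\mu+3\sigma)$ (defeats normality without moving the mean);
then fault segments adding a constant step or linear drift. Timestamps
are a synthetic daily cadence, so 90 observations correspond to a
three-monthly review period. Every point carries ground-truth annotations
(`in_control`, `outlier`, `contaminated`, `fault_id`, `disturbance_mm`).

The `T1`/`T2` presets carry each unit's published per-axis three-monthly
center line and overall SD (e.g. T2 IECZ: CL −0.880 mm, σ = 0.542 mm) and
4-year observation counts (1530 and 1388), so demo data reproduce the
units' qualitative behaviour: all lateral/longitudinal axes acceptable at
±2 mm, the off-center vertical axes borderline, and ±1 mm too conservative
for the wide axes (cp = 2/(6σ) < 1 for σ > 1/3 mm).

`generate_experiment()` composes detected offsets as
`slope_matrix[applied_axis, detected_axis] × applied + noise`, with
defaults: on-axis Z bias slope 1.19/5 per mm (a +1.19 mm detection bias at
+5 mm applied), Z→Y coupling slope 0.234 (1.17 mm at 5 mm), per-read
noise SD 0.2/3 mm so the replicate spread is about ±0.2 mm, and a
1 °/mm gantry-phase response to lateral shifts with 0.17° noise — the
noise level that puts the phase-vs-applied $R^2$ near 0.996 on the
standard grid, solved from the $R^2$ definition.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: autocorrelation between consecutive
sessions, seasonal or thermal cycles, heteroscedasticity across the
4-year span, digitization of the readout, and missing/irregular sessions.
The analyses make no use of these properties, but real-data false-alarm
rates will differ from the iid-based simulations to the extent such
structure is present (positive autocorrelation in particular narrows
moving-range limits and inflates alarm rates).

## Problem sizes and reproducibility

The test suite simulates at the scale the statistics require and no more:
coverage on 10,000-point runs, type-I error over 2,000 samples of n = 90,
step-change detection over 200 seed pairs of 90+90 observations, and
oracle comparisons on n ≤ 10 designs; the whole suite runs in well under
a minute. `scripts/acceptance.R` recomputes the coverage and type-I
figures from scratch for any seed. All randomness flows through explicit
integer seeds; identical spec + seed gives bit-identical synthetic data
within an R version (cross-language reimplementations should expect
statistical, not bit-level, agreement).

## Known limitations

* The individuals chart reacts slowly to small sustained shifts; EWMA or
  CUSUM charts would detect them earlier but are out of scope, as is
  automatic change-point estimation — event indices come from machine
  logbooks, not from the data.
* Capability indices assume an approximately normal window; the package
  reports the AD verdict alongside so a "not normal" window's cp/cpk can
  be read with suitable suspicion, but it does not compute percentile
  (non-normal) capability indices.
* The QA-log dialect is deliberately narrow (one CSV schema, naive
  ISO-8601 timestamps ordered lexically, decimal point only); it is a
  monitoring format, not an interchange format, and no proprietary
  database exports are parsed.
* Energy/output columns are carried through and can be fitted as generic
  linear responses, but no physical model connects them to couch offsets.
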