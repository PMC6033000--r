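---
title: "High-residence acoustic positioning: model, simulator and thinning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-residence acoustic positioning: model, simulator and thinning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrtrack)
library(dplyr)
```

## The problem

High-residence (HR) acoustic tags emit a short (< 10 ms) coded ping every
second or two, so a fixed array of time-synchronised hydrophone receivers
can, in principle, estimate a fish's two-dimensional position once per
transmission — one to two orders of magnitude more often than legacy
pulse-position-modulation (PPM) tags, whose multi-second pulse trains and
collision-avoidance delays push practical positioning periods past a
minute (`min_positioning_period()` returns the hard floor: burst length
plus transmission delay, e.g. `min_positioning_period(3, 5)` = 8 s).

`hrtrack` packages the computational machinery needed to study such a
system end to end without field data:

1. a **simulator** of a small receiver array and of tags transmitting,
   propagating and being detected in it;
2. a **TDOA positioning engine** that converts multi-receiver detections
   of one transmission into a position;
3. **trial statistics** — accuracy and precision summaries for stationary
   and moving reference deployments;
4. a **thinning sensitivity analysis** quantifying what happens to common
   movement metrics when the same track is observed at longer
   transmission periods.

## Coordinate frame

All computation happens in a local planar frame (metres east/north of an
origin), where position error is the plain Euclidean distance.
Geographic input is projected with a local equirectangular projection
about the array centroid (`latlon_to_local()`): `x = R cos(lat0) Δlon`,
`y = R Δlat` with `R` = 6371 km. Over the sub-kilometre extent of an
array this projection is conformal to well below the positioning noise,
and it is exactly invertible (`local_to_latlon()`), which is why we
prefer it to a full geodetic library: round-trip error is below 1e-6 m
at these scales, with no external dependency. Full geodesy (UTM zones,
datum transforms, depth) is out of scope.

## The positioning model

A transmission at unknown time $t_0$ from unknown position $p = (x, y)$
reaches receiver $i$ at position $r_i$ at

$$a_i = t_0 + \lVert p - r_i \rVert / c,$$

with $c$ the speed of sound. Three receivers give three equations in
three unknowns. Subtracting pairs of the squared range equations leaves
two equations *linear* in $(x, y)$ for given $t_0$; substituting the
resulting linear map $p(t_0)$ back into one range equation yields a
quadratic in $t_0$. `solve_tdoa_triple()` therefore returns 0, 1 or 2
algebraically exact candidates, keeping only roots with $t_0$ earlier
than the first arrival. On noise-free forward-simulated arrivals the
true position is recovered to better than 1e-6 m (this is asserted for
1000 random interior positions in the test suite).

Numerical choices: receivers closer than 1e-6 m² of triangle area are
rejected as collinear; the quadratic is solved with the
numerically stable formulation and a discriminant pushed marginally
negative by rounding (a grazing double root) is clamped to zero.

### Error sensitivity and subset combination

With $n \ge 3$ receivers detecting one transmission, every
3-receiver subset is solved and the subset solutions are merged into a
single fix. Subsets differ enormously in how they amplify timing error,
so the merge is a weighted mean that favours the least error-sensitive
subsets. The sensitivity of a subset solution is defined here as the
Frobenius norm of the Jacobian $\partial(x, y)/\partial(a_1, a_2, a_3)$
— metres of position displacement per second of arrival-time
perturbation, a geometric dilution of precision. Implicitly
differentiating the range equations gives it in closed form: with unit
vectors $u_i$ from receiver $i$ to the solution, the Jacobian of
$(x, y, t_0)$ with respect to arrivals is $c\,M^{-1}$ where row $i$ of
$M$ is $(u_{ix}, u_{iy}, c)$; the norm is taken over the two position
rows. A central-finite-difference version (`method = "numeric"`) serves
as an independent cross-check.

The weights are $w_i = 1/s_i^2$ — inverse-variance weighting under the
reading that position scatter scales linearly with $s_i$. The vendor's
actual weighting is proprietary; an inverse-square rule is the
dimensionally natural choice among the defensible readings (another
would be keeping only the single best subset), and the combined fix
reports the minimum subset sensitivity as its quality score. When the
quadratic yields two physical roots for a subset, the ambiguity is
resolved by cross-subset consistency: candidates farther than three
array diameters from the array centroid are dropped; if any subsets are
unambiguous, the mean of their positions anchors the choice for the
rest; failing that, the lower-sensitivity root is kept. No quality
filtering is applied to the resulting fixes — evaluation happens on the
raw output.

`position_run()` composes the pipeline: detections are clustered into
transmissions per tag by single-linkage in time, with link threshold
equal to the maximum acoustic travel-time difference across the array
plus a 0.05 s guard (generous for a sub-10-ms burst plus clock slack);
within a group only the earliest detection per receiver is kept, and
groups with fewer than three distinct receivers are discarded.

## The simulator

The generator emulates the study conditions of a small lake deployment:

* **Array**: seven receivers — one central, six on a regular hexagon of
  radius 77.1 m (`default_array()`). The field array's published
  statistic is a mean spacing of 77.1 m with 18.6 m SD; coordinates are
  not published, and the regular hexagon is the symmetric layout
  matching the mean. Every receiver's nearest neighbour is exactly one
  spacing away.
* **Schedules**: transmission gaps i.i.d. uniform on the tag's period
  range (`gen_transmission_times()`) — 1–2 s (mean 1.5 s) for test
  tags, 3–5 s (mean 4 s) for fish tags. Uniform is the
  minimal-assumption distribution consistent with a stated mean and
  range.
* **Propagation**: sound speed 1447 m/s, fresh water near 10 °C;
  configurable in `propagation_model()`.
* **Timing noise**: `sigma_t` = 1e-4 s per arrival (≈ 0.14 m at `c`),
  chosen once to produce the metre-scale position scatter typical of a
  sync-tag-synchronised array; clock offsets default to zero.
* **Detection loss**: logistic in range, midpoint `d50` = 150 m and
  steepness 0.05 /m, so detection within the array is near-certain
  while a tag a few hundred metres out (or under dense cover, emulated
  by moving it outside effective range) drops below positionability.
  The published range test gives no parametric curve, so these are
  package defaults, not field estimates.
* **Trajectories**: stationary points, constant-speed waypoint tows,
  and a correlated random walk (Normal heading increments, constant
  step speed) for fish-like movement.

What the simulator deliberately omits: multipath, Doppler, directional
receiver sensitivity, temperature-stratified sound speed, and signal
collisions (negligible for sub-10-ms HR bursts). Passing tests on
simulated data therefore demonstrate the correctness of the algorithms
and the internal consistency of the statistics — not the field accuracy
of any particular deployment, which is dominated by survey error in
receiver coordinates and reference GPS error (a handheld GPS's "±3 m"
display is of unstated confidence, possibly 50% CEP).

## Trial statistics

For a stationary deployment, **accuracy** is the distance of each fix
from the reference position and **precision** is the distance of each
fix from the trial's own median position — scatter blind to constant
bias. A track can be centimetre-precise yet metres-inaccurate if the
whole fix cloud is offset; the two statistics decouple exactly that
way, and a constructed test (truth offset by 5.6 m, zero noise) checks
it. "Median position" is read as the coordinate-wise median: the
geometric median is not materially different for compact fix clouds and
the coordinate-wise version is deterministic and standard.

For a moving trial, each fix is compared with the reference GPS track
(nominally 1 Hz) linearly interpolated to the fix's emission time.
"Time-matched" has no published rule; linear interpolation of 1 Hz
samples adds negligible error at towing speeds. Fixes up to 2 s outside
GPS coverage are matched to the nearest endpoint; farther ones are
dropped and counted.

All summaries are median, 5th and 95th percentiles (type-7 linear
interpolation between order statistics) and range, via `trial_stats()`.

## Thinning and movement metrics

`thin_track()` emulates a longer-period tag by deleting fixes until all
consecutive intervals are at least the set period. The reference
procedure is iterative: delete the first (chronological) fix whose gap
from its predecessor is under the threshold, recompute, repeat. A
greedy forward scan — keep the first fix, then keep each fix whose gap
from the last *kept* fix meets the threshold — is provably equivalent
(the first offender's deletion never changes which earlier fixes are
kept, so induction along the track applies) and is what the package
runs; the test suite checks equivalence against the literal iterative
oracle exhaustively on small tracks and on random ones. The retention
rule is "gap ≥ threshold": retained observed periods always sit at or
just above the set period, consistent with how thinned datasets behave.
Thinning is idempotent and anchored at the first fix. Note one subtlety
asserted in the tests: position *count* is non-increasing in the
threshold, but retained sets at two thresholds are not nested, so the
path distance of a 10 s thinning can occasionally exceed that of a 7 s
thinning — only the comparison of any thinned track against the native
track is guaranteed by the triangle inequality.

`movement_metrics()` reports total distance travelled (sum of step
lengths), per-step speeds (step length over duration) and unsigned
turning angles in degrees (0 = straight; vertices touching a
zero-length step are skipped and counted). `sensitivity_analysis()`
tabulates these for the native track plus each thinning period, and
`metric_period_regression()` fits the pooled fish-by-period points by
ordinary least squares, optionally on log10-transformed metrics; with
five fish and seven datasets the fit has 33 residual degrees of
freedom. Whether per-fish speed enters as mean or median is a
presentation choice; the table reports the median (5th–95th percentile)
per-step statistics and the regression takes whatever metric column it
is given.

## The replicated thinning study

`thinning_study()` is the simulation used by `scripts/acceptance.R`:
five 900 s fix sequences per replicate with gaps uniform on [3, 5] s
and 8% of fixes omitted at random (the free calibration for the rate at
which transmissions of a free-swimming fish fail to be positioned; 8%
lifts the native median observed period to ≈ 4.2 s), thinned at 7, 15,
30, 45 and 60 s. Per replicate it records the median across fish of the
per-fish median retained gap, the median per-fish position count, and
the pooled percent reduction in positions; the acceptance script
averages 200 replicates. These problem sizes (200 × 5 × ~210 fixes)
keep the whole study in a few seconds while leaving the Monte-Carlo
error of every reported value far below the comparison tolerances.

## Known limitations

* 2-D only; depth is neither modelled nor estimated.
* Receiver clocks are assumed synchronised; clock-drift estimation from
  sync tags is out of scope.
* The subset weighting reproduces the *behaviour* of
  sensitivity-favouring combination, not any proprietary implementation.
* The logistic detection model is a stand-in parameterisation, not a
  fitted range-test curve.
* No track smoothing or state-space filtering is applied — fixes are
  raw algebraic estimates, which is what the evaluation statistics are
  defined on.
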