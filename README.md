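# hrtrack

Fine-scale positioning of aquatic animals with high-residence (HR)
acoustic telemetry: simulation, TDOA positioning, accuracy/precision
evaluation, and sensitivity of movement metrics to transmission period.

HR tags emit a < 10 ms coded ping every second or two, so an array of
time-synchronised receivers can estimate a 2-D position almost per
transmission — far beyond the ≥ 1 min positioning periods of legacy
pulse-position-modulation (PPM) tags, whose floor is burst length plus
transmission delay (a 3 s burst with a 5 s delay cannot be positioned
more often than every 8 s). `hrtrack` is for movement ecologists and
biotelemetry engineers who want to study such a system quantitatively
without (or before) field data: how positioning error arises from
receiver geometry and timing noise, and how movement metrics degrade
when a track is observed at longer periods.

## What it computes

**Positioning.** A transmission at unknown time *t₀* from unknown
position *p* reaches receiver *i* at
*aᵢ = t₀ + ‖p − rᵢ‖ / c*. For each 3-receiver subset the package solves
this system exactly: differencing the squared range equations is linear
in *p* given *t₀*, and back-substitution leaves a quadratic in *t₀*
(`solve_tdoa_triple()`). Each subset's **error sensitivity** is the
Frobenius norm of the Jacobian ∂(x, y)/∂(a₁, a₂, a₃) (m/s, a GDOP
analogue, closed form via implicit differentiation), and the fix for a
transmission heard by n ≥ 3 receivers is the weighted mean over all
subsets with weights 1/s² (`position_run()`).

**Evaluation.** Accuracy = Euclidean distance of each fix from an
independent reference (fixed point or time-interpolated GPS track);
precision = distance from the trial's own coordinate-wise median
position; both summarised as median [5th–95th percentile] and range
(`accuracy_stationary()`, `precision_stationary()`, `accuracy_moving()`).

**Thinning.** `thin_track()` emulates a longer transmission period by a
greedy scan equivalent to iterative first-offender removal; all
retained gaps are ≥ the set period. `movement_metrics()`,
`sensitivity_analysis()` and `metric_period_regression()` quantify how
total distance travelled, speed and turning angle respond to the
period.

**Simulation.** `default_array()` (7 receivers, hexagon, 77.1 m
spacing), `gen_transmission_times()` (uniform-jittered periods),
`propagation_model()` + `simulate_detections()` (1447 m/s sound speed,
Gaussian timing noise, logistic range-dependent detection), and
stationary / waypoint / correlated-random-walk trajectories.

## Worked example

Simulate a fish-like track in the default array, position it, measure
the error, and run the thinning sensitivity analysis:

```r
library(hrtrack)
library(dplyr)

set.seed(1)
arr   <- default_array()
traj  <- crw_trajectory(n_steps = 600, speed_mean = 0.25, turn_sd_deg = 30, dt_s = 1.5)
times <- gen_transmission_times(max(traj$time_s), period_min = 1, period_max = 2)
det   <- simulate_detections(arr, traj, times, propagation_model())
fixes <- position_run(det, arr)
fixes
#> # A tibble: 603 × 6
#>   tag_id time_s   x_m    y_m sensitivity n_receivers
#>   <chr>   <dbl> <dbl>  <dbl>       <dbl>       <int>
#> 1 T1       1.32 0.380 -0.246       1671.           6
#> 2 T1       2.68 0.711 -0.141       1671.           6
#> 3 T1       4.42 0.958 -0.485       1671.           7

truth <- trajectory_at(traj, fixes$time_s)
trial_stats(plane_distance(fixes$x_m, fixes$y_m, truth$x_m, truth$y_m))
#> # A tibble: 1 × 7
#>       n median_m   p5_m p95_m   min_m max_m duration_s
#>   <int>    <dbl>  <dbl> <dbl>   <dbl> <dbl>      <dbl>
#> 1   603   0.0918 0.0275 0.196 0.00115 0.292         NA
```

603 of the 605 transmissions were positioned; with 0.1 ms timing noise
the median position error inside the array is ≈ 0.09 m (the
`sensitivity` column, ≈ 1700 m/s, maps timing error to position error:
1671 × 1e-4 s ≈ 0.17 m per arrival, shared over many subsets).

```r
tab <- sensitivity_analysis(fixes, periods = c(7, 10, 15, 30, 45, 60))
select(tab, dataset, position_period_median, n_positions, distance_m, speed_median)
#> # A tibble: 7 × 5
#>   dataset    position_period_median n_positions distance_m speed_median
#>   <chr>                       <dbl>       <int>      <dbl>        <dbl>
#> 1 native                       1.48         603       231.        0.255
#> 2 thinned_7                    7.83         115       197.        0.227
#> 3 thinned_10                  10.8           83       187.        0.218
#> 4 thinned_15                  15.8           57       176.        0.206
#> 5 thinned_30                  31.0           30       152.        0.181
#> 6 thinned_45                  45.4           20       130.        0.162
#> 7 thinned_60                  60.9           15       103.        0.129

glance(metric_period_regression(tab, distance_m, transform = "log10"))
#> # A tibble: 1 × 9
#>      slope intercept r_squared     F   df1   df2   p_value transform     n
#>      <dbl>     <dbl>     <dbl> <dbl> <int> <int>     <dbl> <chr>     <int>
#> 1 -0.00540      2.34     0.978  227.     1     5 0.0000233 log10         7
```

Thinning this 15-minute track from its native ~1.5 s period to 60 s
cuts the position count from 603 to 15 and the apparent distance
travelled from 231 m to 103 m — the corner-cutting bias that motivates
regressing log₁₀ metrics on transmission period. `autoplot(tab)` draws
the metric-versus-period panels; `plot_track(fixes, traj)` overlays the
estimated track on the truth.

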