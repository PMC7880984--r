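# saccfit

Model-based saccade kinematics and main-sequence analysis for eye-movement
research.

Saccade amplitude, duration and peak velocity — and the *main sequence*
relating amplitude to peak velocity — are standard summaries of oculomotor
performance in vision science and neurology. The conventional estimators
(numerical differentiation, absolute velocity thresholds, the largest
velocity sample) are tied to the eye tracker's sampling grid: each marked
endpoint can be wrong by a full sampling period (±5 ms at 200 Hz, ±20 ms at
50 Hz) and the sampled maximum systematically underestimates the true peak.
`saccfit` instead fits each detected saccade's projected trajectory with a
Hill-form sigmoid

    y(t) = E0 + (Emax − E0) · t^α / (E50^α + t^α)

and reads the kinematics off the fitted curve analytically: start and end
are the 2% and 98% displacement points `t_f = E50·(f/(1−f))^(1/α)`,
amplitude is `0.96·|Emax − E0|`, and peak velocity is the analytic
derivative evaluated at `t_peak = E50·((α−1)/(α+1))^(1/α)` — all with
sub-sample resolution, which is what keeps the estimates stable down to
~50 Hz sampling. The classic threshold estimator is kept alongside as the
baseline for comparison.

On top of the per-saccade fits the package provides:

- **Detection**: velocity-threshold event detection (20 deg/s default) with
  fixation marking, projection of the 2-D trajectory onto the
  fixation-to-fixation line, micro-saccade filtering (1 deg) and
  horizontal-saccade selection (±15 deg);
- **Nine main-sequence models** (`slope`, `line`, `cubic`, `sqrt`,
  `fixed_sqrt`, `power_law`, `log_log`, `exponential`, `sigmoid`) with
  closed-form or Levenberg–Marquardt estimation and adjusted R²;
- **Reliability machinery**: bootstrap distributions of goodness-of-fit and
  pairwise-curve symmetric MAPE across boot sizes 10–100, Hotelling-T²
  stability sizes, amplitude-range generalization matrices, cross-condition
  (test–retest) MAPE, and a Wilcoxon-based downsampling study across
  decimation factors 1:2–1:8;
- **A synthetic gaze generator** with full ground truth, so the entire
  pipeline is testable without recorded data;
- a thin CLI (`exec/saccfit`) with `synth`, `detect`, `mainseq` and
  `subsample` subcommands.

Everything is tibble-in/tibble-out and pipe-friendly, with broom-style
`tidy()`/`glance()`/`augment()` and `autoplot()` methods for the fitted
objects.

## Worked example

Simulate a 60-saccade free-viewing session (250 Hz, 0.1 deg noise), detect
and fit every saccade, then fit and bootstrap the one-parameter fixed-sqrt
main sequence:

```r
library(saccfit)
library(dplyr)

g <- generate_trace(synth_config(n_saccades = 60, noise_sd = 0.1, seed = 1))

segments <- g$trace |>
  detect_saccades() |>
  filter_microsaccades() |> _$kept |>
  project_trajectory(g$trace)

kin <- saccade_kinematics(segments, g$trace)
kin |> filter(method == "fit") |>
  select(saccade, amplitude, duration, peak_velocity, r_squared) |> head(4)
#>   saccade amplitude duration peak_velocity r_squared
#> 1       1      2.17   0.0368          150.     0.996
#> 2       2      3.25   0.0719          240.     0.996
#> 3       3      6.47   0.166           279.     0.998
#> 4       4     18.6    0.147           453.     1.000

pts <- kin |> filter(method == "fit", is.finite(amplitude), amplitude > 1)
fit <- fit_main_sequence(pts, "fixed_sqrt", constants = list(VA = 40, A_th = 1))
fit
#> <mainseq_fit> fixed_sqrt: V = 101.19 | adj. R2 = 0.9788 on 60 points
```

Each `fit` row is one saccade: amplitude in degrees (2–98% of the fitted
sigmoid), duration in seconds, peak velocity in deg/s from the analytic
derivative, and the fit's R². The generator's law was
`v = 40 + 100·√(A − 1)`; the recovered slope `V = 101.19` is within ~1% of
the configured 100, and `autoplot(fit)` overlays the fitted curve on the
points. Bootstrapping quantifies repeatability — the median pairwise
symmetric MAPE between curves refitted on resamples:

```r
br <- bootstrap_models(pts, "fixed_sqrt", boot_sizes = c(25, 50),
                       n_boots = 200, seed = 2,
                       constants = list(VA = 40, A_th = 1))
tidy(br) |> select(boot_size, mape_median, mape_q3, r2_median)
#>   boot_size mape_median mape_q3 r2_median
#> 1        25       0.782   1.34      0.979
#> 2        50       0.512   0.869     0.979
```

Two fits of the same subject's main sequence from 50-saccade resamples
differ by ~0.5% on the 1–25 deg grid — the repeatability that makes the
one-parameter model useful for comparing sessions, subjects or conditions
(`cross_condition_mape()`).

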