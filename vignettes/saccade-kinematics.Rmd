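---
title: "Model-based saccade kinematics and the main sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based saccade kinematics and the main sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccfit)
```

## The problem

Saccades — the rapid ballistic eye movements between fixations — are
characterized by three kinematic parameters: amplitude (deg), duration (s)
and peak velocity (deg/s). The stereotyped relationship between amplitude
and peak velocity, the *main sequence*, is widely used as a compact summary
of oculomotor performance in both research and clinical settings.

The conventional way to measure these parameters is to differentiate the
sampled gaze position numerically, mark the saccade start and end where the
speed crosses an absolute threshold, and take the largest velocity sample as
the peak. Every step of that recipe is tied to the sampling grid:

* a threshold crossing almost never coincides with a sample, so each marked
  endpoint can be off by up to one sampling period
  (`duration_quantization_error_ms()`: 5 ms at 200 Hz, 20 ms at 50 Hz);
* the true velocity peak falls between samples, so the sampled maximum
  systematically underestimates it, increasingly so at lower rates;
* numerical differentiation amplifies measurement noise in proportion to
  the sampling rate.

This package implements the alternative: fit a parametric model to the
spatial trajectory of each saccade and read all kinematics off the fitted
curve analytically, with sub-sample resolution. The threshold estimator is
retained (`threshold_kinematics()`) as the comparison baseline.

## The trajectory model

A detected saccade is reduced to a scalar trajectory by projecting the 2-D
gaze samples onto the straight line from the pre-saccadic to the
post-saccadic fixation centroid. The projected position is fitted with a
saturating Hill-form sigmoid

$$\hat{y}(t) = E_0 + (E_{max} - E_0)\,\frac{t^{\alpha}}{E_{50}^{\alpha} + t^{\alpha}},$$

where $E_0$ and $E_{max}$ are the flanking plateau positions (deg),
$E_{50}$ is the time of half displacement (s) and $\alpha > 1$ is a
dimensionless slope exponent. This form has the qualitative signature of a
saccade — smooth launch, fast rise, gentler approach to saturation — and,
crucially, closed-form kinematics:

* time at displacement fraction $f$: $t_f = E_{50}\,(f/(1-f))^{1/\alpha}$;
* start and end are defined as the 2% and 98% fractions, so the reported
  amplitude is $0.96\,|E_{max}-E_0|$ and the duration $t_{0.98}-t_{0.02}$;
* the velocity $\dot{y}(t) = (E_{max}-E_0)\,\alpha E_{50}^{\alpha}
  t^{\alpha-1}/(E_{50}^{\alpha}+t^{\alpha})^2$ peaks at
  $t_{peak} = E_{50}\,((\alpha-1)/(\alpha+1))^{1/\alpha}$.

`extract_kinematics()` evaluates these expressions; the test suite checks
them against brute-force grid/root-finding oracles across a parameter sweep.

A caution on notational variants: a denominator of the form
$(E_{50}+t)^{\alpha}$ sometimes appears in print for this family, but it is
inconsistent with $E_{50}$ being the half-saturation time (only
$E_{50}^{\alpha}+t^{\alpha}$ satisfies $\hat y(E_{50})$ = midpoint).
`hill_value(..., form = "printed")` evaluates that variant for comparison;
the fitter never uses it.

### The onset nuisance parameter

The Hill family is *not closed under time translation*: $H(t - c)$ is not a
Hill function of $t$. Since the analysis window deliberately opens several
samples before the detected onset (the fit needs plateau samples to anchor
$E_0$), measuring $t$ naively from the window start misspecifies the model.
On noiseless synthetic saccades this bias reaches ~20% of peak velocity at
250 Hz and ~45% at 50 Hz, where the pad spans 100 ms. `fit_hill()` therefore
estimates a bounded onset shift $t_0$ alongside the four shape parameters,
fitting $\hat y(\max(t - t_0, 0))$; all reported kinematics are measured
from the fitted onset. `estimate_onset = FALSE` restores the literal
four-parameter fit for anyone wanting the uncorrected behaviour.

### Identifiability at low sampling rates

At 50 Hz a small saccade's rise spans only 2–4 samples, and $\alpha$ is then
weakly identified: unconstrained, the optimizer can slide into a
near-step solution ($\alpha \to 1$, $E_{50} \to 0$) whose implied peak
velocity is arbitrarily large while the residuals stay excellent. Two
guards keep the fit physiological, both exposed as arguments:

* `alpha_bounds = c(1.3, 5)` — brackets the velocity-profile skewness
  reported for human saccades; outside it the implied profile is either
  impossibly front-loaded or implausibly symmetric-sharp;
* $E_{50} \ge \Delta t/3$ — a half-rise shorter than a third of a sampling
  period would place the entire movement between two samples.

The optimizer is Levenberg–Marquardt (`minpack.lm::nlsLM`) run from five
starts (plateau-departure inits at $\alpha \in \{2, 1.5, 3\}$ plus two
steepest-slope-anchored inits); the lowest residual sum of squares wins.
Non-convergence is flagged, never fatal: parameters from the best start are
returned with `converged = FALSE`.

## Detection

`detect_saccades()` uses the classic velocity-threshold rule (default
20 deg/s) on the two-point central-difference speed, with three practical
refinements:

* **Noise guard.** Differentiation at 250 Hz turns 0.1-deg white position
  noise into an 18 deg/s per-axis speed floor, which would swamp the
  threshold. Velocity used *for thresholding only* is computed on a copy of
  the trace smoothed with a 20-ms moving average, and supra-threshold runs
  shorter than 12 ms are discarded. All kinematic estimation operates on
  raw samples.
* **Merging.** Runs separated by less than 20 ms merge, so a noisy velocity
  dip does not split one saccade; the value sits below any physiological
  intersaccadic interval.
* **Windows.** Each saccade's analysis window extends `max(5 samples, 20
  ms)` beyond its onset/offset but never across a neighbouring saccade.
  Candidates lacking a usable flanking fixation are dropped with a warning.

Fixation centroids are per-axis medians over the sub-threshold interval
(robust to drift); the centroid-to-centroid distance and direction define
the nominal amplitude and the projection axis. The micro-saccade filter
(1 deg) and the horizontal-cone selector (±15 deg, boundary inclusive)
return or keep their discards explicitly, never silently.

Both differentiation stencils are available: the backward first difference
$\|X(t)-X(t-1)\|/\Delta t$ and the two-point central difference
$\|X(t+1)-X(t-1)\|/(2\Delta t)$ (the default for detection — no phase lag).

## The nine main-sequence models

`fit_main_sequence()` covers the model zoo used in the literature, grouped
by free-parameter count:

| parameters | models |
|---|---|
| 1 | `slope` $y=ax$; `sqrt` $y=V\sqrt{x}$; `fixed_sqrt` $y=V_A + V\sqrt{x-A_{th}}$ |
| 2 | `line` $y=ax+b$; `power_law` $y=mx^V$; `log_log` $y=e^{V\log x + Q}$ |
| 3 | `cubic` $y=ax^2+bx+c$; `exponential` $y=V(1-e^{-(x-A_0)/k})$; `sigmoid` $y=A_{max}/(1+(V_{50}/x)^{\alpha})$ |

`cubic` is the conventional name in this literature for the three-parameter
polynomial even though the equation is a quadratic; the printed equation is
what is implemented. `fixed_sqrt`'s $V_A$ (peak velocity at the
micro-saccade threshold $A_{th}$ = 1 deg) and $A_{th}$ are *constants taken
from the data*, not fitted — `compute_fixed_sqrt_constants()` averages
velocities within ±0.25 deg of $A_{th}$ and falls back to the conventional
40 deg/s with a warning when the band is empty. Note the band mean is only
unbiased when saccades cluster *at* $A_{th}$ (as in a lab protocol with
1-deg targets); on continuous amplitude distributions the $\sqrt{x-A_{th}}$
rise inflates it, so synthetic studies in this package pass the generating
law's constants explicitly.

Models linear in parameters are solved in closed form; `log_log` by
ordinary regression in log–log space (the transformation is that model's
point, so its loss deliberately differs from `power_law`'s);
`power_law`, `exponential` and `sigmoid` by Levenberg–Marquardt with
data-driven starts (log–log regression; $1.1\max y$, $A_0=0$, $k=10$;
$1.2\max y$, median amplitude, $\alpha=2$ respectively). R² is always
computed on untransformed velocities so models are comparable, and the
adjusted version $1-(1-R^2)(n-1)/(n-p-1)$ is reported alongside.

## Reliability machinery

* **Repeatability (MAPE).** `curve_mape()` compares two fitted curves on a
  common amplitude grid (1–25 deg, step 0.25 — starting at the
  micro-saccade bound where every model is defined). The denominator is the
  pair mean (symmetric MAPE): the two fits are equally valid estimates with
  no privileged reference, and symmetry makes the cross-condition matrix
  well-defined. Two curves in ratio $1+\delta$ give
  $200\delta/(2+\delta)$ %, e.g. 9.52% at $\delta = 0.1$.
* **Bootstrap.** `bootstrap_models()` resamples the point set with
  replacement at boot sizes 10–100, refits, and collects parameter vectors,
  adjusted R² *against the full point set*, and all pairwise curve MAPEs
  (a seeded subsample above `max_pairs` = 1e5). Failures are counted and
  excluded, and everything is reproducible per seed.
* **Stability size.** `stability_test()` compares consecutive sizes'
  parameter collections with a two-sample Hotelling T² (a t-test for
  one-parameter models; essentially-constant collections are handled by a
  direct mean comparison) and returns the first size whose comparison with
  the next is non-significant at 0.05. A singular pooled covariance gets a
  `1e-8 * trace` ridge.
* **Range generalization.** `range_generalization()` fits on points within
  5/10/15/20/25 deg and evaluates R² against each range — including ranges
  never seen by the fit — reporting the median across bootstrap fits.
* **Cross-condition MAPE.** `cross_condition_mape()` compares every
  bootstrap fit from one condition with every fit from another
  (`n_boots`² pairs, subsampled above 1e5), using common random numbers per
  boot size so identical conditions compare identically.
* **Downsampling study.** `subsampling_study()` decimates the trace by
  factors 1:2–1:8 (pure decimation, emulating slower devices), re-runs
  detection and both estimators, matches saccades to the reference run by
  onset-time proximity, and reports two-sided Wilcoxon rank-sum p-values
  plus the squared Pearson correlation of matched estimates. The matching
  tolerance is one coarse sampling period plus one original period: onsets
  on the decimated grid are quantized to the coarse period, so a tolerance
  of one *original* period would spuriously unmatch nearly everything at
  high factors. No multiple-testing correction is applied — the p-values
  are reported raw, one per factor/parameter/method cell.

## The synthetic generator

`generate_trace()` builds gaze traces with exactly the structure the method
assumes: fixations alternating with Hill-shaped saccadic displacements whose
peak velocities follow a configured main-sequence law, plus additive white
Gaussian position noise. Each saccade's sigmoid keeps relaxing toward its
asymptote through the following fixation, so position is continuous
everywhere. Ground truth (onset, amplitude, duration, peak velocity,
direction, $\alpha$, $E_{50}$) is returned alongside.

Defaults were chosen once as a plausible free-viewing session and are the
package's study conditions:

* law: `fixed_sqrt` with $V_A$ = 40 deg/s, $A_{th}$ = 1 deg, $V$ = 100
  — mid-range for healthy adults;
* amplitudes log-uniform on [1, 25] deg (short saccades predominate in
  natural viewing); directions uniform, reflected to stay within a ±25 deg
  box; fixations uniform on [0.25, 0.45] s;
* $\alpha$ uniform on [1.6, 2.6], sanity-bounded by a linear
  amplitude–duration law (60 ms + 6 ms/deg, acceptance band 0.4–2.5×) —
  the law only rejects implausible $\alpha$ draws, since duration is fully
  determined once amplitude, velocity and $\alpha$ are set;
* 250 Hz sampling, 0.1 deg noise SD per axis.

What the generator does *not* emulate — and what passing tests therefore do
not certify on real recordings: corrective saccades and dynamic overshoot,
glissades, smooth pursuit, blinks/track loss, drift, and temporally
correlated tracker noise. One structural mismatch is worth knowing: with
peak velocities pinned to a realistic main sequence, the Hill profile's
heavy tails make 2–98% durations two to three times longer than typical
human saccades of the same amplitude. Internal consistency (generate →
detect → fit → recover) is unaffected, but absolute durations from the
generator should not be read as normative.

`generate_points()` bypasses tracing for fast model studies: amplitudes
from the same sampler, velocities from the law with multiplicative Gaussian
noise (default SD 15%).

## Numerical choices and problem sizes

Closed-form-vs-oracle agreement is tested at 1e-6 over a 200-combination
sweep ($\alpha \in [1.2, 4]$, $E_{50} \in [5, 80]$ ms, amplitude
$\in [1, 25]$ deg). The end-to-end studies use 100-saccade traces for slope
recovery, a 200-saccade trace for the downsampling comparison, 100-point
sets with 200 bootstrap resamples for the complexity comparison (400 for
the size-trend, where median-MAPE jitter at 200 resamples occasionally
exceeds the trend step), and 400-point sets for range generalization.
These sizes give stable statistics while keeping a full run in the low
minutes on one core; all of them scale up by argument.

Degenerate inputs are handled explicitly: flat trajectories and
coincident fixation centroids raise errors naming the problem; models
refuse evaluation outside their domain (`fixed_sqrt` below $A_{th}$,
log-like models at non-positive amplitude); saccades whose window has no
supra-threshold sample yield `NA` baseline kinematics rather than failing
the batch.

## Known limitations

* Eye-tracker calibration, vendor file formats, and binocular analyses are
  out of scope; traces arrive as delimited text in degrees or screen pixels
  (with a screen geometry config).
* The pixel-to-angle conversion treats the two axes independently
  (`atan` against viewing distance per axis); within ±25 deg the difference
  from rotation-sequence conventions is sub-percent.
* Blink/track-loss samples are flagged invalid and excluded, not
  interpolated; each eye's trace is analyzed independently.
* Amplitude–duration main-sequence models are not fitted (duration is
  reported per saccade but the model zoo targets amplitude–peak velocity).
* At 50 Hz and below, per-saccade peak velocities from the fit are unbiased
  but individually noisy for small saccades; population-level quantities
  (medians, main-sequence fits) are the reliable outputs there.
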