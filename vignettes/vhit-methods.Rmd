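---
title: "Models and methods behind vorsac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vorsac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorsac)
```

## The measurement problem

During a head impulse — a passive, brief (< 200 ms), high-acceleration
head rotation of 100–300 °/s peak velocity delivered in a
semicircular-canal plane — a healthy vestibulo-ocular reflex (VOR)
rotates the eye almost exactly opposite the head, holding gaze on an
earth-fixed target. When the VOR is deficient, gaze is dragged along
with the head and the brain issues compensatory ("catch-up") saccades to
re-acquire the target, either during the impulse (*covert*) or after it
(*overt*). Video head impulse testing (vHIT) records head and eye
angular velocity at ~250 Hz; quantifying the reflex requires separating
the smooth slow-phase response from the superimposed saccades and
measuring both.

`vorsac` implements that separation pipeline: impulse detection, saccade
deconvolution, VOR gain, visual position error, saccade classification,
and cohort summaries, plus a synthetic-trial generator that provides
ground truth for every stage.

## Impulse detection

Derivatives of noisy velocity signals are estimated by convolution with
sampled Gaussian-derivative (Laplacian-of-Gaussian family) kernels
(`log_gradient()`), normalised exactly on the discrete grid so that a
ramp returns its slope and a quadratic its curvature. The default scale
is `sigma = 8` ms — two samples either side of centre at 250 Hz — which
suppresses sample noise without blurring ~150 ms impulse dynamics.

The impulse onset is defined geometrically: the time-axis intercept of
the line tangent to head velocity at peak head acceleration. Peak
acceleration and peak velocity are refined by three-point parabolic
interpolation, so landmark times are not quantised to the 4 ms sample
grid. The impulse ends at the first zero recrossing of head velocity
after its peak; the interval onset → zero crossing is the duration, the
integral of |head velocity| over it is the amplitude. Any opposite-sign
velocity lobe immediately after the zero crossing is summarised as
*bounce*, its peak expressed as % of the impulse peak velocity. Bounce
has no standard formula in the literature; this package defines it as
above and uses the same definition in its generator.

Gaussian smoothing attenuates the estimated peak acceleration slightly
(about 5% for a 150 ms sin² lobe at `sigma = 8` ms), which moves the
tangent intercept roughly 1.5 ms early. This is the dominant systematic
error in onset-referenced latencies and is well inside the one-sample
(4 ms) accuracy quoted for the detector.

Instead of the visual inspection used during clinical capture, traces
are accepted automatically when peak velocity lies in
[`min_peak_velocity`, `max_peak_velocity`] (default 100–300 °/s) and
duration is below `max_duration_ms` (default 200 ms); everything else is
rejected with a machine-readable reason code.

## The dual-Gaussian saccade model

Saccadic eye velocity in pupil-tracking video recordings shows a main
velocity lobe followed by a small opposite-sign oscillation of the iris.
Both are captured phenomenologically by

$$\hat v_{sac}(t) = A\,e^{-(t - t_{peak})^2 / 2\sigma^2}
                  - B\,e^{-(t - t_{peak} - 2\sigma)^2 / 2\sigma^2},$$

with the main lobe `A` (°/s, signed by direction), oscillation lobe `B`
(same sign, |B| < |A|), centre `t_peak`, and width `sigma` (ms). Its
integral — the saccade amplitude — has the closed form
$(A - B)\,\sigma\sqrt{2\pi}$, which every accepted fit satisfies to
1e-4 relative (the package integrates numerically and checks the
identity in its tests). Peak velocity and onset are read numerically
from a 0.1 ms grid; *onset* is the earliest time the waveform reaches 5%
of its peak velocity in the main-lobe direction. The generator uses the
identical convention, so latency recovery is convention-consistent.

## Localization: acceleration zero crossings with large jerk

Candidate saccades are located where the smoothed eye acceleration
crosses zero — the crests and valleys of eye velocity — with a jerk
magnitude above threshold. Two practical points:

* The slow phase itself has a velocity crest (at the impulse velocity
  peak) that would always qualify. The pipeline therefore first removes
  the predicted slow phase $-g_0\,v_{head}$, where $g_0$ is a robust
  median of $-v_{eye}/v_{head}$ over the impulse core (samples with at
  least 30% of peak head velocity). The median resists contamination by
  a covert saccade occupying a minority of the core.
* The jerk threshold defaults to `"auto"`: 5× the median absolute jerk
  of the pre-impulse baseline, floored at 2×10⁴ °/s³. The floor matters
  for clean recordings (a zero baseline would accept everything) and
  was placed an order of magnitude below the smoothed peak jerk of the
  smallest clinically reported saccades (~1.5°, ≈3×10⁵ °/s³) and well
  above residual slow-phase structure after $g_0$ removal.

Candidates earlier than 50 ms after impulse onset are discarded:
micro-saccades at such latencies belong to the fixation task, not the
compensatory response.

## Fitting: high-pass-filtered least squares by gradient descent

Parameters minimise

$$J = \sum \big(f_{HP} * (v_{eye} - \hat v_{sac})\big)^2 \,\Delta t$$

over a window `t_peak ± 6σ₀` (padded ±60 ms for filter state), where
`f_HP` is a first-order Butterworth high-pass at 3 Hz applied forward
and backward (zero phase). Penalising only the high-frequency error
means the smooth slow-phase signal under the saccade is *preserved*
rather than absorbed into the fit. The 3 Hz default reflects the energy
split: ≥150 ms slow-phase events concentrate below ~3 Hz while 10–30 ms
saccadic transients lie well above.

One subtlety: the slow-phase response to the impulse *bounce* lobe is
only ~D/2 long and passes a first-order 3 Hz high-pass almost
untouched. Fitting the raw eye velocity would let that structure bias
the saccade parameters, so the predicted slow phase $-g_0 v_{head}$ is
subtracted before fitting and the high-pass only has to absorb the
prediction *error*. With that correction, noise-free fits recover
injected parameters to better than 0.1%.

Minimisation is deterministic gradient descent with analytic gradients,
diagonal parameter scaling (A and B in units of the initial amplitude,
t_peak ~5 ms, σ ~3 ms), and backtracking Armijo line search;
convergence is declared when the relative decrease of J falls below
`tol = 1e-6` (cap 500 iterations, non-convergence flagged rather than
discarded). Initialisation is fully data-driven and deterministic:
`t_peak₀` at the candidate, `A₀` from the slow-phase-corrected velocity
there, `σ₀` from the flanking jerk sign changes (a Gaussian velocity
lobe has jerk zero crossings at exactly `t_peak ± σ`), `B₀ = 0.3 A₀`.
When another candidate saccade lies beyond the lobe's own structure
(3.5 σ₀), the fit window shrinks toward the half-distance so a fit
cannot widen itself to swallow its neighbour. There is no randomness
anywhere in the fit, so analyses are bit-reproducible.

Multiple saccades per trial are handled greedily: fit the largest-jerk
candidate, subtract the fitted waveform, re-localize on the residual, up
to `max_saccades = 3`. A backfitting refinement then re-estimates $g_0$
on the fully desaccaded signal and refits each saccade against the
residual of the others; two sweeps suffice for saccades ≥ 60 ms apart
(both recovered within 20% under noise; well-separated saccades within
10%). The descent is constrained to the physical parameter region —
σ in [2, 40] ms and an oscillation lobe of the same sign as, and
smaller than, the main lobe (B/A in [−0.05, 0.9]) — which prevents a
single widened Gaussian from swallowing two neighbouring saccades.
Fits with |A| < |B| or peak velocity under `min_peak_dps` (default
25 °/s, below the smallest clinically reported saccades) are treated as
noise and dropped. Where the original laboratory workflow
allowed manual re-fitting of ambiguous trials, this package instead
reports convergence flags, final J, and residual RMS and leaves
judgement to the analyst.

## Classification and sequencing

A saccade is *compensatory* when its main lobe opposes the head
movement (the catch-up direction), otherwise *anti-compensatory*;
*covert* when its peak falls before the head-velocity zero crossing,
otherwise *overt*. Sequence indices 1..n are assigned over compensatory
saccades only, in onset order — anti-compensatory saccades are fitted
and reported but never numbered, matching the restriction of clinical
saccade metrics to the catch-up direction.

## VOR gain and visual position error

Gain is a *position ratio*: cumulative desaccaded eye velocity over
cumulative head velocity from 60 ms before peak head acceleration to the
head-velocity zero crossing, signed so a compensatory response is
positive. Desaccading (subtracting all fitted waveforms before
integration) keeps covert saccades from inflating the gain — adding a 7°
covert saccade to a gain-0.2 trial moves the estimate by < 0.02 — and
`desaccade = FALSE` provides the raw ratio for comparison. Negative
gains are reported as-is. The estimator is exact on noise-free
synthetic trials across gains 0–1 and scale-invariant in both channels.

The visual position error integrates gaze-in-space velocity
(`v_head + v_eye`) from before the impulse. Integration drift is
anchored in two steps: the mean over a 100 ms pre-impulse baseline is
subtracted, and when the trace ends with ≥ 200 ms free of impulse and
saccade activity, the residual linear drift rate estimated from that
tail's slope is removed (gaze is stationary there, so any slope is
sensor drift). The error is reported at each saccade onset, positive
when gaze lags in the head direction: a gain-0 impulse of 15° leaves a
15° error at the zero crossing; a perfect VOR leaves none. The original
apparatus normalisation constants are unrecoverable, so this concrete
anchoring is the package's own; it reproduces the qualitative law that
pre-saccadic error grows as gain falls.

## Summaries

`summarize_records()` produces one row per (group, canal, condition,
sequence index) cell: accepted-impulse count, saccade frequency (% of
accepted impulses containing a compensatory saccade of that index),
mean amplitude and SEM, mean onset latency and SEM, and *clustering* —
the sample SD of onset latency, reported here explicitly in ms. Cell
statistics are plain means/SEMs over saccade-level observations;
marginal-mean regression adjustments for within-subject correlation are
out of scope. Frequencies are non-increasing in sequence index by
construction (a later saccade requires an earlier one), and total
counts are conserved against `count_saccade_totals()`.

## The synthetic generator

`generate_batch()` builds trials from a seeded configuration:

* **Stimulus**: a sin² velocity lobe — smooth, compactly supported,
  with closed-form amplitude $V_p D/2$ and closed-form tangent-intercept
  onset at $D(1/4 - 1/2\pi)$ — followed by an opposite-sign sin² bounce
  lobe of duration D/2. Per-trial peak velocity, duration and bounce are
  drawn from the cohort statistics of the modelled study (lateral canal
  in light: 204(45.6) °/s, 154(16.2) ms, 33(16.6)%); impulse directions
  alternate by default.
* **Eye response**: `-gain × v_head` plus injected dual-Gaussian
  saccades with the compensatory sign, plus white Gaussian velocity
  noise (default SD 3 °/s — typical of well-calibrated pupil tracking;
  blink artifacts are not modelled because the clinical workflow removed
  them before analysis).
* **Saccade injection**: regime k is injected only when k−1 was (a
  later saccade corrects an earlier one), with conditional probability
  `p_k / p_{k−1}` so the configured marginals are honoured and frequency
  monotonicity holds by construction; successive onsets are kept at
  least 100 ms apart (the saccadic refractory period — real second
  saccades follow the first by ~100 ms or more). Injected onset latencies are placed
  relative to the *analytic tangent-intercept onset* of the profile —
  the detector's reference — under the same 5%-of-peak onset convention
  the analyzer uses.
* **Ground truth** records every draw, and identical seeds reproduce
  identical batches byte-for-byte.

Cohort-level parameter sets for all 30 group × condition × canal
combinations are available through `scenario_presets()`. Where the
published tables report SEMs of marginal means rather than per-trial
spreads, the presets use a coefficient of variation of 0.25 for saccade
amplitude; the latency spread needs no such choice because the
published "clustering" value *is* the SD of onset latency. One
transcription caveat: the lateral/light peak-velocity spread is printed
as an implausible 456 where every neighbouring cell is ~45, and is
treated as 45.6.

### What the generator does and does not emulate

The generator reproduces stimulus envelopes, gain levels, saccade
timing/amplitude statistics, and sensor noise — enough to validate
detection geometry, deconvolution accuracy, and summary bookkeeping.
It does not emulate goggle slip, blink artifacts, pupil-tracking
dropouts, head-velocity sensor noise, trial-to-trial learning, or the
within-subject correlation structure of real cohorts. Passing recovery
tests therefore demonstrates correctness of the algorithms under the
stated signal model, not robustness to every failure mode of clinical
recordings.

## Validation scale and numerical choices

The test suite validates recovery at desk scale: 100-trial cohorts for
gain (recovered within ±0.02), 200 for amplitude (±0.3°) and latency
(±8 ms), 500 for frequency (within 3 binomial SEs), 50 noisy instances
for optimizer-vs-grid-search equivalence (J within 1%), and exhaustive
closed-form identity checks on every accepted fit. Degenerate inputs —
all-zero traces, non-recrossing velocity plateaus, sub-degree head
movements, missing baselines — raise classed errors rather than
propagating NaNs; ties in peak location fall back to the grid point.

## Known limitations

* Only one impulse per trace is detected; continuous multi-impulse
  recordings must be segmented upstream.
* Saccades closer than ~50 ms strain the deconvolution; amplitude
  errors grow toward 20% at 60 ms separation.
* The onset-latency reference carries the ~1.5 ms smoothing bias
  described above.
* Gain windows extending before the first sample (impulses starting
  < 60 ms into the trace) are refused rather than truncated.
* Statistical inference (GEE/GLMM marginal means, significance tests)
  is deliberately out of scope; the package emits the per-trial and
  per-cell quantities such models consume.
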