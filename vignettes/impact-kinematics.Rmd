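---
title: "Head-impact kinematics, histomorphometry and behavioral indices: methods"
author: "impactkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-impact kinematics, histomorphometry and behavioral indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactkin)
```

# The measurement chain

In a pneumatic closed-head impact (CHIMERA-type) experiment, a piston
strikes the intact skull of a supine mouse and the unrestrained head moves
freely in the sagittal plane. Head motion is recorded on high-speed video
(5,000 frames/s) via two markers — paint on the cheek and a dental-floss
mark on the snout — and all published kinematic quantities are derived from
those marker tracks by a fixed chain:

1. low-pass filter the raw X/Y coordinates (400 Hz Butterworth, zero
   phase);
2. differentiate discretely (central differences), forming resultant
   magnitudes from the X and Y components;
3. read off, for six quantities, the peak value and the time-to-peak from
   impactor contact.

`filter_track()`, `derive_kinematics()` and `summarize_peaks()` implement
the three stages; `kinematic_pipeline()` chains them in that fixed order.
An important consequence, which shapes the whole package: **peak
accelerations are properties of the chain, not of the raw trajectory**. A
400 Hz low-pass filter attenuates a millisecond-scale acceleration
transient appreciably, so the numbers a study reports are what the
filtered, sampled, differentiated record shows. The synthetic-trajectory
generator therefore solves its constraints against this exact chain (see
below), and the package's documentation consistently treats "peak
acceleration" as a filtered-chain quantity.

## Filter

A Butterworth low-pass applied forward and backward (zero phase, so
times-to-peak are not shifted). Two design details:

* **Order.** We use order 2 per pass — the classic phaseless 4-pole
  configuration of impact biomechanics. The steeper 4th-order-per-pass
  alternative was rejected on a measured ground: its bidirectional
  step-response slope limit at 400 Hz is about 0.91 ms^-1, which caps the
  recoverable angular acceleration at roughly 279 krad/s^2 for an angular
  velocity of ~306 rad/s — under 10% headroom above the peak this class of
  impact actually produces (≈254 krad/s^2). Near that ceiling the only
  waveforms that reach the published peak are degenerate steps whose
  filter ringing destroys peak-time estimates. Order 2 per pass raises the
  ceiling to ~327 krad/s^2 and leaves the recovery well-conditioned. The
  order is exposed (`order =`) for users who prefer the sharper filter.
* **Cutoff pre-warping.** A single Butterworth pass is −3 dB at its
  nominal cutoff, so two passes are −6 dB there. We pre-warp the design
  cutoff by `(sqrt(2)-1)^(-1/(2 order))` so the *effective* −3 dB point of
  the bidirectional filter sits exactly at the requested 400 Hz.

Edge transients are suppressed by odd-reflection padding before
`filtfilt`; the padded margin is discarded.

## Differentiation, baselines, onset

Velocities are central differences of position; accelerations are central
differences of the velocity components; resultants are Euclidean
magnitudes. The two boundary samples use one-sided differences and are
excluded from peak searches. The marker-pair angle is unwrapped across
±π before differencing (a 2.6 rad deflection sweeps far enough to make
this mandatory), and both the angle and the position baselines are the
means of the first five frames, during which the head must be at rest.

Impactor contact ("onset") is not annotated in a marker file, so it is
detected as the first frame where the resultant linear acceleration
exceeds a configurable fraction (default `onset_frac = 0.05`) of its
global maximum; all six times-to-peak are measured from that frame, and
the peak search runs over the full post-onset record.

With several impacts, the coefficient of variation of each peak is
SD/mean across animals of per-animal day-averaged peaks when animal ids
are supplied (each animal contributes the average of its repeated
impacts), or across pooled impacts otherwise.

## Impact energy and interspecies scaling

Head-equivalent kinetic energy is `KE = 0.5 * M_e * dV^2`
(`impact_energy()`), with the effective mass `M_e` approximated by head
mass (3.4 g for the mouse) and `dV` the change in resultant head velocity,
which equals the peak velocity because the head starts at rest. The
reporting convention rounds to two decimals in joules.

`scale_kinematics()` converts murine peaks to human-equivalent values
under equal-stress/equal-velocity scaling with
λ = (human brain mass / mouse brain mass)^(1/3) = 13.8 by default
(`mouse_to_human()`; the underlying brain masses are not part of the
interface — λ is an opaque constant). Velocity is invariant; lengths and
times scale by λ; the per-quantity exponents for the remaining peaks
(linear acceleration ÷ λ, angular velocity ÷ λ, angular acceleration ÷
λ²) follow from dimensional analysis within that framework. Angles are
dimensionless and unchanged. A scaled table is flagged and refuses to be
scaled again, except by the exact reciprocal factor, which restores the
original to machine precision.

# The synthetic trajectory generator

No raw videos are available, so downstream code is exercised on
constructed tracks. `impact_spec()` packages the six (value, time) peak
constraints; its defaults are the reference murine impact at 0.5 J input
energy (displacement 49.6 mm @ 15.7 ms, deflection 2.6 rad @ 24.8 ms,
velocity 6.6 m/s @ 3.4 ms, acceleration 385.3 g @ 1.5 ms, angular
velocity 305.8 rad/s @ 2.8 ms, angular acceleration 253.6 krad/s^2 @
0.8 ms, 5,000 frames/s). `gen_impact_trajectory()` then builds a
rigid-head two-marker track whose *analysis by the standard pipeline*
reproduces all twelve numbers — within 2% on values and one frame on
times — and optionally adds Gaussian tracking jitter.

Only peak summaries are published, not waveforms, so the profile shape is
the package's own construction, chosen so that each constraint maps onto
one parameter:

* **fast lobe** — the resultant acceleration is a Hann pulse of
  half-width `w` centered at the acceleration-peak time; the velocity
  gains `(1-γ)·V` in a smooth step around it. `w` controls the filtered
  peak acceleration;
* **approach** — a smoothstep carries the remaining `γ·V` (default
  γ = 0.15) from contact to the velocity-peak time, with zero slope
  there, so the velocity rises measurably into a well-conditioned apex
  instead of saturating into a plateau whose discrete maximum would be
  decided by filter ripple;
* **decay** — after the velocity peak, `u = V (1 - x^2)^g` falls to a
  zero crossing at the displacement-peak time, with `g` solved in closed
  form so the integral reaches the target displacement exactly there;
* **return** — a negative bump brings the head most of the way back
  (default 85% of peak displacement), reproducing the looped sagittal
  trajectory of a real impact; it is kept strictly sub-dominant so no
  peak is ever claimed by the return phase.

The same construction drives the deflection-angle profile; marker 2 sits
at a fixed 15 mm from the cheek marker along the deflection angle (rigid
head by construction), and a small lateral excursion (1.5 mm) in phase
with path progress closes the loop in the plane without perturbing the
resultants. The head is exactly stationary over the pre-impact frames
(default 16 at 5,000 frames/s); the angular fast lobe may begin a fraction
of a millisecond before nominal contact — the published angular
acceleration peak time (0.8 ms, with an SD larger than the mean) cannot
be reached by a causal pulse that is also smooth enough to survive the
filter — but never inside the five-frame baseline window.

The free parameters are solved by a damped fixed-point iteration that
repeatedly *runs the real pipeline* on the candidate track and nudges
effective targets (multiplicative on magnitudes; times only when more
than one frame off, to avoid chasing frame quantization). Infeasible
constraint sets — an acceleration too small to reach the velocity in
time, a displacement smaller than the rise-phase travel, mixed zero and
non-zero peaks — fail with an explicit error naming the violated
constraint; the generator never silently returns a best-effort track.

Tracking noise is isotropic Gaussian on each marker coordinate with
default SD 0.05 mm, a realistic sub-pixel jitter for high-speed video
tracking; it is added after the constraint solve, and a seed is required
whenever noise is requested.

What the generator does *not* emulate: skull or brain mechanics, impactor
contact dynamics, marker occlusion or tracking dropouts, and
non-sagittal motion. Passing round-trip tests therefore demonstrates that
the analysis chain is self-consistent and correctly implemented, not that
it is robust to every artifact of real videography.

# Impactor calibration

`fit_calibration()` fits exit velocity against air pressure with an
ordinary least-squares quadratic — the velocity domain is fitted (that is
what is measured), and energy is derived as `0.5 m v(p)^2`; replicates
enter the fit individually rather than as means. `required_pressure()`
inverts the curve for a target energy by root-finding on the calibrated
pressure interval and refuses extrapolation outside the calibrated energy
range (the practical operating range of the instrument is about
0.01–1 J).

`gen_calibration_table()` emulates a calibration session: the standard
pressure ladder 0.5–10 psi, three replicates per pressure, a quadratic
law plus Gaussian velocity noise. The default coefficients
(0.3, 0.75, −0.015) are the package's own choice — the study's raw
calibration points are not published — picked so the curve is monotone
over the ladder and spans the 0.01–1 J range with the 50 g piston.

# Histomorphometry

`boxcount_fd()` computes the box-counting fractal dimension the way the
standard FracLac workflow does: threshold, keep the largest connected
component, reduce to a one-pixel outline (foreground minus its 3×3
erosion), overlay box grids of sizes 2, 4, … up to a quarter of the
image side at four offsets per size keeping the minimum count, and take
minus the slope of log N(ε) against log ε. Known shapes anchor the
implementation: a straight line measures 1.00, a filled square (counted
without outline extraction) 2.00, and a 512-px Sierpinski triangle
1.585 = log 3 / log 2, each within ±0.05; the estimate is also invariant
to translation and 2× upsampling within the same band. D is reported
unclamped; values for planar outlines land in [1, 2] up to fit tolerance.

`cell_density()` divides an upstream (manual) count by the ROI mask area
converted to mm² — automated cell detection is deliberately out of scope.
`percent_positive()` thresholds a grayscale image (fixed cutoff, or Otsu
computed on the ROI histogram, since a manual threshold is not
reproducible) and reports the positive fraction of the ROI as a
percentage; it is monotone non-increasing in the threshold.

`gen_microglia_image()` draws binary silhouettes along the activation
continuum: `ramified` (small soma, five recursive generations of thin
tortuous processes), `hypertrophic` (thick soma, primary branches only),
`bushy` (stubby protrusions) and `amoeboid` (smooth blob with a gently
lobed boundary). The drawing parameters were set so the mean outline
fractal dimension decreases strictly along that sequence (about 1.46,
1.26, 1.20, 1.08 at 256 px), mirroring the qualitative ordering seen in
stained tissue; the generator produces clean connected silhouettes and
does not attempt to model staining variability, overlapping cells or
background texture.

# Behavioral indices

The open field is a 14 × 24 inch box divided into 60 equal squares — 6
columns across the short side and 10 rows along the long side, the
orientation that makes cells near-square — of which the 28 wall-touching
cells form the peripheral zone and the 32 interior cells the central zone
(`zone_partition()`). Samples landing exactly on a cell boundary belong
to the cell on their right/above (half-open intervals, left/bottom
inclusive). The thigmotaxis index is TI = (T_P − T_C)/(T_P + T_C)
(`thigmotaxis_index()`), +1 for pure wall-hugging, −1 for pure
center-dwelling.

`gen_openfield_track()` alternates wall-following bouts (a reflected
random walk in a perimeter coordinate, inset a random fraction of one
cell from the wall) with central excursions (a reflected walk in the
interior rectangle). The time budget is split deterministically between
the two states before the bout lengths are randomized, so the realized
peripheral fraction equals the target up to sampling resolution — the
controlled quantity is occupancy, not locomotor realism; inter-bout
transitions are instantaneous.

`nss_score()` counts failures over exactly ten pass/fail tasks (0 =
intact, 10 = maximal deficit; the task definitions themselves are opaque
inputs). `pa_latency()` applies the passive-avoidance convention: no
crossing within the session means the full 300 s ceiling, and recorded
crossings are capped there. `fold_change()` and `bonferroni_alpha()` are
the helpers used for biochemical endpoints (group mean over matched sham
mean; α/m, e.g. 0.05/5 = 0.01 for a five-timepoint family). Group-level
inference (repeated-measures ANOVA and post-hoc tests) is left to R's
standard routines on the tidy values these functions return.

# Numerical choices and problem sizes

* Internal units are SI (m, s, rad); print methods convert to mm, ms, g
  (9.81 m/s²) and krad/s² for reporting.
* Default record length for synthetic impacts is 80 ms (401 frames at
  5,000 frames/s), long enough for the deflection peak at 24.8 ms plus a
  return phase.
* The constraint solver runs at most 60 pipeline evaluations and
  converges in well under a second for the reference spec; its achieved
  errors are attached to the generated track (`attr(track,
  "generator")`).
* Test-suite problem sizes: morphology ordering uses 20 seeds per class
  at 256 px; calibration noise recovery uses 100 simulated sessions;
  filter oracles use 2,000-sample sinusoids. The full suite runs in
  about 10–15 s on one CPU.

# Known limitations

* The generator's peak constraints are defined through the filtered
  measurement chain; the raw (unfiltered) accelerations of a generated
  track are correspondingly larger than the constraint values, most
  visibly for the narrow angular-acceleration transient. Raw velocity,
  displacement, deflection and angular velocity agree with the
  constraints within 2%.
* Box-counting on shapes touching the image border loses grid offsets;
  generated silhouettes keep a margin.
* The open-field generator controls zone occupancy exactly but produces
  teleporting transitions between zones; speed- or immobility-based
  endpoints should not be computed from it.
* `required_pressure()` only inverts within the calibrated range — this
  is a feature (interpolation was the instrument's documented use), not a
  numerical limitation.
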