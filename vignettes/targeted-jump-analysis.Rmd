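---
title: "Targeted-jump kinematics: models, estimators and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted-jump kinematics: models, estimators and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`katyjump` analyses 2-D digitized tracking of a predatory glass katydid
jumping onto overhead targets.  The animal sits on a substrate, sways to
gauge distance by motion parallax, then leaps vertically and rotates its
body through half a turn so that it lands inverted on the underside of a
target 50, 75 or 100 mm above.  The package turns per-frame coordinates
of four tracked body points (head, abdomen tip, femorotibial joint,
tarsus) into take-off kinematics, energy budgets, a mechanical null
model, and a ballistic flight simulator -- and, because the original
videos are not required, ships a synthetic-study generator that
reproduces the study's statistical structure with known ground truth.

## Coordinate and estimator conventions

Files are comma-delimited with 0-based frame indices; the y axis points
up (image-coordinate files are read with `y_flip = TRUE`).  The time
column is a consistency check only: time is always recomputed as
`frame / frame_rate`.  Missing points are an error rather than being
interpolated, because interpolation silently distorts finite
differences.

The body is treated as a uniform rod; its centroid is the head/abdomen
midpoint and the body angle is the angle of the abdomen-to-head vector,
unwrapped across frames so that multi-revolution rotations never alias.
Two velocity estimators are exposed:

* **secant** -- displacement (or unwrapped angle change) between the
  frames of interest divided by elapsed time.  The field convention
  divides by the *number of frames*; we divide by elapsed time
  (`frames / frame_rate`), since otherwise the units would be per-frame
  rather than per-second.
* **local** -- least-squares slopes of centroid position and unwrapped
  angle over a short window (default 5 frames).  `analyze_jump()`
  evaluates the take-off values over the first airborne frames only, so
  the slower stance phase cannot bias the slope.  On a ballistic path
  the linear-speed estimate is centred `window / 2` frames after
  take-off, giving a known discretization bias of about
  `g * window / (2 * frame_rate)` (0.01 m/s at 2000 Hz), which the
  recovery tests account for.

Take-off is detected as the first frame at which the tarsus clears the
substrate by more than 0.5 mm and stays clear; target contact as the
first frame at which the head is within 1 mm of the target height.
Contact can therefore only fire early, never late; when the head crosses
the target slowly (a near-apex approach), the 1 mm band can span several
frames, and a tighter tolerance moves the detection closer to the
geometric crossing.  The femorotibial (FTJ) angle is the interior angle
at the joint between the rays toward the abdomen tip (the closest
tracked proxy for the femur-proximal direction -- the anatomical hip is
not among the four tracked points) and toward the tarsus; the
stationary-posture value averages the first ten frames to suppress
digitization noise.

## Energy budget and the calibrated body length

With mass $m$, body length $L$, take-off speed $v$ and spin $\omega$,
the rod model gives $I = mL^2/12$, $E_{\mathrm{trans}} = mv^2/2$,
$E_{\mathrm{rot}} = I\omega^2/2$, and the rotation fraction
$100\,E_{\mathrm{rot}}/(E_{\mathrm{rot}}+E_{\mathrm{trans}})$, which is
mass-free.  The study animals' body length is not reported, so the
package derives a single calibration constant by solving the
rotation-fraction equation at the 50-mm condition (speed 1.40 m/s, spin
47.36 rad/s, fraction 2%), giving $L = 14.63$ mm:

```{r}
L <- calibrate_body_length(1.40, 47.36, 2)
round_sigfig1(rotation_fraction(1.55, 38.10, L))  # 75 mm  -> 1
round_sigfig1(rotation_fraction(1.79, 31.80, L))  # 100 mm -> 0.6
```

Because $L$ is fixed at 50 mm once, the 75- and 100-mm fractions are
genuine cross-checks, not fits.  Per-jump fractions are reported
unrounded and averaged per height; note that averaging per-jump
fractions (a convex function of noisy spin) yields systematically larger
values than evaluating the fraction at the mean velocities -- both
routes are available, and the calibration deliberately uses the
mean-velocity route.

## The rigid-beam null model

Modelling the body as a uniform rod with the leg force applied at moment
arm $l$ from the centre of mass couples linear and angular acceleration
-- and, integrated over a fixed-posture stance, the take-off velocities
-- as $v/\omega = L^2/(12\,l)$.  If the animal modulated jump height by
leg force alone, speed and spin would rise together (positive rank
correlation); `null_hypothesis_test()` checks exactly this sign with a
self-contained Spearman statistic and permutation p-value.  Observed
studies of this behaviour show the opposite sign -- faster but
slower-spinning jumps at higher targets -- implying a posture change
that shrinks the effective arm, which `posture_arm()` quantifies per
jump ($l = \omega L^2/(12 v)$, a descriptive, fitted quantity, never a
measurement).

## Flight simulator

After take-off the simulator uses drag-free closed-form projectile
motion plus constant body rotation (sampled, never numerically
integrated; an independent Euler integrator serves as a test oracle).
Air drag and in-air limb manoeuvres are out of scope: for these short
flights (tens of milliseconds) pre-take-off posture is the dominant spin
control.  An inverted overhead landing requires a rotation of $\pi$
between take-off and contact; `simulate_flight()` flags success when the
contact rotation is within 0.35 rad (about 20 degrees) of $\pi$, a
configurable operationalization of "landed and held on".  Gravity
defaults to 9.81 m/s^2.

## The synthetic study

`simulate_study()` emulates the study conditions: 7 animals (5 male, 2
female), masses uniform on 0.0678-0.0822 g, 151 jumps split 47/53/51
across the 50/75/100 mm targets, filmed at 2000 Hz, hind legs exactly
1.37 body lengths.  Each response (take-off speed and spin, stationary
and take-off FTJ angle) follows

\[ y_{ijh} = \mu_h + a_i + \varepsilon_{ijh}, \]

with per-height means set to the reported values (speed 1.40/1.55/1.79
m/s; spin 47.36/38.10/31.80 rad/s; take-off FTJ 129/136.5/144 degrees)
and the between-jump SD recovered from the reported standard errors as
$SE\sqrt{n_h}$.  Half of that SD (in quadrature) is assigned to the
per-animal intercept $a_i$ -- the study reports no variance components,
so `animal_sd_fraction = 0.5` is an explicit, exposed assumption.
Values not reported anywhere were fixed once: the 75-mm take-off FTJ
mean (136.5 degrees, the midpoint of the printed endpoints, matching the
reported monotone increase) and SE (3.5), the stationary FTJ mean (100
degrees, SE 4; only "no height difference" is reported), the resting
body angle (45 degrees), and a 12-mm stance travel.

Draws are truncated to physically admissible values: the vertical
take-off speed must carry the *head* to the target
($v_y \ge \sqrt{2g(h + L/2 - y_0)}$, slightly stronger than the
centroid bound so synthesis can never strand a jump short), spin is
positive, and FTJ angles stay in (60, 178) degrees so the leg pose
remains constructible.  Truncation is **mean-preserving**: the
pre-truncation location is solved numerically so the truncated draw
keeps the configured conditional mean -- naive truncation would inflate
the 100-mm speed mean far above its target value.

Each trajectory has three phases sampled at the frame rate: at least ten
stationary frames; a constant-acceleration stance (the simplest profile
consistent with a constant leg force) reaching the take-off state at
centroid height `y0` while the FTJ opens linearly from its resting to
its take-off angle; and closed-form ballistic flight with constant
rotation until the head reaches the target.  Head and abdomen tip sit at
$\pm L/2$ along the body axis (an exactly rigid rod); while the feet are
grounded, the knee is placed at the apex of the inscribed-angle arc over
the hip-tarsus chord, which realizes any interior FTJ angle exactly (the
implied leg segment lengths vary with posture -- no estimator uses
them); in flight the leg folds against the body.  Gaussian noise
(SD 0.1 mm) is added to every coordinate.

Two reported quantities cannot all be honoured at once: take-off spin
(about 47 rad/s at 50 mm), air time (about 20 ms at 50 mm) and a full
$\pi$ rotation in flight are mutually inconsistent
($47 \times 0.020 \approx 0.95$ rad).  The generator keeps the measured
quantities -- velocity means and ballistic air times, reconciled by a
take-off centroid height of `y0 = 0.024` m, which brackets the reported
20-44 ms air times -- while the $\pi$-rotation landing criterion lives
in the flight simulator, where `required_av()` answers "what spin would
an inverted landing need".  Generated study jumps therefore rotate less
than $\pi$ between take-off and contact, and per-jump "success" in the
pipeline means the target was reached.

What passing tests do and do not show: the generator exercises the full
estimation path (event detection, windowed slopes, angle unwrapping,
joint geometry, noise propagation), so recovery results demonstrate
estimator correctness and calibration under the assumed structure.  It
does not emulate digitization dropouts, lens distortion, out-of-plane
motion, flexible-abdomen bending, or in-air spin changes (reported at
100 mm), so real-data performance on those axes is untested.

## Inference

The height effect is tested by an animal-stratified permutation test:
the statistic is the between-height weighted sum of squares of height
means of within-animal-centred values, and the null is built by
permuting height labels *within* each animal, conditioning on the
repeated sampling of each individual.  P-values use the add-one rule
$(b+1)/(m+1)$.  Pairwise contrasts reuse the same test with Holm
correction.  The original mixed-model stack (REML, Satterthwaite,
marginal-means post hocs) is intentionally not re-implemented: it is
off-the-shelf machinery, and the permutation test answers the same
question exactly under weaker assumptions.  A mixed-model fit can always
be layered on the results table externally.

Summaries report both the naive SE and an animal-level (cluster) SE --
the SD of per-animal means over $\sqrt{7}$ -- since with seven animals
the intercept draw, not the jump count, dominates the uncertainty of a
height mean.  Recovery checks compare estimated height means to the
configured ones using the SE of the difference,
$\sqrt{SE_\mathrm{reported}^2 + SE_\mathrm{cluster}^2}$.

## Problem sizes and numerical choices

The default study (151 jumps, about 150 frames each) simulates and
analyses in a couple of seconds, so tests run it in full; unit tests use
a 12-jump variant.  Type-I error of the permutation test is calibrated
over 200 null replicates at 199 permutations each; production tests use
999.  Tolerances trace to their sources: 1e-9 m for IO round trips
(full-precision text), one frame for event detection, `g/frame_rate`
per window frame for ballistic speed slopes, 1e-12 relative for
algebraic identities.  Ties in angle wrapping map differences to
$(-\pi, \pi]$; degenerate geometry (coincident points, zero moment arm,
unreachable targets) raises labelled errors rather than propagating
NaNs.

## Limitations

Everything is 2-D sagittal-plane; yaw and roll are ignored.  The
energy budget counts take-off kinetic energy only (no elastic storage or
muscle work).  The moment arm is an effective parameter of a one-force
rod model, not an anatomical measurement.  The calibrated body length
inherits the rounding of the values it was solved from; treat 14.63 mm
as a reporting constant, not a morphometric claim.
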