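---
title: "Analyzing robot-assisted needle driving: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing robot-assisted needle driving: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlekin)
```

## The problem

Driving a curved surgical needle through soft tissue is one of the defining
bimanual skills of surgery, and one of the tasks most affected by the loss
of haptic feedback in robot-assisted minimally invasive surgery (RAMIS).
`needlekin` implements a surgeon-centered analysis of this task: from raw
6-DOF tooltip recordings (position, orientation, gripper state) synchronized
with tissue-interaction forces and torques, through trial and subtask
segmentation, to a suite of fifteen performance metrics and the
nonparametric statistics of a three-condition learning experiment (no force
feedback, position-exchange feedback, direct force-sensor feedback; NF, PE,
DF).

Because raw human-subject recordings of this kind are rarely deposited, the
package includes a first-class synthetic-data module that generates single
trials, whole cohorts, and special-purpose trajectories with known ground
truth. Every downstream stage is tested against these constructions.

## Teleoperation feedback models

Two simple force-feedback controllers are modeled. Position exchange
renders a force proportional to the error between the desired (master) and
current (patient-side) tooltip state,

$$ f = K_P\,(x_{des} - x_{cur}) + K_D\,(\dot x_{des} - \dot x_{cur}), $$

with defaults $K_P = 1000$ N/m and $K_D = 30$ N·s/m, so a pure position
error of 1 mm produces 1 N. Direct feedback transmits the force-sensor
reading scaled by $G_{DF} = 0.7$, the largest gain at which operators can
comfortably stabilize the coupled system. The master-to-patient translation
scaling is 0.4 and the force-sensor noise floor is 0.06 N; both live in
`feedback_params()` alongside the gains.

```{r}
p <- feedback_params()
pe_feedback_force(c(1e-3, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), p)
df_feedback_force(c(1, 0, 0), p)
```

## Preprocessing

Raw recordings arrive at 120 Hz (open instrument, magnetic tracking) or
500 Hz (teleoperation). `preprocess_trial()` brings every trial onto a
uniform 100 Hz grid and computes filtered derivatives:

* position, force and torque are interpolated with shape-preserving
  piecewise-cubic (monotone Hermite) interpolation, which cannot overshoot
  the data hull;
* orientation is interpolated per interval with spherical linear quaternion
  interpolation after enforcing sign continuity
  ($\langle q_n, q_{n+1}\rangle \ge 0$), which prevents spurious
  $2\pi$-complement rotations from the quaternion double cover;
* the gripper channel is categorical and uses nearest-previous-sample
  interpolation;
* the tooltip position is filtered with a 2nd-order 10 Hz Butterworth
  low-pass applied forward and backward (zero phase). The double pass has
  an empirical −3 dB point of 8 Hz;
* velocity, acceleration and jerk come from central differences, each
  re-filtered with the same zero-phase filter. Force and torque are *not*
  low-pass filtered, so the force-threshold structure used by segmentation
  is preserved.

Two numerical choices deserve mention. First, the zero-phase filter uses
odd-reflection padding with steady-state initial conditions, and the pad
length is sized from the slowest filter pole so that edge transients decay
below 1e−12; this makes filtering exactly DC-preserving and time-reversal
symmetric, at the cost of requiring trials longer than about 1.3 s at
100 Hz. Second, derivative accuracy is an interior property: the first and
last few dozen samples carry one-sided-difference and transient error, so
all polynomial-exactness tests assert on the interior only.

## Segmentation

A trial runs from the first to the last sample at which the force
magnitude exceeds the 0.06 N noise threshold *and* the tooltip projects
inside the tissue outline (both conditions simultaneously, so accidental
contact with the fixture is ignored). Within those bounds, samples with a
closed gripper and suprathreshold force form the needle-driving runs; the
first run is the insertion, the last the extraction, and intermediate runs
are corrections when their mean projected position is closer to the
entrance than to the exit point. Gaps between runs are repositioning.

Three rules are the package's own where the task definition is silent:
the "closer to entrance" test uses the run's mean tooltip position
projected on the tissue plane; a single continuous run is labeled
insertion (the insertion always exists, the extraction may be merged into
it); and the last run wins over the closer-to-exit rule, which otherwise
could label a middle run extraction before the final run. The
gripper-closed threshold is a configuration value (default 0.5 on the
gripper channel) since no physical threshold is dictated by the data
model. `override_bounds()` lets manually validated bounds replace the
automatic ones, mirroring a human review step, but there is no GUI.

## The metric suite

Per trial (and per subtask; the insertion is scored by default, since it
dominates the task — its median relative duration is about 51%), the
package computes:

* **Task performance** — completion time $t_{end} - t_{start}$; exit-point
  error, the in-plane distance between desired and actual exit points
  (teleoperation trials only, where calibrated cameras provide the exit
  point).
* **Force** — total normalized force
  $\tfrac{1}{d_{ie}}\sum_n |f(n)|\,\Delta t(n)$ with $d_{ie}$ the
  entrance-to-exit distance; maximum force; maximum $|\tau_z|$ about the
  tissue normal (ideally zero: a correct drive is planar); and force
  consistency, the DTW-aligned dispersion of five consecutive force
  profiles.
* **Kinematics** — path length; circle deviation
  $\tfrac{1}{\Theta_{arc}}\sum_n s^2(n)\,\Delta\theta(n)$, the squared
  radial deviation of the plane-projected path from its fitted circle
  (for an ideal drive the fitted circle has the needle's radius, 18.7 mm
  for the large half-circle needle modeled here); plane deviation
  $\tfrac{1}{PL}\sum_n r^2(n)\,\Delta x(n)$; normalized angular path, the
  accumulated quaternion geodesic angle per meter of tooltip travel; and
  DTW trajectory consistency.
* **Motor-control-grounded** — the speed–curvature–torsion power law
  $v = \alpha\,\kappa^{\beta}\,|\tau|^{\gamma}$ fitted by ordinary least
  squares in log space (the theoretical scribbling exponents are −1/3 and
  −1/6), and the duration-normalized RMS jerk, reported as $\log_{10}$
  because it spans orders of magnitude.

Design choices in this suite that were genuinely open:

* The plane fit regresses the out-of-plane coordinate on the two in-plane
  coordinates, but in a frame chosen by PCA of the path rather than the
  fixed world frame. Needle-insertion planes are near-vertical, where a
  fixed world-z regression is rank-deficient; the PCA frame keeps the
  regression well conditioned for any plane orientation and reduces to the
  world-frame regression for near-horizontal movements.
* The circle fit is algebraic (Kasa) followed by geometric refinement
  (BFGS with analytic gradient plus a Gauss–Newton polish). The polish
  matters: it drives the minimizer to machine precision so the metric is
  rigid-motion invariant to ~1e−12 rather than to the optimizer's
  termination tolerance.
* $\Theta_{arc}$ uses the fitted radius by default, with a switch to a
  nominal needle radius: the fitted radius keeps the metric self-contained
  when the true needle is unknown.
* The maximum torque uses $|\tau_z|$, making the metric sign-invariant;
  the ideal value is zero either way.
* DTW uses squared-Euclidean local cost and the symmetric step pattern
  without a window; profiles are aligned to the medoid (the profile with
  the smallest summed DTW cost to the others), averaged pointwise on the
  medoid's time base, and scored as the mean summed squared distance to
  that average. The consistency metric is zero iff the profiles are
  identical after alignment.
* Power-law samples with speed below 1e−4 m/s or $|\tau|$ below 1e−6 1/m
  are excluded (the log of a vanishing torsion is unbounded); the fit
  requires at least 10 valid samples.
* The double-exponent notation in the consistency definitions is read as
  the standard sum of squared Euclidean distances, not a fourth power.

## Statistics

Per-trial values are collapsed to block medians of 5 trials at four
stages: late baseline (open-1 late), early and late teleoperation, and
early post-teleoperation (open-2 early). Three contrasts are formed per
participant: learning (tele late − tele early), aftereffect (open-2 early
− open-1 late) and final performance (tele late − open-1 late). Each
metric × contrast × condition cell gets the median difference, a
two-sided Wilcoxon signed-rank p (exact for n ≤ 25 without ties, normal
approximation with tie correction otherwise; exact zeros are dropped
first, the classic convention) and a nonparametric bootstrap percentile
CI of the median (10,000 resamples of participants by default). Each
metric × contrast additionally gets a Kruskal–Wallis test across the
three conditions with tie correction and a chi-squared reference, plus
pairwise two-group comparisons whose location difference is reported as
the difference of pooled mean ranks — a rank-based effect size that the
twin table documents on its own terms. A `p_method = "permutation"`
option enumerates the exact permutation distribution of H for small
samples. No multiple-testing correction is applied by default;
Benjamini–Hochberg columns are available via `p_adjust = "BH"`.

Metrics that are unavailable in a setup (exit-point error and total
normalized force exist only in teleoperation) propagate as explicit `NA`
cells in every contrast touching an open stage, never as zeros.

## The synthetic-data module

`generate_trial()` builds a complete trial in the tissue surface frame:
the tooltip approaches from outside the tissue outline, drives the needle
along a circular arc (radius 18.7 mm, sweep 150°) whose plane is vertical
and contains the horizontal diagonal, lifts off between driving runs, and
retreats after extraction. Forces follow the phase pattern of a correctly
executed trial: correlated horizontal components during insertion with a
mid-insertion sign reversal of the vertical component, small (< 0.06 N)
transients during repositioning, and a vertical-dominant extraction pull.
Waveforms are smooth sinusoidal envelopes — the qualitative phase
structure is the contract, asserted qualitatively in tests, not any exact
waveform. The default subtask schedule gives the insertion 50.9% and the
extraction 16.5% of the bounded trial, following the observed median
relative durations for this task; repositioning absorbs the remainder
because observed medians (which include optional corrections) are not
additive. Default noise magnitudes (0.15 mm positional jitter, 0.4 mm
out-of-plane ripple, 0.3 mm radial drift, 4 mN force noise) are set to
what magnetic/robotic tracking of a hand-held tool realistically shows;
the tissue's force-deflection behavior is not modeled — force magnitude
is a free parameter with a 2.5 N default peak.

`generate_powerlaw_trajectory()` time-reparameterizes a geometric base
path so the sampled speed obeys $v = \alpha\kappa^\beta|\tau|^\gamma$
exactly. The default base path is a perturbed rising sweep whose
curvature (11.7–18.5 1/m) and torsion (1.1–6.2 1/m) vary at
incommensurate frequencies and stay bounded away from zero — torsion
near zero makes the reparameterized speed blow up and is rejected. The
canonical law-exact check uses a slow tempo ($\alpha$ = 0.015 m/s,
≈ 170 s of trajectory), keeping the temporal frequency content far below
the 10 Hz filter so that numerically differentiated curvature and
torsion recover the generating exponents to better than 1e−3 with
$R^2 > 0.999$.

`generate_cohort()` draws per-trial *metric values* for 3 × 10
participants × 120 trials (4 open blocks, 6 teleoperation blocks, 2 open
blocks of 10 trials) from a per-metric effect model: a baseline, log-normal
trial and participant variability for strictly positive metrics (Gaussian
for sign-carrying ones — the power-law exponents and log-jerk), a
teleoperation offset, and a learning effect that elevates the metric at
the start of teleoperation and decays linearly to zero by its end.
Effects are additive on the log scale for positive metrics precisely so
that injected learning can never drive them negative. Default magnitudes
are set to the order of magnitude reported for inexperienced operators
(e.g. a ≈ 5 s completion-time improvement during teleoperation, a
teleoperation slowdown of roughly 2× against the open baseline, lower
jerk under teleoperation because the robot's dynamics damp the hand);
by default the three conditions share the same effects, matching the
empirical finding that condition differences were absent, and
`learning_scale` can inject condition differences when a non-null
Kruskal–Wallis is wanted. `materialize_trial()` turns a cohort row into
a full raw recording (120 Hz open / 500 Hz teleoperation) whose bounded
duration and peak force follow that row, which is how the end-to-end
pipeline is exercised; only the duration and force-scale parameters are
materialized, so pipeline-level recovery checks target those.

What the generator deliberately does not emulate: tissue mechanics (no
deformation or friction model), hand tremor spectra, visual-feedback
strategy changes, or participant-specific movement styles. Passing tests
therefore certify the *analysis* — segmentation rules, metric formulas,
statistical calibration — on data with the assumed structure, not any
claim about real surgical recordings.

## Problem sizes and calibration checks

The test suite and the acceptance script size their simulations for a
single CPU: the statistical calibration uses 100 replicate cohorts
(metric-level, 30 × 120 trials each) for the null false-positive rate
(≈ 4.9% at the 0.05 level over 2700 cells) and the learning detection
power (100% for the default completion-time effect, whose per-participant
effect-to-noise ratio is large); bootstrap coverage is checked with 1000
simulated n = 10 Gaussian samples at 1000 resamples each; the end-to-end
pipeline check materializes 75 full trials. The noise-free cohort defines
the injected truth for the learning-delta recovery check, and estimates
agree within the simulation's standard error.

## Known limitations

* The effect model generates per-trial values for the two consistency
  metrics as if they were trial-level scores; in the real pipeline they
  are stage-level statistics over five aligned profiles. The pipeline
  path computes them correctly; the cohort shortcut treats their block
  median as the stage value, which preserves the statistical structure
  the contrasts need but not the metric's literal definition.
* Exit points are data inputs. Extracting them from camera images is out
  of scope, as are hardware interfacing, gravity compensation and
  closed-loop stability analysis.
* The permutation option of the Kruskal–Wallis test enumerates the full
  assignment distribution and is limited to small groups; the chi-squared
  reference is the default, as in the analysis this package mirrors.
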