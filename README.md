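# needlekin

Surgeon-centered analysis of robot-assisted surgical needle driving.

`needlekin` is for researchers in surgical robotics and human motor control
who record 6-DOF tooltip kinematics (position, orientation, gripper state)
together with tissue-interaction forces and torques while a person drives a
curved needle through soft tissue — in teleoperation (e.g. on a da Vinci
class system, with or without force feedback) or with a hand-held needle
holder. The package turns those raw, variable-rate recordings into
per-trial performance metrics and the statistics of a learning experiment,
and ships a synthetic-data module that generates trials and whole cohorts
with known ground truth so the entire pipeline is testable without any
human-subject data.

## What it computes

**Preprocessing.** All channels are resampled to a uniform 100 Hz grid
(shape-preserving cubic interpolation; quaternion slerp with sign
continuity for orientation), the tooltip position is filtered with a
zero-phase 2nd-order Butterworth low-pass (10 Hz design, 8 Hz effective
cutoff for the double pass), and velocity, acceleration and jerk are
obtained by central differences with re-filtering after each step.

**Segmentation.** Trial bounds are the first/last samples with force above
the 0.06 N sensor noise threshold *and* the tooltip inside the tissue
outline. Samples with a closed gripper and suprathreshold force form the
needle-driving runs: first run = insertion, last = extraction, intermediate
runs = correction when nearer the entrance than the exit; gaps are
repositioning.

**Metrics** (per trial, insertion subtask by default):

| class | metrics |
|---|---|
| task performance | completion time `t_end − t_start`; in-plane exit-point error `‖x_desired − x_actual‖` |
| force | total normalized force `(1/d_ie) Σ |f(n)| Δt(n)`; max `|f|`; max `|τ_z|`; DTW force consistency |
| kinematics | path length; circle deviation `(1/Θ_arc) Σ s²(n) Δθ(n)`; plane deviation `(1/PL) Σ r²(n) Δx(n)`; normalized angular path; DTW trajectory consistency |
| motor control | speed–curvature–torsion power law `v = α κ^β |τ|^γ` (log-space OLS; theoretical scribbling exponents β = −1/3, γ = −1/6); log₁₀ duration-normalized RMS jerk |

**Statistics.** Block medians of 5 trials at four stages, three
pre-registered contrasts per participant (learning = tele late − tele
early; aftereffect = open-2 early − open-1 late; final performance = tele
late − open-1 late), two-sided Wilcoxon signed-rank tests (exact null for
n ≤ 25 without ties), Kruskal–Wallis across the three feedback conditions
(NF / PE / DF) with an exact-permutation option, and bootstrap percentile
confidence intervals of the median.

## Worked example

Generate one synthetic teleoperation-style trial, preprocess, segment and
score it:

```r
library(needlekin)

gt  <- generate_trial(trial_config(seed = 42))
seg <- classify_segments(preprocess_trial(gt$trial), gt$geom)
seg
#> <segmented_trial> bounds [100, 649] of 701 samples
#>    outside  insertion correction reposition extraction
#>        151        280          0        180         90

round(relative_durations(seg), 3)
#>  insertion correction reposition extraction
#>      0.509      0.000      0.327      0.164

compute_trial_metrics(seg, gt$geom)
#> completion_time          2.79        (s; insertion subtask)
#> exit_point_error         0.0015      (m)
#> total_normalized_force   136.2       (N·s/m)
#> max_force                2.508       (N)
#> max_torque_z             0.007572    (N·m)
#> path_length              0.037       (m)
#> circle_deviation         1.908e-07   (m·rad)
#> plane_deviation          8.472e-08   (m²)
#> angular_path             49.52       (rad/m)
#> powerlaw_beta            -0.347
#> log_jerk                 0.4062      (log10 m/s³)
```

The insertion occupies 50.9% of the bounded trial (the observed median for
this task), the tooltip path hugs the 18.7 mm needle arc (circle deviation
≈ 2·10⁻⁷ m·rad), and the fitted curvature exponent is already close to the
−1/3 power-law value typical of human movement.

A full cohort (30 participants × 120 trials, three feedback conditions)
with injected learning, analyzed end to end:

```r
co  <- generate_cohort(cohort_config(seed = 1))
res <- run_full_analysis(co, metrics = "completion_time", B = 2000, seed = 1)
res$signed_rank[res$signed_rank$contrast == "learning", ]
#>   metric          contrast condition delta       p ci_lower ci_upper  n
#> 1 completion_time learning        NF  -5.18 0.00195    -5.41    -3.72 10
#> 2 completion_time learning        PE  -6.41 0.00195    -6.64    -4.63 10
#> 3 completion_time learning        DF  -4.82 0.00195    -8.28    -2.36 10
```

Each condition improves its completion time by about 5 s across the
teleoperation phase (negative delta = faster late than early), significant
by signed-rank test in every group — the injected learning effect,
recovered.

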