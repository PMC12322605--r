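---
title: "Quantifying hand motion control from landmark trajectories: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hand motion control from landmark trajectories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Webcam-based hand-pose estimators return, per video frame, 21 labelled hand
landmarks with 3D coordinates in normalized camera units (wrist = landmark 0,
thumb tip = landmark 4). A hand-rotation task — repeatedly pronating and
supinating the hand as fast and as fully as possible for a fixed 10-second
trial — turns that stream into a motor-control probe: older adults rotate
fewer times, through smaller excursions, than young adults, and the trial
structure (two hands, three trials) exposes learning effects. `handrot`
implements the full chain from landmark trajectories to group-level
inference, plus synthetic generators that make every stage testable with
programmed ground truth.

## Rotation angle from the palm vector

Palm orientation is summarized by the wrist-to-thumb-tip position vector
$\mathbf{v} = \mathbf{p}_4 - \mathbf{p}_0$. The rotation angle
$\theta \in [0^\circ, 180^\circ]$ is defined by the convention: $0^\circ$
when the palm faces the camera and $180^\circ$ when the back of the hand
faces the camera. Because the task is performed seated with the forearm
upright, pronation/supination is a rotation about the camera-frame vertical
($y$) axis. We therefore take the angle of the shortest-arc quaternion about
$y$ that maps the canonical palm-forward reference direction onto the
observed palm vector projected into the horizontal $x$–$z$ plane;
numerically $\theta = \operatorname{atan2}(|v_x r_z - v_z r_x|,\;
v_x r_x + v_z r_z)$ with $\mathbf{r}$ the reference direction. This makes
$\theta$ exactly invariant to translation, uniform scaling and vertical
wobble of the hand, well defined at both endpoints, and requires no
physical calibration (coordinates stay in the estimator's normalized
units — every downstream quantity is scale-free). A frame whose palm vector
has no horizontal component (tracking collapse) is flagged degenerate; its
angle is linearly interpolated when the gap is short (default at most 5
frames) and otherwise splits the series, so no rotation is ever scored
across a tracking loss.

The synthetic template (`hand_template()`, `make_pose()`) realizes the same
convention: a stylized 21-landmark palm-forward hand rotated by $\theta$
about the vertical axis through the wrist, so
`rotation_angle(make_pose(theta))` recovers $\theta$ to floating-point
precision. This round trip anchors the angle tests.

## Segmentation into full rotations

A full rotation is one half-excursion in each direction, nominally
$0 \to 180 \to 0$ degrees ($360^\circ$ total) in about 30 frames at 30 fps
(one frame $\approx 0.03$ s). Per frame we estimate the signal slope by
ordinary least squares over a centered 5-frame window (truncated to at
least 2 frames at the edges; the window length is the `window_frames`
parameter). Frames are labelled *increase* / *maintain* / *decrease* by the
slope sign with a deadband (default 1 deg/frame; a slope of exactly the
deadband counts as maintain). A reversal is the first frame where the
nonzero direction flips.

Two numerical choices matter here:

* **Amplitude at the extremum, not the reversal frame.** The 5-frame slope
  lags the signal, so theta at the detected reversal frame understates the
  excursion. The excursion boundary is refined to the local extremum of
  theta between the last frame of the old direction and the first frame of
  the new one.
* **Boundary anchors stay near the motion.** On long motionless stretches
  theta is flat and its extremum carries no boundary information — under
  noise an unrestricted argmin would land anywhere in the stretch. Opening
  and closing anchors are therefore confined to the slope-window margin
  beyond the outermost directed-motion frames.

Half-excursions smaller than `amp_min` (default $60^\circ$, deliberately low
so reduced-amplitude rotations in older adults still count) are merged into
their neighbours, smallest first. Surviving half-excursions alternate in
sign and are paired in temporal order into rotation events; a trailing
unpaired half-excursion is an incomplete rotation and scores nothing.

On the ideal one-rotation trajectory rendered over 30 frames the pipeline
reports exactly one event. Its measured excursion is $\approx 358^\circ$
rather than $360^\circ$: a 30-frame video spans frames $t = 0, \dots, 29/30$
s, so the last sample sits one frame before signal closure. This one-frame
sampling shortfall is bounded by $2 \times 90\,(1 - \cos(2\pi/30)) \approx
3.9^\circ$ and is asserted, not hidden, in the tests.

## The seven indicators

With per-rotation durations $t_1, \dots, t_n$ (s) and excursions
$a_1, \dots, a_n$ (deg), a trial yields: the rotation count $n$; total
rotation time $\sum t_i$; total time change $\sum_{i \ge 2} (t_i - t_{i-1})$
(telescopes to $t_n - t_1$; negative = speeding up); the signed tally
$\sum_{i \ge 2} \operatorname{sign}(t_i - t_{i-1})$; total rotation angle
$\sum a_i$; total angle change $\sum_{i \ge 2} (a_i - a_{i-1})$
($= a_n - a_1$; negative = shrinking amplitude); and the signed tally of
angle changes. The change tallies are *signed* (+1/-1 per consecutive
increase/decrease, ties contribute 0): population means of these indicators
sit near zero and can be negative, which an unsigned count could not
produce. The telescoping identities are exact and tested on randomized
event lists against a naive per-definition loop.

## Screening and the cohort table

Eligibility screening uses Purdue Pegboard norms by age band and gender
(20–29 years: male 12.8 (SD 2.9), female 13.6 (0.9); 60+: male 7.9 (1.7),
female 8.2 (1.8)). A participant's score is the mean of their available
trials; exclusion is a two-sided band, mean $\pm k \cdot$SD with $k = 2$ by
default. The band form and $k$ are design choices (a conventional normality
band; the source norms do not define "range"), exposed in the config.
Older adults aged 65–80 are screened against the 60+ band, the only band
covering them. The demographic summary reports group sizes as percentages
of the total sample and within-group breakdowns as percentages of the
group, the way cohort tables are conventionally printed.

## The marginal model

Each indicator is analyzed with a Gaussian identity-link marginal
regression — the GEE approach to repeated measures — on group (reference:
older), hand (reference: right) and trial dummies (reference: trial 1),
optionally with group-by-hand and group-by-trial interactions, clustered by
participant. The working correlation is exchangeable by default
(independence and AR(1) are available); estimation iterates generalized
least squares with moment re-estimation of the scale and correlation from
standardized residuals. The family/link and working structure are modeling
choices: the indicators are continuous or count-valued with large means, so
Gaussian-identity matches the B/SE scale on which such analyses are
reported.

Standard errors are robust sandwich estimates. By default the package uses
the Mancl–DeRouen bias-corrected sandwich, which inflates each cluster's
residual by $(I - H_i)^{-1}$: at cohort-scale cluster counts (tens of
participants) the uncorrected sandwich is known to be anticonservative —
in our null calibration at 68 clusters the uncorrected group test rejected
at 0.070 instead of 0.05, while the corrected test sits at 0.058, inside
binomial Monte-Carlo error of the nominal level over 1000 replicates. The
uncorrected form remains available (`se_type = "robust"`). Wald $z$ and
normal $p$-values are reported per coefficient.

For balanced complete Gaussian designs the GEE point estimates coincide
*exactly* with ordinary least squares (cluster-constant and shared
within-cluster design columns make GLS reduce to OLS); the test suite uses
this exactness as an independent oracle via `lm()`. A cohort whose metric
is fitted exactly (zero residual variance, possible in tiny demo cohorts
with deterministic generators) makes the working correlation
unidentifiable; the solver then reports independence and the affected
coefficients carry `NA` p-values rather than spurious certainty.

Post-hoc trial comparisons collapse hands by averaging (one value per
participant per trial — matching the degrees of freedom, participants minus
one, that such analyses report), then run paired $t$-tests for trial pairs
(1,2), (1,3), (2,3) with a Bonferroni factor of 3 and Hedges $g$ per pair.
$g$ uses the two-condition pooled-SD form, $(\bar{x}_i - \bar{x}_j) /
s_\text{pooled}$ times the small-sample correction $J = 1 - 3/(4(2n-2)-1)$ —
not the paired-difference SD form, whose values would be several times
larger than the $g \approx 0.2$ magnitudes conventionally reported for this
kind of learning effect. Differences are earlier-minus-later, so
improvement on later trials yields negative $t$ and $g$. The report flags a
*learning plateau* when trial 1 differs from trials 2 and 3 (adjusted)
while trials 2 and 3 do not differ — the pattern that justifies treating
trial 1 as practice.

## What the synthetic generators emulate

`make_trajectory()` renders piecewise raised-cosine half-cycles
($0 \to A \to 0$ per rotation) with per-rotation period and amplitude
drift and optional Gaussian angle noise, through `make_pose()`, and returns
the programmed rotations as ground truth. Raised-cosine reversals have
near-zero slope, deliberately exercising the deadband/maintain logic.
Defaults are the task's nominal figures: amplitude $180^\circ$, period 1 s
(about 30 frames at 30 fps), 10-second trials.

`simulate_cohort()` works at the metric level: cell value = group mean +
trial shift + hand shift + participant random effect + residual, with the
random-effect share of variance $\rho$ inducing exchangeable correlation
across a participant's six cells. Defaults are the reference study's group
means and SDs (e.g. rotation count 25.66 (7.16) young vs 19.56 (7.02)
older; 29 + 39 participants), the reported trial-2/3 learning shifts for
count (+1.77, +2.31), angle (+193.69, +295.09) and time (+0.33, +0.32),
zero hand effects (none was found), and $\rho = 0.5$ — a modeling choice,
as no within-participant correlation is published for this task. Counts
are rounded and floored at zero; total time is clipped to the 10-second
window; the signed tallies are left continuous (their discreteness is
irrelevant to the Gaussian marginal analysis).

What the generators do **not** emulate: real landmark-estimator noise
structure (occlusion bursts, depth jitter correlated across landmarks),
fatigue within a trial, non-Gaussian metric distributions, or any
relationship between the trajectory-level and metric-level simulators'
parameters. Passing tests therefore demonstrate correctness of the
measurement and inference machinery under controlled conditions, not
clinical validity on recorded video.

## Problem sizes and reproducibility

The calibration analyses use 1000 null cohorts for the type-I error check
(binomial MC SE $\approx 0.007$) and 200 replicates for effect recovery;
segmentation is validated against a brute-force extremum-pairing oracle on
200 randomized noise-free profiles. These sizes keep Monte-Carlo error
well below the decision margins while completing in seconds. All
randomness flows from integer seeds; trajectory files serialize
coordinates at 17 significant digits so write/read round trips are exact
and reruns are byte-identical, and `run_all()` writes a manifest with MD5
hashes, the seed and the config.

## Known limitations

* The rotation axis is fixed to the camera vertical rather than estimated
  from the forearm; large postural tilt would bias theta.
* Angles are folded to $[0, 180]$: over-rotation past $180^\circ$ is
  indistinguishable from incomplete return, and the angle convention cannot
  separate pronation from supination direction.
* Very slow rotations whose slope never clears the deadband score no
  events by construction.
* The screening band (mean $\pm 2$ SD, two-sided, mean of available
  pegboard trials) is one reasonable reading of an under-specified rule;
  alternatives (one-sided, best-of-three) are config-level changes.
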