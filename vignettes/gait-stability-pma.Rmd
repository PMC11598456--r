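---
title: "Estimating the margin of gait stability from six-DoF pelvis motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the margin of gait stability from six-DoF pelvis motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstab)
```

## The problem

Falls during walking are a leading cause of injury in older adults, and the
*margin of stability* (MoS) is the standard biomechanical index of how close
a walker is to losing balance. Computing it requires the body centre of mass
(CoM), its velocity, and the foot positions — laboratory motion-capture
quantities. A single pelvis-worn inertial sensor, however, can measure the
six-axis velocity of one body segment. `gaitstab` implements the full chain
needed to study whether those six signals suffice to *estimate* per-step
critical MoS values: MoS computation from markers, step-normalised six-axis
feature construction (a "virtual IMU"), and a supervised principal motion
analysis (PMA) — a PLS1-style regression on multivariate gait waveforms —
with cross-validated selection of the number of components.

## The stability model

The body is treated as an inverted pendulum of length $l$ (the CoM height
above the floor) with natural frequency $\omega = \sqrt{g/l}$. The
*extrapolated centre of mass* advances the horizontal CoM by its velocity
scaled by the pendulum time constant,

$$x_{xcom} = x_{com} + \frac{v_{com}}{\omega},$$

and the MoS is the distance from the XCoM to the boundary of the base of
support, represented by the support-foot toe point (centre of the 2nd/3rd
metatarsals). In a trial-local gait frame (anterior $y$, mediolateral $x$,
vertical up),

$$\mathrm{mos}^{(x)} = \lvert x_{bos}^{(x)} - x_{xcom}^{(x)} \rvert, \qquad
  \mathrm{mos}^{(y)} = x_{bos}^{(y)} - x_{xcom}^{(y)}.$$

The mediolateral MoS is folded to be non-negative (the XCoM stays medial of
the stance foot in intact gait, and the fold keeps the sign convention
stable when the leading foot switches); the anterior MoS is signed and is
typically negative at comfortable speeds. Per step — one heel contact to
the next, half a gait cycle — the *critical* values are the minimum
mediolateral MoS over the step and the anterior MoS at the step-initiating
heel contact.

Assumptions inherited from this model: the CoM is approximated by the
centroid of the two anterior superior iliac spine markers and the sacral
crest; $\omega$ is constant within a trial ($l$ = trial-mean CoM height,
not per-frame, because the pendulum model treats it as a constant); and
support during double stance is resolved by rule — the foot on the side of
the mediolateral CoM velocity for the mediolateral axis, the leading (most
anterior) foot for the anterior axis. The second rule is a design choice:
the anterior base of support visibly jumps forward at heel contact, and
the velocity-direction rule is ambiguous along the anterior axis.

## From markers to features

* **Filtering.** Marker positions are smoothed with a 4th-order
  zero-phase Butterworth low-pass at 6 Hz (`lowpass()`), the conventional
  gait-analysis choice. Because no filtering package is assumed, the
  bilinear-transform design and the forward–backward pass are implemented
  in-package and validated in the tests against coefficient values frozen
  from an independent reference implementation, against the analytic
  magnitude response, and against exact DC pass-through.
* **Differentiation.** Second-order central differences, one-sided at the
  ends (`deriv_central()`).
* **Pelvis pose.** The three pelvis markers define a rigid body
  (`pelvis_pose()`): the lateral axis is kept exactly along RASIS→LASIS,
  the vertical axis orthogonalises the sacrum→ASIS-midpoint direction
  against it, and the anterior axis completes a right-handed triad.
* **Gait frame.** The anterior direction is the horizontal CoM
  displacement between the first two left heel contacts; mediolateral =
  vertical × anterior (`gait_frame()`).
* **Events.** Heel contact is the first frame at which the heel marker is
  low (< 5 mm above its trial minimum), slow (anterior speed < 0.2 m/s)
  and no longer descending (vertical velocity > −0.15 m/s) after an
  airborne phase; toe off is the upward crossing of the toe vertical
  velocity through 0.1 m/s ahead of an airborne phase (`detect_events()`).
  All thresholds are configurable; the defaults were set for 1.0–1.6 m/s
  over-ground walking sampled at 200 Hz and hold heel contacts to within
  one frame on the synthetic walker across a grid of cadences and widths.
  Event files, when supplied, override detection.
* **Six-axis features.** Per step, the pelvis translational velocity (in
  gait axes) and angular velocity (the vee of $\dot R R^\top$, projected
  onto the gait axes as roll/pitch/yaw rates — named by the *gait*
  directions, not body axes, following how the channels are interpreted in
  the source analyses) are linearly resampled onto 51 instants covering
  0–50% of the gait cycle, giving a 306-vector in fixed channel order
  (`vx`,`vy`,`vz`,`wroll`,`wpitch`,`wyaw` × 51). Right-lead steps are
  mirrored onto left-lead ones by negating `vx`, roll and yaw
  (`laterality_flip()`), assuming lateral symmetry. Columns are z-scored;
  in cross-validation the statistics come from the training folds only
  (the variant that standardises once before splitting leaks test
  information and is available as `standardize = "global"` for
  comparison).

## The regression

`pma_fit()` implements the supervised PMA recursion, identical to PLS1:

$$s_n = \frac{X_n X_n^\top y_n}{\lVert X_n^\top y_n \rVert}, \quad
  p_n = \frac{X_n^\top s_n}{s_n^\top s_n}, \quad
  q_n = \frac{y^\top s_n}{s_n^\top s_n},$$

with deflation $X_{n+1} = X_n - s_n p_n^\top$, $y_{n+1} = y_n - q_n s_n$.
The coefficient uses the *undeflated* response, as printed in the source
formulation; under exact score orthogonality this equals the deflated-y
variant, which the tests assert numerically. Two details are the package's
own:

* **Intercept.** Scores of column-centred data have zero mean, so
  $\sum_n q_n s_n$ can only reproduce the centred response. The response
  is centred internally and its training mean is stored and added back at
  prediction. Without this, predictions would be offset by the mean MoS.
* **Test-score rule.** The published rule projects the (undeflated)
  standardized test data straight onto the loadings,
  $s_n^{(test)} = X^{(test)} p_n$. Because PLS loadings are not mutually
  orthogonal, this is *not* the training-score recursion: later components
  pick up large cross-talk from earlier ones, and the rule is inexact even
  on noiseless data of exactly the fitted rank. `predict()` therefore
  offers `projection = "paper"` (the literal rule, the default, for
  fidelity) and `projection = "pls_rotation"` (the standard weight
  rotation $R = W (P^\top W)^{-1}$, which reproduces the recursion exactly
  and is machine-precision exact in the noiseless full-rank limit). The
  acceptance suite asserts exact noiseless recovery under the rotation
  rule and records that the literal rule's residual is small relative to
  the response scale but bounded away from zero.

`pma_cross_validate()` runs repeated k-fold cross-validation (default
5 × 5, matching the protocol the package emulates), reports per-`a` the
Pearson correlation (mean ± SD over repeats) and the pooled RMSE averaged
over repeats, and selects the smallest `a` within 1% relative RMSE of the
minimum — a parsimony tie-break mirroring "the simpler model was chosen".
Folds are drawn over steps by default; `groups` draws them over subjects
for leakage-free evaluation.

## What the synthetic data states, and what a green test means

Two generators provide ground truth:

**The analytic walker** (`make_walker()`) produces marker trajectories for
a smooth, periodic, laterally symmetric walk: constant-speed CoM with
stride-periodic sway (peaking towards the stance side at midstance) and
double-frequency bounce, a rigid pelvis triplet with sinusoidal
roll/pitch/yaw, and feet that alternate stance and cosine-profile swing
with a double-hump toe-height arc (mid-swing clearance dip 0.021 m).
Defaults state typical comfortable-pace values for healthy older adults:
step length 0.63 m, width 0.15 m, cadence 118 steps/min, CoM height
0.97 m, sway amplitude 0.019 m (peak mediolateral CoM velocity
≈ 0.12 m/s), anterior velocity fluctuation 0.1 m/s, double support 7.2% of
the stride per step (85.6% single support over the two-step cycle). With
these values the generator's closed-form evaluation puts the critical
mediolateral MoS near 0.034 m at ~8% of the stride and the anterior MoS at
contact near −0.04 m — in the range reported for this population. The
truth object carries exact event times and an independent evaluation of
the XCoM/MoS equations on the commanded trajectories, so the pipeline's
agreement (to 1e-6 m on identical inputs; to 1e-3 m end-to-end through
filtering, differentiation and event detection) is checked against
arithmetic the pipeline code never touches.

The walker does **not** emulate: marker soft-tissue artefact and gap
structure (optional isotropic noise only), asymmetric or pathological
gait, turning, treadmill walking, foot roll-over (the stance toe is
stationary), or IMU sensor error. A green walker test therefore
establishes algorithmic correctness on clean kinematics, not robustness to
real measurement pathology.

**The latent-factor generator** (`make_latent_dataset()`) states the
statistical world the regression assumes: `X = 1 m^T + S L + E_x`,
`y = S β + e`, with three orthonormal smooth (low-order Fourier) loading
waveforms, β = (0.11, 0.050, 0.030) echoing the reported coefficient
magnitudes, response noise at SNR 1 by default, and feature noise 0.02 per
entry. One default deserves explanation: the factor score SDs are
(1, 2, 4), *not* equal. With isotropic scores the model
`y = Sβ, X = SL + E` is invariant under joint rotation of `(S, L, β)`, so
the "three factors" collapse to one predictive direction plus
y-irrelevant variance — a single component then suffices and no method
could (or should) select a = 3. A spread variance spectrum in which the
*most predictive* motion is *not* the largest — precisely the regime PLS
exists for — makes all three factors separately recoverable and separately
useful. With these defaults, cross-validation selects a = 3 and the
held-out correlation sits near the SNR-1 ceiling of $1/\sqrt 2$, which is
what the acceptance suite asserts over 20 seeds.

A related nuance: the reported-equation property "coefficients decrease,
$q_1 > q_2 > q_3$" is not a theorem about the recursion — $q_n$ is a
regression slope, confounded by the score variance — and raw-q ordering is
unstable even on noiseless synthetic data. The construction-guaranteed,
and tested, statement is the ordering of the component *contributions*
$\lvert q_n\rvert \cdot \mathrm{sd}(s_n)$.

## Numerical choices

* g = 9.80665 m/s², configurable.
* Argmin ties in the per-step MoS minimum break to the earliest frame.
* The heel-contact frame for the anterior critical MoS is the first frame
  at or after the contact time (the base of support has switched by then;
  using the nearest frame can land just *before* contact and mis-assign
  the trailing foot, an error of a full step length).
* Marker gaps ≤ 10 frames are linearly interpolated; longer gaps error.
* Zero-variance feature columns error when fitting standardisation
  statistics (they indicate degenerate input); inside cross-validation a
  unit-SD guard is used instead so a degenerate fold fails softly.
* Rank exhaustion ($\lVert X_n^\top y_n\rVert = 0$) raises an error
  naming the achievable number of components; cross-validation truncates
  its component range accordingly with a warning.
* TRC files are read/written in their native units (header-declared,
  converted to metres); CSV trials carry a YAML sidecar for rate and
  units.

## Known limitations

* The pipeline assumes over-ground, roughly straight, symmetric walking
  with at least two left heel contacts per trial.
* Event detection is kinematic and threshold-based; force-plate or
  learned detectors are out of scope, and the defaults were not tuned for
  pathological gait.
* The minimum-foot-clearance operationalisation (lowest interior local
  minimum of toe height over the swing frames where |toe z − heel z| <
  5 mm) is one of several in circulation; sole geometry is not modelled.
* No uncertainty quantification on predictions; only CV dispersion is
  reported.
* The reference numbers of the emulated study (r ≈ 0.72 / RMSE 0.88 cm
  mediolateral, r ≈ 0.87 / 0.73 cm anterior on 600 steps of 60 adults)
  require its proprietary-access motion database and are deliberately not
  reproduced here; nothing in this package's tests claims them.
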