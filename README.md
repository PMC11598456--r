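# gaitstab

Dynamic gait stability from optical motion capture, and its estimation
from six-axis pelvis motion.

## What it does, and for whom

The **margin of stability (MoS)** is the standard biomechanical index of
balance during walking: the distance between the boundary of the base of
support (the support-foot toe) and the **extrapolated centre of mass**

    xcom = com + vcom / omega,    omega = sqrt(g / l),

where `l` is the CoM height (inverted-pendulum model). Per step, the
critical values are the minimum mediolateral MoS,
`mos_ml = |bos_x − xcom_x|`, and the anterior MoS at heel contact,
`mos_ap = bos_y − xcom_y`. Computing these requires laboratory motion
capture — but a single pelvis-worn IMU measures six velocity signals of
one segment. `gaitstab` is for movement scientists who want to study
whether those six signals can *predict* the critical MoS values. It
provides:

* **Marker pipeline** — TRC/CSV readers, 6 Hz zero-phase Butterworth
  smoothing, three-marker pelvis CoM and rigid-body pose, trial-local gait
  frame, kinematic heel-contact/toe-off detection (or sidecar event
  files), per-frame MoS and per-step critical values.
* **Virtual IMU features** — per step, six-axis pelvic velocities
  (translational + roll/pitch/yaw rates on the gait axes) resampled to 51
  instants over 0–50% of the gait cycle, laterality-flipped for right-lead
  steps and z-scored: a 306-feature vector per step.
* **Supervised principal motion analysis (PMA)** — a PLS1-type regression
  decomposing the feature matrix into orthogonal-score "principal
  motions" whose scores linearly predict the MoS
  (`y ≈ Σ q_n s_n`), with repeated 5-fold cross-validation, RMSE-based
  selection of the number of motions, and score–gait-parameter
  correlation tables.
* **Synthetic ground truth** — an analytic walker (marker trajectories
  with exact event times and closed-form MoS) and a latent-factor feature
  generator, used by the test suite to validate every stage end to end.

## Worked example

Generate a synthetic walker (step length 0.63 m, width 0.15 m, cadence
118 steps/min — typical comfortable-pace values for healthy older
adults), run the marker pipeline, and inspect the per-step critical MoS:

```r
library(gaitstab)
w <- make_walker(walker_spec())
a <- analyse_trial(w$trial)
head(a$critical[, c("step_id","lead_side","mos_ml_min","mos_ap_hc","t_ml_min_pct")], 3)
#>   step_id lead_side mos_ml_min mos_ap_hc t_ml_min_pct
#> 1       1         L     0.0335   -0.0434         14.7
#> 2       2         R     0.0335   -0.0446         14.9
#> 3       3         L     0.0335   -0.0417         15.7
```

The critical mediolateral MoS is 3.35 cm, reached ~15% into the step
(~8% of the two-step cycle, early single support), and the anterior MoS at
contact is −4.3 cm (negative: the XCoM is ahead of the toe, as at normal
speeds) — both in the range reported for older adults. They agree with
the generator's independent closed-form evaluation (`w$truth$critical`)
to ~3e-5 m through the full filter/differentiate/detect pipeline.

Fit and select a PMA regression on the latent-factor benchmark (3 true
motions, response signal-to-noise 1):

```r
d <- make_latent_dataset(latent_spec(seed = 1))
pma_cross_validate(d$X, d$y, a_max = 5, seed = 1)
#> <pma_cv: 5-fold x 5 repeats, chosen a = 3>
#>  a    r_mean        r_sd rmse_mean  rmse_cm
#>  1 0.5509324 0.001473646 0.2370152 23.70152
#>  2 0.6701958 0.001981034 0.2088403 20.88403
#>  3 0.7221166 0.001649741 0.1999615 19.99615
#>  4 0.3858191 0.022765320 0.2968024 29.68024
#>  5 0.4688582 0.014427117 0.2565765 25.65765
```

Cross-validation recovers the true number of principal motions (a = 3)
and a held-out correlation of 0.72, near the SNR-1 ceiling of 0.71;
extra components overfit and are rejected. `run_pipeline()` chains
everything (markers → MoS targets → features → CV reports per axis and
channel subset → score–parameter correlations) from a YAML or list
config; `inst/cli/gaitstab.R` exposes `run` and `synth` subcommands.

## Documentation

See the methods vignette (`vignettes/gait-stability-pma.Rmd`) for the
model, its assumptions, all tunable parameters with units and defaults,
what the synthetic generators do and do not emulate, and known
limitations.
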