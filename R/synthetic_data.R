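#' Specification for the analytic walker generator
#'
#' Defines a smooth, periodic, laterally symmetric over-ground walk. The
#' defaults are chosen to match typical values reported for healthy older
#' adults walking at a comfortable speed: step length 0.63 m, step width
#' 0.15 m, cadence 118 steps/min, CoM height 0.97 m, mediolateral CoM
#' sway giving a peak mediolateral velocity of ~0.12 m/s, anterior
#' velocity fluctuation ~0.1 m/s about the 1.24 m/s mean, and a double
#' support occupying 7.2% of the stride per step (85.6% total single
#' support over the two-step cycle).
#'
#' @param step_length Anterior distance per step (m).
#' @param step_width Mediolateral distance between the feet (m).
#' @param cadence Steps per minute.
#' @param com_height Mean CoM height above the floor (m).
#' @param lateral_sway_amp Mediolateral CoM sway amplitude (m).
#' @param vertical_bounce_amp Vertical CoM oscillation amplitude (m).
#' @param anterior_fluct_amp Anterior CoM velocity fluctuation amplitude (m/s).
#' @param pelvis_roll_amp,pelvis_pitch_amp,pelvis_yaw_amp Pelvis angular
#'   oscillation amplitudes (rad).
#' @param heading Walking direction in the horizontal plane (rad from +x).
#' @param n_steps Number of heel contacts to simulate (>= 2).
#' @param rate Sampling rate (Hz).
#' @param ds_frac Double-support duration as a fraction of the stride.
#' @param lead_in Recording margin before the first and after the last
#'   heel contact (s).
#' @param toe_peak Toe lift amplitude during swing (m).
#' @param min_clearance Mid-swing toe clearance dip (m).
#' @param heel_lift_amp Heel-above-toe lift amplitude during swing (m).
#' @param marker_noise_sd Isotropic Gaussian marker noise (m); the ground
#'   truth stays noiseless.
#' @param g Gravitational acceleration (m/s^2).
#' @param seed Integer seed (used only when `marker_noise_sd > 0`).
#' @return List of class `walker_spec`.
#' @export
walker_spec <- function(step_length = 0.63, step_width = 0.15,
                        cadence = 118, com_height = 0.97,
                        lateral_sway_amp = 0.019,
                        vertical_bounce_amp = 0.02,
                        anterior_fluct_amp = 0.1,
                        pelvis_roll_amp = 0.06, pelvis_pitch_amp = 0.035,
                        pelvis_yaw_amp = 0.12,
                        heading = 0, n_steps = 10L, rate = 200,
                        ds_frac = 0.072, lead_in = 0.3,
                        toe_peak = 0.08, min_clearance = 0.021,
                        heel_lift_amp = 0.025,
                        marker_noise_sd = 0, g = 9.80665, seed = 1L) {
  spec <- as.list(environment())
  if (step_length <= 0 || step_width <= 0 || cadence <= 0 ||
      com_height <= 0 || rate <= 0)
    stop("lengths, cadence, CoM height and rate must be positive")
  if (n_steps < 2L) stop("need at least 2 steps")
  if (ds_frac <= 0 || ds_frac >= 0.25) stop("ds_frac must be in (0, 0.25)")
  if (step_width < 0.04)
    stop("foot overlap: step width ", step_width, " m is below 0.04 m")
  if (heel_lift_amp * 2 >= toe_peak)
    stop("heel_lift_amp must be below toe_peak / 2 (heel would dig in)")
  class(spec) <- "walker_spec"
  spec
}

# piecewise toe/heel trajectories for one foot given its placement times
# (heel-contact times) and toe positions; returns toe centre and heel T x 3
.foot_track <- function(times, t_place, y_place, x_ml, spec, t_step) {
  ds <- spec$ds_frac * 2 * t_step
  swing <- t_step - ds
  A <- spec$toe_peak
  B <- A - spec$min_clearance
  toe <- cbind(x_ml, rep(y_place[1], length(times)), 0)
  heel_z <- numeric(length(times))
  for (i in seq_along(t_place)) {
    t_hc <- t_place[i]
    stance_end <- if (i < length(t_place)) t_place[i + 1] - swing else max(times) + 1
    idx <- times >= t_hc & times < stance_end
    toe[idx, 2] <- y_place[i]
    if (i < length(t_place)) {
      sw <- times >= stance_end & times < t_place[i + 1]
      u <- (times[sw] - stance_end) / swing
      toe[sw, 2] <- y_place[i] +
        (y_place[i + 1] - y_place[i]) * (1 - cos(pi * u)) / 2
      tz <- A * sin(pi * u) - B * sin(pi * u)^2
      toe[sw, 3] <- tz
      heel_z[sw] <- tz + spec$heel_lift_amp * sin(2 * pi * u)
    }
  }
  before <- times < t_place[1]
  toe[before, 2] <- y_place[1] - if (length(y_place) > 1)
    (y_place[2] - y_place[1]) else 2 * spec$step_length
  # positions before the first in-window placement: previous stance, then the
  # swing arriving at placement 1
  if (any(before)) {
    swing_start <- t_place[1] - swing
    y_prev <- toe[which(before)[1], 2]
    sw <- before & times >= swing_start
    u <- (times[sw] - swing_start) / swing
    toe[sw, 2] <- y_prev + (y_place[1] - y_prev) * (1 - cos(pi * u)) / 2
    tz <- A * sin(pi * u) - B * sin(pi * u)^2
    toe[sw, 3] <- tz
    heel_z[sw] <- tz + spec$heel_lift_amp * sin(2 * pi * u)
  }
  heel <- toe
  heel[, 2] <- heel[, 2] - 0.18          # heel marker 0.18 m behind the toe
  heel[, 3] <- heel_z
  list(toe = toe, heel = heel)
}

#' Generate an analytic walker trial with ground truth
#'
#' Produces smooth periodic marker trajectories (pelvis triplet, heels,
#' 2nd/3rd-metatarsal toe markers) for the walk described by a
#' [walker_spec()], together with a `truth` list carrying the exact event
#' times, the analytic CoM position and velocity, the gait frame, and an
#' independent evaluation of the XCoM/MoS equations on the commanded
#' trajectories (per-frame series and per-step critical values).
#'
#' The walk: heel contacts alternate sides every `60/cadence` s starting
#' with the left foot; the CoM advances at constant mean speed with a
#' stride-periodic mediolateral sway (peaking towards the stance side at
#' midstance) and a double-frequency vertical bounce (lowest at double
#' support); the pelvis triplet rides rigidly on the CoM with sinusoidal
#' roll/pitch/yaw. MoS values follow: the mediolateral minimum falls in
#' early single support (near 8% of the stride with the default sway
#' phasing) and grows with step width; the anterior MoS at heel contact is
#' `step_length/2 - v/omega`, decreasing in walking speed.
#'
#' @param spec A [walker_spec()].
#' @return List with `trial` (a [marker_trial()]) and `truth`.
#' @export
make_walker <- function(spec = walker_spec()) {
  stopifnot(inherits(spec, "walker_spec"))
  t_step <- 60 / spec$cadence
  t_stride <- 2 * t_step
  vbar <- spec$step_length / t_step
  t0 <- spec$lead_in
  hc_times <- t0 + (seq_len(spec$n_steps) - 1L) * t_step
  hc_sides <- rep(c("L", "R"), length.out = spec$n_steps)
  t_end <- hc_times[spec$n_steps] + spec$lead_in
  times <- seq(0, t_end, by = 1 / spec$rate)
  T <- length(times)
  th <- 2 * pi * (times - t0) / t_stride
  # CoM in gait coordinates (x = mediolateral towards the left, y = anterior)
  sway <- spec$lateral_sway_amp
  afl <- spec$anterior_fluct_amp
  x_com <- sway * sin(th)
  y_com <- vbar * (times - t0) - afl * (t_stride / (4 * pi)) * sin(2 * th)
  z_com <- spec$com_height - spec$vertical_bounce_amp * cos(2 * th)
  vx <- sway * (2 * pi / t_stride) * cos(th)
  vy <- vbar - afl * cos(2 * th)
  vz <- 2 * spec$vertical_bounce_amp * (2 * pi / t_stride) * sin(2 * th)
  # foot placements, including virtual pre-trial ones
  lead_off <- spec$step_length / 2
  place_idx <- seq(-2L, spec$n_steps - 1L)
  place_t <- t0 + place_idx * t_step
  place_y <- vbar * (place_t - t0) + lead_off
  place_side <- ifelse(place_idx %% 2L == 0L, "L", "R")
  ml_of <- c(L = spec$step_width / 2, R = -spec$step_width / 2)
  tracks <- lapply(c(L = "L", R = "R"), function(s) {
    sel <- place_side == s
    .foot_track(times, place_t[sel], place_y[sel], ml_of[[s]], spec, t_step)
  })
  # world frame: anterior = (cos h, sin h, 0), ml = (-sin h, cos h, 0)
  h <- spec$heading
  ant <- c(cos(h), sin(h), 0)
  ml <- c(-sin(h), cos(h), 0)
  up <- c(0, 0, 1)
  to_world <- function(g) cbind(g[, 1] * ml[1] + g[, 2] * ant[1],
                                g[, 1] * ml[2] + g[, 2] * ant[2],
                                g[, 3])
  com_w <- to_world(cbind(x_com, y_com, z_com))
  vcom_w <- to_world(cbind(vx, vy, vz))
  # pelvis rigid body: local axes (anterior, left, up); markers chosen so
  # the triplet centroid sits exactly on the CoM
  roll <- spec$pelvis_roll_amp * sin(th)
  pitch <- spec$pelvis_pitch_amp * sin(2 * th)
  yaw <- spec$pelvis_yaw_amp * cos(th)
  af <- 0.06; hw <- 0.12
  local <- rbind(LASIS = c(af, hw, 0), RASIS = c(af, -hw, 0),
                 SACR = c(-2 * af, 0, 0))
  markers <- list(LASIS = matrix(0, T, 3), RASIS = matrix(0, T, 3),
                  SACR = matrix(0, T, 3))
  rot <- array(0, dim = c(3, 3, T))
  for (i in seq_len(T)) {
    R <- .rot_z(h + yaw[i]) %*% .rot_y(pitch[i]) %*% .rot_x(roll[i])
    rot[, , i] <- R
    pts <- com_w[i, ] + R %*% t(local)
    markers$LASIS[i, ] <- pts[, 1]
    markers$RASIS[i, ] <- pts[, 2]
    markers$SACR[i, ] <- pts[, 3]
  }
  toe_w <- lapply(tracks, function(tr) to_world(tr$toe))
  heel_w <- lapply(tracks, function(tr) to_world(tr$heel))
  toe_sep <- 0.015
  markers$LHEE <- heel_w$L; markers$RHEE <- heel_w$R
  for (s in c("L", "R")) {
    off <- outer(rep(1, T), toe_sep * ml)
    markers[[paste0(s, "TOE2")]] <- toe_w[[s]] + off
    markers[[paste0(s, "TOE3")]] <- toe_w[[s]] - off
  }
  if (spec$marker_noise_sd > 0) {
    set.seed(spec$seed)
    markers <- lapply(markers, function(m)
      m + matrix(stats::rnorm(length(m), sd = spec$marker_noise_sd),
                 nrow(m), 3))
  }
  trial <- marker_trial(markers, rate = spec$rate,
                        trial_id = sprintf("walker_c%03.0f_w%03.0f",
                                           spec$cadence,
                                           1000 * spec$step_width),
                        subject_height = spec$com_height / 0.57,
                        subject_meta = list(synthetic = TRUE))
  # ---- independent MoS evaluation on the commanded trajectories ----
  ds <- spec$ds_frac * t_stride
  # the foot placed at contact k lifts one double-support after the next
  # contact; feet placed last never lift within the trial
  k <- seq_len(length(place_t) - 1L)
  to_t <- place_t[k + 1L] + ds
  to_s <- place_side[k]
  # a foot only lifts if its swing has a destination placement in the trial
  keep <- to_t > 0 & to_t < t_end & (k + 2L) <= length(place_t)
  events <- gait_events(
    heel_contacts = data.frame(time = hc_times, side = hc_sides),
    toe_offs = data.frame(time = to_t[keep], side = to_s[keep]))
  l <- mean(z_com)
  om <- sqrt(spec$g / l)
  xcom_x <- x_com + vx / om
  xcom_y <- y_com + vy / om
  # support foot over [hc_i, hc_{i+1}) is the foot placed at hc_i (the sway
  # moves towards it throughout the double support that starts the step)
  support_of_frame <- findInterval(times, place_t)
  bos_x <- ml_of[place_side[pmax(support_of_frame, 1L)]]
  bos_y <- place_y[pmax(support_of_frame, 1L)]
  mos <- data.frame(time = times,
                    xcom_x = xcom_x, xcom_y = xcom_y,
                    bos_x = bos_x, bos_y = bos_y,
                    mos_ml = abs(bos_x - xcom_x),
                    mos_ap = bos_y - xcom_y)
  crit <- do.call(rbind, lapply(seq_len(spec$n_steps - 1L), function(i) {
    win <- which(times >= hc_times[i] - 1e-9 & times <= hc_times[i + 1] + 1e-9)
    j <- win[which.min(mos$mos_ml[win])]
    # first frame at/after contact: the BoS has switched to the new foot
    i_hc <- win[1]
    data.frame(step_id = i, lead_side = hc_sides[i],
               mos_ml_min = mos$mos_ml[j],
               mos_ap_hc = mos$mos_ap[i_hc],
               mos_ap_hc_exact = lead_off - (vbar - afl) / om,
               t_ml_min_pct = 100 * (times[j] - hc_times[i]) / t_step)
  }))
  truth <- list(spec = spec, events = events, l = l, omega = om,
                frame = structure(list(anterior = ant, mediolateral = ml,
                                       vertical = up), class = "gait_frame"),
                com = com_w, vcom = vcom_w,
                com_gait = cbind(x_com, y_com, z_com),
                toes = list(L = toe_w$L, R = toe_w$R),
                rotation = rot,
                mos = mos, critical = crit,
                hc_times = hc_times, hc_sides = hc_sides,
                mean_speed = vbar, t_step = t_step)
  list(trial = trial, truth = truth)
}

.rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                            c(0, sin(a), cos(a)))
.rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                            c(-sin(a), 0, cos(a)))
.rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))

#' Specification for the latent-factor feature generator
#'
#' Describes step-normalised six-axis feature vectors generated as a shared
#' mean waveform plus a small number of orthonormal smooth "principal
#' motion" waveforms whose sample scores linearly determine the response:
#' `X = 1 m^T + S L + E_x`, `y = S beta + e`. The default coefficient
#' pattern (0.11, 0.050, 0.030) mirrors the magnitude ordering reported
#' for mediolateral MoS regressions; the default response noise makes the
#' signal-to-noise ratio 1 (`noise_sd = ||beta .* score_sd||`). The
#' default score SDs (1, 2, 4) are distinct on purpose: with isotropic
#' scores the factor decomposition is only identified up to rotation (the
#' world collapses to a single predictive direction and one regression
#' component suffices), whereas a spread variance spectrum with the most
#' predictive motion *not* the largest — the regime partial least squares
#' is designed for — makes all three factors separately recoverable and
#' separately useful for prediction.
#'
#' @param n_samples Number of samples (steps).
#' @param n_features Feature dimension (51 samples x 6 channels = 306).
#' @param n_factors Number of latent principal motions.
#' @param factor_score_sd Score standard deviation per factor.
#' @param coeffs Regression coefficients `beta` per factor.
#' @param noise_sd Response noise SD; `NULL` means SNR = 1.
#' @param x_noise_sd Per-feature measurement noise SD on `X`.
#' @param seed Integer seed.
#' @return List of class `latent_spec`.
#' @export
latent_spec <- function(n_samples = 600L, n_features = 306L, n_factors = 3L,
                        factor_score_sd = 2^(seq_len(n_factors) - 1),
                        coeffs = c(0.11, 0.050, 0.030)[seq_len(n_factors)],
                        noise_sd = NULL, x_noise_sd = 0.02, seed = 1L) {
  if (n_factors > n_features)
    stop("cannot have more factors than features")
  if (length(factor_score_sd) != n_factors || length(coeffs) != n_factors)
    stop("factor_score_sd and coeffs must have length n_factors")
  if (is.null(noise_sd))
    noise_sd <- sqrt(sum((coeffs * factor_score_sd)^2))
  if (noise_sd < 0 || x_noise_sd < 0) stop("noise SDs must be non-negative")
  structure(as.list(environment()), class = "latent_spec")
}

# smooth waveform bank: low-order Fourier shapes over the 0-50% grid,
# different harmonics/phases per channel block and factor
.latent_waveforms <- function(n_features, n_factors) {
  stopifnot(n_features %% 6L == 0L)
  npct <- n_features %/% 6L
  pct <- seq(0, 0.5, length.out = npct)
  mk <- function(coefs) {
    w <- numeric(npct)
    for (k in seq_along(coefs$amp))
      w <- w + coefs$amp[k] * cos(2 * pi * coefs$freq[k] * pct +
                                  coefs$phase[k])
    w
  }
  mean_profile <- c(
    mk(list(amp = 0.11, freq = 1, phase = 0)),                 # vx
    1.3 + mk(list(amp = 0.15, freq = 2, phase = 0)),           # vy
    mk(list(amp = 0.15, freq = 2, phase = -pi / 2)),           # vz
    mk(list(amp = 0.10, freq = 1, phase = -pi / 2)),           # roll
    mk(list(amp = 0.15, freq = 2, phase = 0.5)),               # pitch
    mk(list(amp = 0.30, freq = 1, phase = 0)))                 # yaw
  raw <- list(
    c(mk(list(amp = 1, freq = 1, phase = 0)),
      mk(list(amp = 0.3, freq = 2, phase = 1)),
      mk(list(amp = 0.4, freq = 2, phase = -1)),
      mk(list(amp = 0.5, freq = 1, phase = 2)),
      mk(list(amp = 0.2, freq = 3, phase = 0)),
      mk(list(amp = -1, freq = 1, phase = 0))),
    c(mk(list(amp = 0.4, freq = 2, phase = 0.5)),
      mk(list(amp = -1, freq = c(1, 2), phase = c(0, 0.7))),
      mk(list(amp = -0.6, freq = 2, phase = -pi / 2)),
      mk(list(amp = 0.3, freq = 1, phase = 1)),
      mk(list(amp = 0.4, freq = 2, phase = 2)),
      mk(list(amp = -0.7, freq = 1, phase = 0.3))),
    c(mk(list(amp = c(0.6, 0.4), freq = c(1, 3), phase = c(1, 0))),
      mk(list(amp = 0.8, freq = 2, phase = pi / 2)),
      mk(list(amp = 0.5, freq = 4, phase = 0)),
      mk(list(amp = -0.4, freq = 2, phase = 0)),
      mk(list(amp = 0.6, freq = 1, phase = -1)),
      mk(list(amp = 0.5, freq = 3, phase = 1))))
  L <- do.call(rbind, raw[seq_len(n_factors)])
  # Gram-Schmidt: orthonormal rows, still smooth
  for (i in seq_len(nrow(L))) {
    if (i > 1)
      for (j in seq_len(i - 1))
        L[i, ] <- L[i, ] - sum(L[i, ] * L[j, ]) * L[j, ]
    L[i, ] <- L[i, ] / sqrt(sum(L[i, ]^2))
  }
  list(mean_profile = mean_profile, loadings = L)
}

#' Generate a latent-factor feature data set with known truth
#'
#' @param spec A [latent_spec()].
#' @return List with `X` (raw n x p feature matrix, before any
#'   standardisation), `y`, and `truth` (scores, loadings, mean profile,
#'   coefficients and the drawn noise).
#' @export
make_latent_dataset <- function(spec = latent_spec()) {
  stopifnot(inherits(spec, "latent_spec"))
  if (spec$n_factors > 3L)
    stop("the waveform bank defines at most 3 factors")
  wf <- .latent_waveforms(spec$n_features, spec$n_factors)
  set.seed(spec$seed)
  n <- spec$n_samples
  S <- matrix(stats::rnorm(n * spec$n_factors), n) %*%
    diag(spec$factor_score_sd, spec$n_factors)
  Ex <- matrix(stats::rnorm(n * spec$n_features, sd = spec$x_noise_sd), n)
  ey <- stats::rnorm(n, sd = spec$noise_sd)
  X <- outer(rep(1, n), wf$mean_profile) + S %*% wf$loadings + Ex
  colnames(X) <- if (spec$n_features == 306L) feature_index() else
    paste0("f", seq_len(spec$n_features))
  y <- drop(S %*% spec$coeffs) + ey
  list(X = X, y = y,
       truth = list(spec = spec, scores = S, loadings = wf$loadings,
                    mean_profile = wf$mean_profile, coeffs = spec$coeffs,
                    y_noise = ey))
}
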