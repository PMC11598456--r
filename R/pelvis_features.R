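#' Six-axis pelvic velocity series
#'
#' Computes the "virtual IMU" signals: per-frame translational velocity of
#' the pelvis origin and angular velocity of the pelvis rigid body, both
#' expressed on the constant gait-frame axes. Translational channels are
#' (vx, vy, vz) = (mediolateral, anterior, vertical); angular channels are
#' (roll, pitch, yaw) = rotation rates about the (anterior, mediolateral,
#' vertical) axes, obtained as the vee of `Rdot R^T` (world angular
#' velocity) projected onto the gait axes.
#'
#' @param pose A [pelvis_pose()].
#' @param frame A [gait_frame()].
#' @param rate Sampling rate, Hz.
#' @return T x 6 matrix with columns `vx, vy, vz, wroll, wpitch, wyaw`
#'   (m/s and rad/s).
#' @export
six_axis_velocity <- function(pose, frame, rate) {
  T <- nrow(pose$origin)
  if (T < 3L) stop("need at least 3 frames to differentiate the pose")
  v_world <- deriv_central(pose$origin, rate)
  v <- v_world %*% cbind(frame$mediolateral, frame$anterior, frame$vertical)
  # angular velocity: omega_world = vee(Rdot %*% t(R)), Rdot by central
  # differences on the rotation entries
  R <- pose$rotation
  Rdot <- array(0, dim = dim(R))
  Rdot[, , 2:(T - 1)] <- (R[, , 3:T, drop = FALSE] -
                          R[, , 1:(T - 2), drop = FALSE]) * rate / 2
  Rdot[, , 1] <- (R[, , 2] - R[, , 1]) * rate
  Rdot[, , T] <- (R[, , T] - R[, , T - 1]) * rate
  w_world <- matrix(0, T, 3)
  for (i in seq_len(T)) {
    W <- Rdot[, , i] %*% t(R[, , i])
    W <- (W - t(W)) / 2                      # enforce skew symmetry
    w_world[i, ] <- c(W[3, 2], W[1, 3], W[2, 1])
  }
  w <- w_world %*% cbind(frame$anterior, frame$mediolateral, frame$vertical)
  out <- cbind(v, w)
  colnames(out) <- c("vx", "vy", "vz", "wroll", "wpitch", "wyaw")
  out
}

#' Resample a six-axis series onto the 0--50% step grid
#'
#' Linearly interpolates each channel onto 51 equally spaced instants from
#' the step's start to its end inclusive (0, 1, ..., 50% of the gait
#' cycle).
#'
#' @param series T x 6 matrix from [six_axis_velocity()].
#' @param step One row of [steps_from_events()].
#' @param rate Sampling rate, Hz.
#' @return Object of class `six_axis_profile`: a 51 x 6 matrix with the
#'   step's `lead_side`/`cycle_half` attached as attributes.
#' @export
resample_step <- function(series, step, rate) {
  T <- nrow(series)
  times <- (seq_len(T) - 1L) / rate
  grid <- seq(step$t_start, step$t_end, length.out = 51L)
  if (step$t_start < times[1] - 1e-9 || step$t_end > times[T] + 1e-9)
    stop("step [", step$t_start, ", ", step$t_end,
         "] lies outside the series time span")
  out <- apply(series, 2, function(ch)
    stats::approx(times, ch, xout = grid, rule = 2)$y)
  colnames(out) <- colnames(series)
  structure(out, class = "six_axis_profile",
            lead_side = step$lead_side, cycle_half = step$cycle_half)
}

#' Cancel laterality between left- and right-lead steps
#'
#' Steps from the second half of the gait cycle (right-lead under the
#' left-first convention) are mirrored onto the first half by negating the
#' mediolateral velocity `vx`, the roll rate and the yaw rate; `vy`, `vz`
#' and the pitch rate are symmetric and left unchanged. Applying the flip
#' twice returns the original profile.
#'
#' @param profile A `six_axis_profile`.
#' @param step The step the profile came from (row of
#'   [steps_from_events()]); only `cycle_half` is consulted.
#' @return The (possibly sign-flipped) profile.
#' @export
laterality_flip <- function(profile, step) {
  if (identical(step$cycle_half, "second")) {
    profile[, c("vx", "wroll", "wyaw")] <- -profile[, c("vx", "wroll", "wyaw")]
  }
  profile
}

#' Fixed feature-column labels
#'
#' Channel-major ordering: `vx_00 ... vx_50, vy_00 ... wyaw_50`.
#'
#' @return Character vector of length 306.
#' @export
feature_index <- function() {
  as.vector(vapply(c("vx", "vy", "vz", "wroll", "wpitch", "wyaw"),
                   function(ch) sprintf("%s_%02d", ch, 0:50),
                   character(51L)))
}

#' Assemble standardized feature vectors from step profiles
#'
#' Flattens each 51 x 6 profile into a 306-vector in the fixed channel
#' order (vx, vy, vz, roll, pitch, yaw; 51 percentages each) and z-scores
#' every column. When `stats` is omitted the column means/SDs are fitted
#' from the supplied profiles (training); pass the returned `stats` to
#' standardize held-out data with the training statistics.
#'
#' @param profiles List of `six_axis_profile` objects.
#' @param stats Optional list with `mean` and `sd` vectors of length 306.
#' @return Object of class `feature_matrix`: the k x 306 standardized
#'   matrix with attributes `stats` (the column statistics used) and
#'   `feature_index`.
#' @export
assemble_features <- function(profiles, stats = NULL) {
  if (inherits(profiles, "six_axis_profile")) profiles <- list(profiles)
  X <- do.call(rbind, lapply(profiles, function(p) as.vector(unclass(p))))
  colnames(X) <- feature_index()
  if (is.null(stats)) {
    if (nrow(X) < 2L)
      stop("need at least 2 profiles to fit standardisation statistics")
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    zero <- which(sdv < 1e-12)
    if (length(zero))
      stop("zero-variance feature column(s): ",
           paste(utils::head(colnames(X)[zero], 5), collapse = ", "))
    stats <- list(mean = mu, sd = sdv)
  }
  Xs <- sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
  structure(Xs, class = c("feature_matrix", class(Xs)),
            stats = stats, feature_index = colnames(X))
}

#' Export a feature matrix with targets to CSV
#'
#' @param X A `feature_matrix` (or plain matrix with 306 columns).
#' @param targets Data frame with per-row step metadata and critical MoS
#'   targets (e.g. `step_id`, `trial_id`, `mos_ml_min_m`, `mos_ap_hc_m`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, targets, path) {
  stopifnot(nrow(X) == nrow(targets))
  utils::write.csv(cbind(targets, as.data.frame(unclass(X))), path,
                   row.names = FALSE)
  invisible(path)
}
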