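#' Extrapolated centre of mass (XCoM)
#'
#' The XCoM advances the horizontal CoM position by the CoM velocity scaled
#' by the inverted-pendulum natural frequency: `xcom = com + vcom / omega`,
#' `omega = sqrt(g / l)`, where `l` is the pendulum length (CoM height above
#' the floor).
#'
#' @param com_xy N x 2 matrix (or length-2 vector) of horizontal CoM
#'   positions (m).
#' @param vcom_xy Matching CoM velocities (m/s).
#' @param l Pendulum length (m), > 0.
#' @param g Gravitational acceleration (m/s^2), > 0.
#' @return Same shape as `com_xy`.
#' @export
xcom <- function(com_xy, vcom_xy, l, g = 9.80665) {
  if (!is.numeric(l) || l <= 0) stop("pendulum length `l` must be positive")
  if (!is.numeric(g) || g <= 0) stop("`g` must be positive")
  com_xy + vcom_xy / sqrt(g / l)
}

#' Step segmentation from heel contacts
#'
#' A step runs from one heel contact to the next (contralateral) heel
#' contact; it is the half of the gait cycle led by the contacting foot.
#' Under the left-first convention, left-lead steps are the first half
#' (0--50%) of the cycle and right-lead steps the second half (50--100%).
#'
#' @param events A [gait_events()].
#' @return Data frame of class `step_segments` with columns `step_id`,
#'   `t_start`, `t_end`, `lead_side`, `cycle_half`.
#' @export
steps_from_events <- function(events) {
  hc <- events$heel_contacts
  if (nrow(hc) < 2L) stop("need at least two heel contacts to form a step")
  n <- nrow(hc) - 1L
  steps <- data.frame(
    step_id = seq_len(n),
    t_start = hc$time[-nrow(hc)],
    t_end = hc$time[-1],
    lead_side = hc$side[-nrow(hc)],
    stringsAsFactors = FALSE)
  steps$cycle_half <- ifelse(steps$lead_side == "L", "first", "second")
  class(steps) <- c("step_segments", class(steps))
  steps
}

#' Per-frame support-foot schedule
#'
#' Reconstructs which feet are on the ground at each frame from heel-contact
#' and toe-off events: a foot supports from its heel contact until its next
#' toe off. When toe-off events are absent, support is approximated as
#' lasting until the next contralateral heel contact (no double support).
#'
#' @param events A [gait_events()].
#' @param times Frame times (s).
#' @return Logical T x 2 matrix with columns `L`, `R`.
#' @keywords internal
.support_schedule <- function(events, times) {
  on <- matrix(FALSE, length(times), 2, dimnames = list(NULL, c("L", "R")))
  hc <- events$heel_contacts; to <- events$toe_offs
  for (side in c("L", "R")) {
    hcs <- hc$time[hc$side == side]
    tos <- to$time[to$side == side]
    # assume on-ground from trial start until the first toe off
    first_to <- tos[if (length(hcs)) tos < hcs[1] else rep(TRUE, length(tos))]
    start <- times[1] - 1
    if (length(first_to)) {
      on[, side] <- on[, side] | (times >= start & times < first_to[1])
    } else if (!length(hcs) || (length(tos) == 0 && length(hcs) == 0)) {
      on[, side] <- TRUE
    }
    for (h in hcs) {
      nxt <- tos[tos > h]
      end <- if (length(nxt)) nxt[1] else times[length(times)] + 1
      on[, side] <- on[, side] | (times >= h & times < end)
    }
    if (!length(tos) && length(hcs)) {
      # no toe offs: support until next contralateral contact
      other <- hc$time[hc$side != side]
      for (h in hcs) {
        nxt <- other[other > h]
        end <- if (length(nxt)) nxt[1] else times[length(times)] + 1
        on[, side] <- on[, side] | (times >= h & times < end)
      }
    }
  }
  on
}

#' Per-frame margin of stability series
#'
#' Projects the CoM, its velocity and the support-foot toe position into the
#' gait frame and evaluates the mediolateral MoS
#' `mos_ml = |bos_x - xcom_x|` and the anterior MoS
#' `mos_ap = bos_y - xcom_y`, where the base of support (BoS) is the toe
#' point (centre of the 2nd/3rd metatarsals) of the support foot. During
#' single support the stance foot is used for both axes; during double
#' support the mediolateral BoS is the foot on the side of the mediolateral
#' CoM velocity and the anterior BoS is the leading (most anterior) foot.
#'
#' @param com T x 3 CoM positions (m), ground frame.
#' @param events A [gait_events()].
#' @param toes List with `L` and `R` T x 3 toe-centre positions (m).
#' @param frame A [gait_frame()].
#' @param rate Sampling rate (Hz).
#' @param g Gravitational acceleration (m/s^2).
#' @param vcom Optional T x 3 CoM velocities; computed by central
#'   differences of `com` when omitted.
#' @param l Optional pendulum length (m); defaults to the trial-mean
#'   vertical CoM height above the floor (z = 0).
#' @return Data frame of class `mos_series`: `time`, `xcom_x`, `xcom_y`,
#'   `bos_x`, `bos_y`, `mos_ml`, `mos_ap`, `support` (`"L"`, `"R"` or
#'   `"double"`). The pendulum length is attached as attribute `l`.
#' @export
mos_series <- function(com, events, toes, frame, rate, g = 9.80665,
                       vcom = NULL, l = NULL) {
  T <- nrow(com)
  times <- (seq_len(T) - 1L) / rate
  if (is.null(vcom)) vcom <- deriv_central(com, rate)
  if (is.null(l)) l <- mean(com[, 3])
  ax <- cbind(frame$mediolateral, frame$anterior)   # 3 x 2 projection
  com_xy <- com %*% ax
  vcom_xy <- vcom %*% ax
  xc <- xcom(com_xy, vcom_xy, l = l, g = g)
  toe_xy <- list(L = toes$L %*% ax, R = toes$R %*% ax)
  on <- .support_schedule(events, times)
  if (any(!on[, "L"] & !on[, "R"]))
    on[!on[, "L"] & !on[, "R"], ] <- TRUE   # flight phases: fall back to both
  support <- ifelse(on[, "L"] & on[, "R"], "double",
                    ifelse(on[, "L"], "L", "R"))
  # mediolateral BoS: stance foot, or (double support) the foot in the
  # direction of the mediolateral CoM velocity
  ml_side <- support
  dbl <- support == "double"
  if (any(dbl)) {
    vx <- vcom_xy[dbl, 1]
    lead_x <- toe_xy$L[dbl, 2] >= toe_xy$R[dbl, 2]
    ml_side[dbl] <- ifelse(vx > 0, "L", ifelse(vx < 0, "R",
                                               ifelse(lead_x, "L", "R")))
  }
  ap_side <- support
  if (any(dbl))
    ap_side[dbl] <- ifelse(toe_xy$L[dbl, 2] >= toe_xy$R[dbl, 2], "L", "R")
  bos_x <- ifelse(ml_side == "L", toe_xy$L[, 1], toe_xy$R[, 1])
  bos_y <- ifelse(ap_side == "L", toe_xy$L[, 2], toe_xy$R[, 2])
  out <- data.frame(time = times,
                    xcom_x = xc[, 1], xcom_y = xc[, 2],
                    bos_x = bos_x, bos_y = bos_y,
                    mos_ml = abs(bos_x - xc[, 1]),
                    mos_ap = bos_y - xc[, 2],
                    support = support,
                    stringsAsFactors = FALSE)
  attr(out, "l") <- l
  class(out) <- c("mos_series", class(out))
  out
}

#' Per-step critical MoS values
#'
#' For each step, the critical mediolateral MoS is the minimum of `mos_ml`
#' over the step (ties broken to the earliest frame) and the critical
#' anterior MoS is `mos_ap` at the step-initiating heel contact frame.
#'
#' @param series A [mos_series()].
#' @param steps A [steps_from_events()] data frame.
#' @return Data frame with `step_id`, `lead_side`, `mos_ml_min` (m),
#'   `mos_ap_hc` (m), `t_ml_min_pct` (% of step), `t_hc` (s).
#'
#' @details The heel-contact frame is the first frame at or after the
#'   contact time, so the base of support has already switched to the
#'   newly leading foot (the anterior BoS jumps forward at contact).
#' @export
critical_mos <- function(series, steps) {
  rate <- 1 / diff(series$time[1:2])
  T <- nrow(series)
  out <- lapply(seq_len(nrow(steps)), function(i) {
    s <- steps[i, ]
    i0 <- .time_to_frame_ceil(s$t_start, rate, T)
    i1 <- .time_to_frame_floor(s$t_end, rate, T)
    if (series$time[1] > s$t_start + 0.5 / rate || series$time[T] < s$t_end - 0.5 / rate)
      stop("step ", s$step_id, " is not covered by the MoS series")
    win <- i0:i1
    j <- win[which.min(series$mos_ml[win])]
    data.frame(step_id = s$step_id, lead_side = s$lead_side,
               mos_ml_min = series$mos_ml[j],
               mos_ap_hc = series$mos_ap[i0],
               t_ml_min_pct = 100 * (series$time[j] - s$t_start) /
                 (s$t_end - s$t_start),
               t_hc = s$t_start)
  })
  do.call(rbind, out)
}

#' Write per-step critical MoS values to CSV
#'
#' Writes SI columns plus cm copies of the two MoS values for reporting.
#'
#' @param crit Output of [critical_mos()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_critical_mos <- function(crit, path) {
  d <- data.frame(step_id = crit$step_id, lead_side = crit$lead_side,
                  mos_ml_min_m = crit$mos_ml_min,
                  mos_ap_hc_m = crit$mos_ap_hc,
                  t_ml_min_pct = crit$t_ml_min_pct,
                  mos_ml_min_cm = 100 * crit$mos_ml_min,
                  mos_ap_hc_cm = 100 * crit$mos_ap_hc)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
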