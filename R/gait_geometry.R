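#' Approximate the body centre of mass from pelvis markers
#'
#' The CoM is approximated by the per-frame centroid of the two anterior
#' superior iliac spine markers and the sacral crest, a standard single-
#' segment approximation for gait-stability work.
#'
#' @param trial A [marker_trial()] with `LASIS`, `RASIS` and `SACR` (or the
#'   `LPSIS`/`RPSIS` pair from which `SACR` is derived).
#' @return T x 3 matrix of CoM positions (m).
#' @export
compute_com <- function(trial) {
  trial <- require_markers(trial, c("LASIS", "RASIS", "SACR"))
  with(trial$markers, (LASIS + RASIS + SACR) / 3)
}

#' Pelvis rigid-body pose from the three-marker model
#'
#' Builds an anatomical pelvis frame per frame: the lateral axis is kept
#' exactly along RASIS -> LASIS; the vertical axis is the unit vector along
#' (provisional anterior) x (lateral), where the provisional anterior runs
#' from the sacral crest to the ASIS midpoint; the anterior axis completes
#' the right-handed triad. Rotation matrices have columns
#' (anterior, lateral, vertical), so the pose is the identity when the
#' pelvis faces +x with the ASIS line along +y and `SACR` behind.
#'
#' @param trial A [marker_trial()].
#' @return List of class `pelvis_pose` with `origin` (T x 3 centroid of the
#'   marker triplet) and `rotation` (3 x 3 x T array, each orthonormal with
#'   determinant +1).
#' @export
pelvis_pose <- function(trial) {
  trial <- require_markers(trial, c("LASIS", "RASIS", "SACR"))
  L <- trial$markers$LASIS; R <- trial$markers$RASIS; S <- trial$markers$SACR
  origin <- (L + R + S) / 3
  T <- nrow(L)
  lat <- L - R
  prov_ant <- (L + R) / 2 - S
  # degenerate if the marker triangle collapses
  nlat <- sqrt(rowSums(lat^2))
  cr <- .cross_rows(lat, prov_ant)
  area2 <- sqrt(rowSums(cr^2))         # twice the triangle area
  bad <- which(area2 / 2 < 1e-6 | nlat < 1e-9)
  if (length(bad))
    stop("degenerate pelvis marker configuration (collinear/coincident) at frame ",
         bad[1])
  lat <- lat / nlat
  up <- .cross_rows(prov_ant, lat)
  up <- up / sqrt(rowSums(up^2))
  ant <- .cross_rows(lat, up)
  rotation <- array(0, dim = c(3, 3, T))
  rotation[, 1, ] <- t(ant)
  rotation[, 2, ] <- t(lat)
  rotation[, 3, ] <- t(up)
  structure(list(origin = origin, rotation = rotation, rate = trial$rate),
            class = "pelvis_pose")
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Trial-local gait coordinate frame
#'
#' The anterior axis is the horizontal projection of the CoM displacement
#' between the first two left heel contacts; the vertical axis is global up;
#' the mediolateral axis is vertical x anterior (so it points to the
#' walker's left and the triad (anterior, mediolateral, vertical) is
#' right-handed).
#'
#' @param com T x 3 CoM series (m).
#' @param events A [gait_events()] with at least two left heel contacts.
#' @param rate Sampling rate, Hz.
#' @return List of class `gait_frame` with unit vectors `anterior`,
#'   `mediolateral`, `vertical`.
#' @export
gait_frame <- function(com, events, rate) {
  hc <- events$heel_contacts
  lhc <- hc$time[hc$side == "L"]
  if (length(lhc) < 2L)
    stop("need at least two left heel contacts to orient the gait frame")
  i1 <- .time_to_frame(lhc[1], rate, nrow(com))
  i2 <- .time_to_frame(lhc[2], rate, nrow(com))
  d <- com[i2, ] - com[i1, ]
  d[3] <- 0
  if (sqrt(sum(d^2)) < 1e-9)
    stop("no horizontal CoM displacement between left heel contacts")
  anterior <- .unit(d)
  vertical <- c(0, 0, 1)
  mediolateral <- .cross3(vertical, anterior)
  structure(list(anterior = anterior, mediolateral = mediolateral,
                 vertical = vertical), class = "gait_frame")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.time_to_frame <- function(t, rate, T) {
  i <- as.integer(round(t * rate)) + 1L
  min(max(i, 1L), T)
}

.time_to_frame_ceil <- function(t, rate, T) {
  i <- as.integer(ceiling(t * rate - 1e-6)) + 1L
  min(max(i, 1L), T)
}

.time_to_frame_floor <- function(t, rate, T) {
  i <- as.integer(floor(t * rate + 1e-6)) + 1L
  min(max(i, 1L), T)
}

#' Construct a gait-event set
#'
#' @param heel_contacts Data frame with `time` (s) and `side` (`"L"`/`"R"`).
#' @param toe_offs Data frame with `time` and `side`.
#' @return Object of class `gait_events`. Heel contacts that fail to
#'   alternate sides raise a warning (not an error).
#' @export
gait_events <- function(heel_contacts, toe_offs = NULL) {
  mk <- function(d) {
    if (is.null(d) || !nrow(d))
      return(data.frame(time = numeric(0), side = character(0)))
    d <- data.frame(time = as.numeric(d$time), side = as.character(d$side))
    if (!all(d$side %in% c("L", "R"))) stop("event side must be 'L' or 'R'")
    d[order(d$time), , drop = FALSE]
  }
  hc <- mk(heel_contacts); to <- mk(toe_offs)
  if (nrow(hc) >= 2L && any(hc$side[-1] == hc$side[-nrow(hc)]))
    warning("heel contacts do not alternate sides")
  structure(list(heel_contacts = hc, toe_offs = to), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events: %d heel contacts, %d toe offs>\n",
              nrow(x$heel_contacts), nrow(x$toe_offs)))
  invisible(x)
}

#' Read a gait-event sidecar file
#'
#' CSV with columns `time_s,side,event`, `event` in `{HC, TO}`.
#'
#' @param path File path.
#' @return A [gait_events()].
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "side", "event") %in% names(d)))
    stop("event sidecar must have columns time_s,side,event")
  gait_events(
    heel_contacts = data.frame(time = d$time_s[d$event == "HC"],
                               side = d$side[d$event == "HC"]),
    toe_offs = data.frame(time = d$time_s[d$event == "TO"],
                          side = d$side[d$event == "TO"]))
}

#' Write gait events to a sidecar CSV
#' @param events A [gait_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  hc <- events$heel_contacts; to <- events$toe_offs
  d <- rbind(data.frame(time_s = hc$time, side = hc$side, event = "HC"),
             data.frame(time_s = to$time, side = to$side, event = "TO"))
  utils::write.csv(d[order(d$time_s), ], path, row.names = FALSE)
  invisible(path)
}

#' Detect heel-contact and toe-off events from foot markers
#'
#' Kinematic detection intended for over-ground walking recorded without
#' force plates. Heel contact is the first frame at which the heel marker
#' is low (below `contact_height` above its trial minimum), its anterior
#' speed has dropped below `hc_vel_thresh`, and it is no longer descending
#' (vertical velocity above `-descend_thresh`), after having been airborne.
#' Toe off is the first frame at which the toe-centre vertical velocity
#' rises through `to_vel_thresh` before an airborne phase. Detection runs
#' on the signals as provided; supply an `events` sidecar to override
#' detection entirely.
#'
#' @param trial A [marker_trial()] with heel (`LHEE`/`RHEE`) and toe
#'   (`*TOE2`/`*TOE3`) markers.
#' @param frame A [gait_frame()] (for the anterior direction).
#' @param events Optional [gait_events()]; returned verbatim when supplied.
#' @param contact_height Height band above the per-marker minimum regarded
#'   as ground contact (m).
#' @param airborne_height Height above which a marker counts as airborne (m).
#' @param hc_vel_thresh Heel anterior-speed threshold at contact (m/s).
#' @param descend_thresh Largest residual downward heel speed at contact (m/s).
#' @param to_vel_thresh Toe vertical-velocity threshold at toe off (m/s).
#' @return A [gait_events()].
#' @export
detect_events <- function(trial, frame, events = NULL,
                          contact_height = 0.005, airborne_height = 0.015,
                          hc_vel_thresh = 0.2, descend_thresh = 0.15,
                          to_vel_thresh = 0.1) {
  if (!is.null(events)) return(events)
  trial <- require_markers(trial, c("LHEE", "RHEE",
                                    "LTOE2", "LTOE3", "RTOE2", "RTOE3"))
  rate <- trial$rate
  tt <- trial_times(trial)
  hc <- to <- list()
  for (side in c("L", "R")) {
    heel <- trial$markers[[paste0(side, "HEE")]]
    toe <- (trial$markers[[paste0(side, "TOE2")]] +
            trial$markers[[paste0(side, "TOE3")]]) / 2
    hz <- heel[, 3] - min(heel[, 3])
    hv_ant <- deriv_central(drop(heel %*% frame$anterior), rate)
    hv_z <- deriv_central(hz, rate)
    airborne <- hz > airborne_height
    # heel contact: end of each airborne run, refined forward
    runs <- rle(airborne)
    ends <- cumsum(runs$lengths)
    for (k in which(runs$values)) {
      i <- ends[k]                      # last airborne frame of the run
      T <- length(hz)
      j <- i + 1L
      while (j <= T && !(hz[j] <= contact_height &&
                         abs(hv_ant[j]) < hc_vel_thresh &&
                         hv_z[j] > -descend_thresh)) j <- j + 1L
      if (j <= T) hc[[length(hc) + 1L]] <- data.frame(time = tt[j], side = side)
    }
    # toe off: first frame with vertical toe velocity above threshold ahead
    # of each airborne run of the toe centre
    tz <- toe[, 3] - min(toe[, 3])
    tv_z <- deriv_central(tz, rate)
    truns <- rle(tz > airborne_height)
    tstarts <- cumsum(truns$lengths) - truns$lengths + 1L
    for (k in which(truns$values)) {
      if (tstarts[k] == 1L) next      # already airborne at trial start
      j <- tstarts[k]
      while (j > 1L && tv_z[j - 1L] > to_vel_thresh) j <- j - 1L
      to[[length(to) + 1L]] <- data.frame(time = tt[j], side = side)
    }
  }
  if (!length(hc))
    stop("no gait events found (is the trial standing still?)")
  gait_events(do.call(rbind, hc), if (length(to)) do.call(rbind, to) else NULL)
}
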