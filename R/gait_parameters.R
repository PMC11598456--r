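#' Per-step gait parameters
#'
#' Computes the descriptive spatiotemporal parameters commonly correlated
#' with principal-motion scores, one row per step:
#' \describe{
#'   \item{max_ml_vel, max_ant_vel}{maxima of the absolute CoM velocity
#'     along the mediolateral / anterior gait axes within the step (m/s).}
#'   \item{step_width}{mediolateral heel-to-heel distance at the first
#'     double-support frame of the step (m).}
#'   \item{step_length}{anterior distance between the step's two heel
#'     contact positions (m).}
#'   \item{cadence}{steps per minute, 60 / step duration.}
#'   \item{single_support_pct}{percentage of the two-step cycle starting at
#'     the step's heel contact during which exactly one foot is on the
#'     ground (needs toe-off events; `NA` otherwise).}
#'   \item{min_foot_clearance}{lowest interior local minimum of the
#'     swing-foot toe height while the foot is parallel to the ground
#'     (|toe z - heel z| < `parallel_tol`), above the standing baseline
#'     (m); `NA` when no such local minimum exists.}
#' }
#' When `subject_height` is available on the trial, `*_norm` copies of the
#' velocities, width and length divided by height are appended.
#'
#' @param trial A [marker_trial()] with heel and toe markers.
#' @param events A [gait_events()].
#' @param frame A [gait_frame()].
#' @param com T x 3 CoM series (m); typically low-pass filtered.
#' @param parallel_tol Foot-parallel tolerance on |toe z - heel z| (m).
#' @return Data frame of class `gait_parameters`, one row per step.
#' @export
compute_gait_parameters <- function(trial, events, frame, com,
                                    parallel_tol = 0.005) {
  rate <- trial$rate
  tt <- trial_times(trial)
  steps <- steps_from_events(events)
  if (!nrow(steps)) stop("no steps between the supplied heel contacts")
  vcom <- deriv_central(com, rate)
  v_ml <- drop(vcom %*% frame$mediolateral)
  v_ant <- drop(vcom %*% frame$anterior)
  trial <- require_markers(trial, c("LHEE", "RHEE",
                                    "LTOE2", "LTOE3", "RTOE2", "RTOE3"))
  heel <- list(L = trial$markers$LHEE, R = trial$markers$RHEE)
  toe <- list(L = (trial$markers$LTOE2 + trial$markers$LTOE3) / 2,
              R = (trial$markers$RTOE2 + trial$markers$RTOE3) / 2)
  heel_ml <- lapply(heel, function(m) drop(m %*% frame$mediolateral))
  heel_ant <- lapply(heel, function(m) drop(m %*% frame$anterior))
  toe_z0 <- lapply(toe, function(m) m[, 3] - min(m[, 3]))
  heel_z0 <- lapply(heel, function(m) m[, 3] - min(m[, 3]))
  on <- .support_schedule(events, tt)
  have_to <- nrow(events$toe_offs) > 0L
  out <- lapply(seq_len(nrow(steps)), function(i) {
    s <- steps[i, ]
    i0 <- .time_to_frame(s$t_start, rate, length(tt))
    i1 <- .time_to_frame(s$t_end, rate, length(tt))
    win <- i0:i1
    lead <- s$lead_side; trail <- setdiff(c("L", "R"), lead)
    # width: first double-support frame of the step
    dbl <- win[on[win, "L"] & on[win, "R"]]
    width <- if (length(dbl) && have_to)
      abs(heel_ml[[lead]][dbl[1]] - heel_ml[[trail]][dbl[1]])
    else abs(heel_ml[[lead]][i0] - heel_ml[[trail]][i0])
    # step length: anterior distance between the step's two heel-contact
    # positions (contralateral heel at t_end vs lead heel at t_start)
    length_ <- abs(heel_ant[[trail]][i1] - heel_ant[[lead]][i0])
    dur <- s$t_end - s$t_start
    # single support over the two-step cycle from this heel contact
    ssp <- NA_real_
    if (have_to) {
      cyc_end <- s$t_start + 2 * dur
      cyc <- which(tt >= s$t_start & tt < min(cyc_end, tt[length(tt)]))
      if (length(cyc) && tt[length(tt)] >= cyc_end - 1.5 / rate) {
        one <- xor(on[cyc, "L"], on[cyc, "R"])
        ssp <- 100 * mean(one)
      }
    }
    # minimum foot clearance of the swing (trailing) foot during this step
    mfc <- NA_real_
    if (have_to) {
      tos <- events$toe_offs
      to_t <- tos$time[tos$side == trail & tos$time >= s$t_start - 1e-9 &
                       tos$time < s$t_end]
      if (length(to_t)) {
        sw <- which(tt > to_t[1] & tt < s$t_end)
        if (length(sw) > 2L) {
          z <- toe_z0[[trail]][sw]
          par <- abs(toe_z0[[trail]][sw] - heel_z0[[trail]][sw]) < parallel_tol
          interior <- 2:(length(sw) - 1L)
          locmin <- interior[z[interior] < z[interior - 1L] &
                             z[interior] <= z[interior + 1L] & par[interior]]
          if (length(locmin)) mfc <- min(z[locmin])
        }
      }
    }
    data.frame(step_id = s$step_id, lead_side = lead,
               max_ml_vel = max(abs(v_ml[win])),
               max_ant_vel = max(abs(v_ant[win])),
               step_width = width, step_length = length_,
               cadence = 60 / dur, single_support_pct = ssp,
               min_foot_clearance = mfc)
  })
  out <- do.call(rbind, out)
  if (!is.null(trial$subject_height)) {
    h <- trial$subject_height
    out$max_ml_vel_norm <- out$max_ml_vel / h
    out$max_ant_vel_norm <- out$max_ant_vel / h
    out$step_width_norm <- out$step_width / h
    out$step_length_norm <- out$step_length / h
  }
  class(out) <- c("gait_parameters", class(out))
  out
}

#' Correlate principal-motion scores with gait parameters
#'
#' Pearson correlation of every (score, parameter) pair with a two-sided
#' test; entries with p >= `alpha` are masked to `NA` in the returned `r`
#' matrix (the full matrices are kept as `r_all` and `p`). Zero-variance
#' columns are masked with a warning.
#'
#' @param scores k x a matrix of principal-motion scores.
#' @param params Data frame or matrix of per-step parameters (numeric
#'   columns only are used).
#' @param alpha Significance level for masking.
#' @return List of class `score_correlations` with `r` (masked), `r_all`,
#'   `p`, `n`, `alpha`.
#' @export
correlate_scores <- function(scores, params, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("s", seq_len(ncol(scores)))
  pd <- as.data.frame(params)
  pd <- pd[vapply(pd, is.numeric, logical(1))]
  if (nrow(scores) != nrow(pd)) stop("row mismatch between scores and params")
  if (nrow(scores) < 3L) stop("need at least 3 paired observations")
  r <- p <- matrix(NA_real_, ncol(pd), ncol(scores),
                   dimnames = list(names(pd), colnames(scores)))
  for (j in seq_len(ncol(pd))) {
    x <- pd[[j]]
    for (i in seq_len(ncol(scores))) {
      sc <- scores[, i]
      ok <- stats::complete.cases(x, sc)
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok]) < 1e-12 || stats::sd(sc[ok]) < 1e-12) {
        warning("zero-variance column '", names(pd)[j], "' or score ", i,
                "; correlation masked")
        next
      }
      ct <- stats::cor.test(x[ok], sc[ok])
      r[j, i] <- unname(ct$estimate)
      p[j, i] <- ct$p.value
    }
  }
  masked <- r
  masked[!is.finite(p) | p >= alpha] <- NA_real_
  structure(list(r = masked, r_all = r, p = p, n = nrow(scores),
                 alpha = alpha),
            class = "score_correlations")
}

#' @export
print.score_correlations <- function(x, ...) {
  cat(sprintf("<score_correlations: n = %d, masked at p >= %g>\n",
              x$n, x$alpha))
  print(round(x$r, 2))
  invisible(x)
}
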