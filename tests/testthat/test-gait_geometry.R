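make_pelvis_frame_trial <- function(R = diag(3), T = 5, origin = c(0, 0, 1)) {
  # canonical neutral: facing +x, ASIS line along +y, SACR behind
  local <- rbind(LASIS = c(0.06, 0.12, 0), RASIS = c(0.06, -0.12, 0),
                 SACR = c(-0.12, 0, 0))
  markers <- lapply(rownames(local), function(nm) {
    p <- origin + drop(R %*% local[nm, ])
    matrix(rep(p, each = T), T, 3)
  })
  names(markers) <- rownames(local)
  marker_trial(markers, rate = 100)
}

test_that("compute_com is the marker-triplet centroid", {
  tr <- marker_trial(list(LASIS = matrix(c(0, 0, 0), 2, 3, byrow = TRUE),
                          RASIS = matrix(c(2, 0, 0), 2, 3, byrow = TRUE),
                          SACR = matrix(c(1, 3, 0), 2, 3, byrow = TRUE)),
                     rate = 100)
  expect_equal(compute_com(tr), matrix(c(1, 1, 0), 2, 3, byrow = TRUE))
  # coincident points map to themselves
  p <- matrix(c(0.3, -0.2, 0.9), 2, 3, byrow = TRUE)
  tr2 <- marker_trial(list(LASIS = p, RASIS = p, SACR = p), rate = 100)
  expect_equal(compute_com(tr2), p)
  # walker fixture: centroid reproduces the commanded CoM path exactly
  w <- default_walker()
  expect_lt(max(abs(compute_com(w$trial) - w$truth$com)), 1e-12)
})

test_that("pelvis_pose recovers known rigid-body orientations", {
  pose0 <- pelvis_pose(make_pelvis_frame_trial())
  expect_equal(pose0$rotation[, , 1], diag(3), tolerance = 1e-12)
  expect_equal(pose0$origin[1, ], c(0, 0, 1), tolerance = 1e-12)
  # a known rotation is recovered exactly
  R0 <- rot_z(0.7) %*% rbind(c(cos(0.2), 0, sin(0.2)), c(0, 1, 0),
                             c(-sin(0.2), 0, cos(0.2)))
  pose <- pelvis_pose(make_pelvis_frame_trial(R0))
  expect_lt(max(abs(pose$rotation[, , 1] - R0)), 1e-9)
  # orthonormality with determinant +1
  R <- pose$rotation[, , 1]
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
  expect_equal(det(R), 1, tolerance = 1e-9)
})

test_that("degenerate pelvis configurations raise an error", {
  tr <- make_pelvis_frame_trial()
  tr$markers$LASIS <- tr$markers$RASIS
  expect_error(pelvis_pose(tr), "degenerate")
})

test_that("pelvis_pose varies continuously on the walker fixture", {
  w <- default_walker()
  pose <- pelvis_pose(w$trial)
  T <- dim(pose$rotation)[3]
  max_step <- 0
  for (i in seq(2, T, by = 7)) {
    dR <- t(pose$rotation[, , i - 1]) %*% pose$rotation[, , i]
    ang <- acos(pmin(1, pmax(-1, (sum(diag(dR)) - 1) / 2)))
    max_step <- max(max_step, ang)
  }
  expect_lt(max_step * 180 / pi, 10)
})

test_that("gait_frame follows the CoM displacement between left contacts", {
  ev <- gait_events(data.frame(time = c(0, 0.5, 1.0),
                               side = c("L", "R", "L")))
  com <- cbind(seq(0, 1.2, length.out = 101), 0, 1)
  fr <- gait_frame(com, ev, 100)
  expect_equal(fr$anterior, c(1, 0, 0))
  expect_equal(fr$mediolateral, c(0, 1, 0))
  expect_equal(fr$vertical, c(0, 0, 1))
  # diagonal walk normalises; vertical displacement is projected out
  com2 <- cbind(seq(0, 1, length.out = 101), seq(0, 1, length.out = 101),
                1 + sin(seq(0, 3, length.out = 101)))
  fr2 <- gait_frame(com2, ev, 100)
  expect_equal(fr2$anterior, c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  # right-handed orthonormal triad
  M <- rbind(fr2$anterior, fr2$mediolateral, fr2$vertical)
  expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)
  expect_equal(det(M), 1, tolerance = 1e-9)
  expect_error(gait_frame(com, gait_events(
    data.frame(time = 0, side = "L")), 100), "two left heel contacts")
})

test_that("gait_frame recovers the commanded heading exactly on a
           grid-aligned walker", {
  # cadence 120 puts every heel contact exactly on a frame
  w <- make_walker(walker_spec(cadence = 120, heading = pi / 6, n_steps = 6))
  com <- compute_com(w$trial)
  fr <- gait_frame(com, w$truth$events, w$trial$rate)
  expect_lt(max(abs(fr$anterior - c(cos(pi / 6), sin(pi / 6), 0))), 1e-9)
})

test_that("heel contacts are detected within one frame on the walker grid", {
  for (cad in c(105, 130)) for (wd in c(0.11, 0.19)) {
    w <- make_walker(walker_spec(cadence = cad, step_width = wd,
                                 n_steps = 6))
    ev <- detect_events(w$trial, w$truth$frame)
    truth <- w$truth$events$heel_contacts
    expect_equal(nrow(ev$heel_contacts), nrow(truth))
    expect_equal(ev$heel_contacts$side, truth$side)
    expect_lt(max(abs(ev$heel_contacts$time - truth$time)),
              1 / w$trial$rate + 1e-9)
    # toe offs within two frames
    tt <- w$truth$events$toe_offs
    expect_equal(nrow(ev$toe_offs), nrow(tt))
    expect_lt(max(abs(ev$toe_offs$time - tt$time)), 2 / w$trial$rate + 1e-9)
  }
})

test_that("standing still yields the empty-events error", {
  tr <- make_pelvis_frame_trial(T = 300)
  tr$markers$LHEE <- tr$markers$RHEE <- matrix(rep(c(0, 0.1, 0), each = 300),
                                               300, 3)
  tr$markers$LTOE2 <- tr$markers$LTOE3 <- tr$markers$LHEE
  tr$markers$RTOE2 <- tr$markers$RTOE3 <- tr$markers$RHEE
  fr <- structure(list(anterior = c(1, 0, 0), mediolateral = c(0, 1, 0),
                       vertical = c(0, 0, 1)), class = "gait_frame")
  expect_error(detect_events(tr, fr), "no gait events")
})

test_that("a supplied event set overrides detection verbatim", {
  w <- default_walker()
  ev <- gait_events(data.frame(time = c(0.1, 0.6), side = c("L", "R")))
  out <- detect_events(w$trial, w$truth$frame, events = ev)
  expect_identical(out, ev)
})

test_that("event sidecar files round-trip", {
  w <- default_walker()
  path <- file.path(withr::local_tempdir(), "ev.csv")
  write_events(w$truth$events, path)
  back <- read_events(path)
  expect_equal(back$heel_contacts$time, w$truth$events$heel_contacts$time)
  expect_equal(back$toe_offs$side, w$truth$events$toe_offs$side)
})

test_that("detection is invariant to rigid horizontal rotation", {
  w <- make_walker(walker_spec(n_steps = 5))
  ev0 <- detect_events(w$trial, w$truth$frame)
  ang <- 2 * pi / 7
  tr2 <- rotate_trial(w$trial, ang)
  fr2 <- w$truth$frame
  fr2$anterior <- drop(rot_z(ang) %*% fr2$anterior)
  fr2$mediolateral <- drop(rot_z(ang) %*% fr2$mediolateral)
  ev2 <- detect_events(tr2, fr2)
  expect_equal(ev2$heel_contacts$time, ev0$heel_contacts$time)
  expect_equal(ev2$toe_offs$time, ev0$toe_offs$time)
})

test_that("non-alternating heel contacts warn but do not error", {
  expect_warning(gait_events(data.frame(time = c(0, 0.5), side = c("L", "L"))),
                 "alternate")
})
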