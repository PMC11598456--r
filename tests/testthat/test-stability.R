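test_that("xcom closed forms", {
  # stationary limit: zero velocity leaves the CoM unchanged
  expect_equal(xcom(c(0.2, 0.4), c(0, 0), l = 1), c(0.2, 0.4))
  # l = g gives omega = 1, so xcom = com + vcom
  expect_equal(xcom(c(1, 2), c(0.3, -0.1), l = 9.81, g = 9.81),
               c(1.3, 1.9))
  # hand evaluation at omega = sqrt(9.81) = 3.132092
  expect_equal(xcom(c(0, 0), c(0.1, 1.2), l = 1, g = 9.81),
               c(0.031928, 0.383130), tolerance = 1e-5)
  # stiff-pendulum limit: as l -> 0, omega -> infinity and xcom -> com
  expect_lt(max(abs(xcom(c(0, 0), c(5, 5), l = 1e-9) - c(0, 0))), 1e-3)
  expect_error(xcom(c(0, 0), c(0, 0), l = -1), "positive")
  expect_error(xcom(c(0, 0), c(0, 0), l = 1, g = 0), "positive")
})

static_mos_fixture <- function(com_x = 0.065, toe_x = 0.10, toe_y = 0.50,
                               com_y = 0.40, T = 50, rate = 100) {
  com <- matrix(rep(c(com_x, com_y, 1), each = T), T, 3)
  # single stance on the left foot throughout (right lifts at the start)
  ev <- gait_events(data.frame(time = 0, side = "L"),
                    data.frame(time = 0, side = "R"))
  toes <- list(L = matrix(rep(c(toe_x, toe_y, 0), each = T), T, 3),
               R = matrix(rep(c(-toe_x, toe_y - 0.4, 0), each = T), T, 3))
  fr <- structure(list(anterior = c(0, 1, 0), mediolateral = c(1, 0, 0),
                       vertical = c(0, 0, 1)), class = "gait_frame")
  mos_series(com, ev, toes, fr, rate, vcom = matrix(0, T, 3), l = 1,
             g = 9.80665)
}

test_that("static fixtures reproduce the MoS arithmetic", {
  ms <- static_mos_fixture()
  expect_true(all(abs(ms$mos_ml - 0.035) < 1e-12))
  # anterior: toe at 0.50, XCoM anterior at 0.40 (v = 0) -> +0.10;
  # shifting the CoM forward to 0.533 gives the signed -0.033
  ms2 <- static_mos_fixture(com_y = 0.533)
  expect_true(all(abs(ms2$mos_ap - (-0.033)) < 1e-12))
  expect_true(all(ms$support == "L"))
})

test_that("mos invariants: non-negative ml, reflection invariance", {
  w <- default_walker()
  th <- w$truth
  ms <- mos_series(th$com, th$events, th$toes, th$frame, w$trial$rate,
                   vcom = th$vcom, l = th$l)
  expect_true(all(ms$mos_ml >= 0))
  expect_true(all(abs(ms$mos_ml - abs(ms$bos_x - ms$xcom_x)) < 1e-12))
  expect_true(all(abs(ms$mos_ap - (ms$bos_y - ms$xcom_y)) < 1e-12))
  # mirroring the whole world about the mediolateral axis (axis flipped,
  # foot labels and event sides swapped) leaves mos_ml unchanged
  fr_r <- th$frame
  fr_r$mediolateral <- -fr_r$mediolateral
  swap <- function(s) ifelse(s == "L", "R", "L")
  ev_r <- suppressWarnings(gait_events(
    transform(th$events$heel_contacts, side = swap(side)),
    transform(th$events$toe_offs, side = swap(side))))
  toes_r <- list(L = th$toes$R, R = th$toes$L)
  ms_r <- mos_series(th$com, ev_r, toes_r, fr_r, w$trial$rate,
                     vcom = th$vcom, l = th$l)
  expect_equal(ms_r$mos_ml, ms$mos_ml, tolerance = 1e-12)
  expect_equal(ms_r$mos_ap, ms$mos_ap, tolerance = 1e-12)
})

test_that("mos_series matches the generator's independent evaluation", {
  w <- default_walker()
  th <- w$truth
  ms <- mos_series(th$com, th$events, th$toes, th$frame, w$trial$rate,
                   vcom = th$vcom, l = th$l)
  steps <- steps_from_events(th$events)
  inside <- ms$time >= min(steps$t_start) & ms$time <= max(steps$t_end)
  expect_lt(max(abs(ms$mos_ml - th$mos$mos_ml)[inside]), 1e-6)
  expect_lt(max(abs(ms$mos_ap - th$mos$mos_ap)[inside]), 1e-6)
  cr <- critical_mos(ms, steps)
  expect_lt(max(abs(cr$mos_ml_min - th$critical$mos_ml_min)), 1e-6)
  expect_lt(max(abs(cr$mos_ap_hc - th$critical$mos_ap_hc)), 1e-6)
})

test_that("critical_mos argmin and tie-breaking", {
  T <- 101; rate <- 100
  ms <- data.frame(time = (0:100) / rate,
                   xcom_x = 0, xcom_y = 0, bos_x = 0, bos_y = 0,
                   mos_ml = rep(0.04, T), mos_ap = seq(0, 1, length.out = T),
                   support = "L")
  steps <- data.frame(step_id = 1L, t_start = 0, t_end = 1,
                      lead_side = "L", cycle_half = "first")
  cr <- critical_mos(ms, steps)
  # constant series: tie broken to the earliest frame
  expect_equal(cr$mos_ml_min, 0.04)
  expect_equal(cr$t_ml_min_pct, 0)
  # |sin|-shaped series with a minimum of 0.02 at 12%
  ms$mos_ml <- 0.02 + abs(sin(pi * (ms$time - 0.12)))
  cr2 <- critical_mos(ms, steps)
  expect_equal(cr2$mos_ml_min, 0.02, tolerance = 1e-9)
  expect_equal(cr2$t_ml_min_pct, 12, tolerance = 0.5)
  # a step outside the series errors
  expect_error(critical_mos(ms, data.frame(step_id = 1, t_start = 0.5,
                                           t_end = 1.5, lead_side = "L")),
               "not covered")
})

test_that("critical mediolateral MoS grows strictly with step width", {
  ml <- vapply(c(0.10, 0.14, 0.18, 0.22), function(wd) {
    w <- make_walker(walker_spec(step_width = wd, n_steps = 5))
    mean(w$truth$critical$mos_ml_min)
  }, numeric(1))
  expect_true(all(diff(ml) > 0))
})

test_that("anterior MoS at contact decreases with walking speed", {
  ap <- vapply(c(100, 115, 130), function(cad) {
    w <- make_walker(walker_spec(cadence = cad, n_steps = 5))
    mean(w$truth$critical$mos_ap_hc)
  }, numeric(1))
  expect_true(all(diff(ap) < 0))
})

test_that("critical MoS CSV export carries cm copies", {
  w <- default_walker_analysis()
  path <- file.path(withr::local_tempdir(), "crit.csv")
  write_critical_mos(w$critical, path)
  d <- utils::read.csv(path)
  expect_equal(d$mos_ml_min_cm, 100 * d$mos_ml_min_m, tolerance = 1e-9)
})
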