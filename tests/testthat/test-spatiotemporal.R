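test_that("the CoM zone score counts outward zone entries by weight", {
  z <- zone_spec()
  inner <- rep(c(0, 0.05, -0.05), 20)
  expect_identical(com_zone_score(NULL, z, ml_dev = inner), 0)
  # two excursions into zone 1, one direct excursion into zone 2: 1+1+2
  dev <- c(0, 0.2, 0, 0.2, 0, 0.3, 0)
  expect_identical(com_zone_score(NULL, z, ml_dev = dev), 4)
  z10 <- zone_spec(boundaries = c(1.524, 2.54, 3.81))
  expect_identical(com_zone_score(NULL, z10, ml_dev = dev), 0)
})

test_that("zone scores are zero for a straight-line walker under tight zones", {
  sj <- quick_subject("HS", 60)
  sj$sway <- 0.005; sj$wander <- 0.005; sj$catchup_rate <- 0
  tr <- generate_trial(sj, "comfortable", 61)
  trf <- add_virtual_markers(lowpass(tr))
  com <- compute_com(trf)
  tight <- zone_spec(boundaries = c(0.05, 0.10, 0.15))
  expect_identical(com_zone_score(com, tight), 0)
  expect_identical(foot_zone_score(trf, zone_spec()), 0)
})

test_that("the foot zone score integrates time with both feet in the zones", {
  z <- zone_spec()
  n <- 100
  on_line <- rep(0, n)
  expect_identical(foot_zone_score(NULL, z, ml_dev_l = on_line,
                                   ml_dev_r = on_line), 0)
  both_z1 <- c(rep(0, 80), rep(0.2, 20))
  expect_equal(foot_zone_score(NULL, z, ml_dev_l = both_z1,
                               ml_dev_r = both_z1), 0.2, tolerance = 1e-12)
  one_out <- rep(0.3, n)
  expect_identical(foot_zone_score(NULL, z, ml_dev_l = one_out,
                                   ml_dev_r = on_line), 0)
})

test_that("step width is the ML heel separation, invariant to floor-plane rotation", {
  steps <- data.frame(time = seq(0.5, 4, by = 0.5),
                      side = rep(c("left", "right"), 4),
                      x = seq(0.5, 4, by = 0.5) * 1.2,
                      y = rep(c(0.06, -0.06), 4))
  expect_equal(step_width(steps, c(1, 0)), 0.12, tolerance = 1e-12)
  th <- 30 * pi / 180
  xy <- cbind(steps$x, steps$y) %*% t(matrix(c(cos(th), sin(th),
                                               -sin(th), cos(th)), 2, 2))
  rot <- steps; rot$x <- xy[, 1]; rot$y <- xy[, 2]
  expect_equal(step_width(rot, c(cos(th), sin(th))), 0.12, tolerance = 1e-12)
})

test_that("ML step distance flags a single catch-up step and ignores AP changes", {
  steps <- data.frame(time = 1:6, side = rep("left", 6),
                      x = 1:6 * 1.2, y = rep(0.06, 6))
  expect_equal(ml_step_distance(steps, c(1, 0), "left"), 0, tolerance = 1e-12)
  steps$y[4] <- 0.06 + 0.15
  expect_equal(ml_step_distance(steps, c(1, 0), "left"), 0.15,
               tolerance = 1e-12)
  # arbitrary AP spacing leaves the ML measure unchanged
  steps$x <- cumsum(c(1, 0.4, 2.0, 0.9, 1.5, 0.2))
  expect_equal(ml_step_distance(steps, c(1, 0), "left"), 0.15,
               tolerance = 1e-12)
  expect_true(is.na(ml_step_distance(steps[1, ], c(1, 0), "left")))
})

test_that("tandem step counts match the generator and stop at the first off-line placement", {
  for (g in c("BV", "HS")) {
    for (s in 1:4) {
      sj <- quick_subject(g, 70 + s)
      tr <- generate_trial(sj, "tandem", 80 + s)
      res <- compute_trial_parameters(tr, "left")
      expect_identical(unname(res$values["Step_number"]),
                       as.numeric(tr$ground_truth$tandem_n_online))
    }
  }
  # first placement already off the line: zero steps
  n <- 50
  mk <- static_pose_markers(n)
  mk$LHEE[, 2] <- 0.31
  tr0 <- trial_record("T0", "tandem", mk, 100)
  ev0 <- gait_event_table(0.1, "left", "foot_strike")
  expect_identical(tandem_step_count(tr0, ev0), 0L)
  expect_error(tandem_step_count(static_trial(task = "comfortable"), ev0),
               "tandem")
})

test_that("walking speed is CoM path over elapsed strike-to-strike time", {
  n <- 501
  t <- (0:(n - 1)) / 100
  com <- make_com(cbind(1.2 * t, 0, 1))
  ev <- gait_event_table(c(0, 5), c("left", "right"),
                         c("foot_strike", "foot_strike"))
  expect_equal(walking_speed(com, ev), 1.2, tolerance = 1e-6)
  ev1 <- gait_event_table(2.0, "left", "foot_strike")
  expect_true(is.na(walking_speed(com, ev1)))
})

test_that("double support reproduces hand intervals, scales linearly, and matches the dense oracle", {
  ev <- gait_event_table(
    c(0.00, 0.12, 0.55, 0.67, 1.10),
    c("right", "left", "left", "right", "right"),
    c("foot_strike", "foot_off", "foot_strike", "foot_off", "foot_strike"))
  ds <- double_support_time(ev, "right")
  expect_equal(ds$median, 0.24, tolerance = 1e-12)
  ev2 <- gait_event_table(ev$time * 2, ev$side, ev$kind)
  expect_equal(double_support_time(ev2, "right")$median, 0.48,
               tolerance = 1e-12)
  # flight phase (off before contralateral strike): no double support
  evf <- gait_event_table(
    c(0.00, 0.20, 0.35, 0.55, 0.70),
    c("right", "right", "left", "left", "right"),
    c("foot_strike", "foot_off", "foot_strike", "foot_off", "foot_strike"))
  expect_equal(double_support_time(evf, "right")$median, 0,
               tolerance = 1e-12)
  # generated trial: event-table arithmetic equals dense boolean integration
  tr <- generate_trial(quick_subject("HS", 90), "comfortable", 91)
  res <- compute_trial_parameters(tr, "left")
  mine <- double_support_time(res$events, "left")$per_cycle
  dense <- oracle_double_support(res$events, "left")
  expect_equal(mine, dense, tolerance = 5e-4)
})

test_that("task time uses the event-bounded window when events exist", {
  tr <- static_trial(500)
  expect_equal(task_time(tr), 5.0, tolerance = 1e-12)
  ev <- gait_event_table(c(0.4, 4.2), c("left", "left"),
                         c("foot_strike", "foot_off"))
  expect_equal(task_time(tr, ev), 3.8, tolerance = 1e-12)
})

test_that("per-trial aggregation is the median with a cycle count", {
  expect_identical(aggregate_per_trial(3), list(value = 3, n_cycles = 1L))
  expect_identical(aggregate_per_trial(c(1, 2, 10))$value, 2)
  expect_identical(aggregate_per_trial(c(1, 2, 3, 4))$value, 2.5)
  expect_true(is.na(aggregate_per_trial(numeric())$value))
})
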