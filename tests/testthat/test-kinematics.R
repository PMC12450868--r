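make_angles <- function(head_lab, trunk_lab = NULL, head_trunk = NULL,
                        rate = 100) {
  n <- nrow(head_lab)
  z <- matrix(0, n, 3)
  named <- function(m) { colnames(m) <- c("yaw", "pitch", "roll"); m }
  if (is.null(trunk_lab)) trunk_lab <- z
  if (is.null(head_trunk)) head_trunk <- z
  structure(list(head_lab = named(head_lab),
                 trunk_lab = named(trunk_lab),
                 head_trunk = named(head_trunk),
                 rate = rate), class = "segment_angles")
}

test_that("segment orientations recover pure rotations exactly", {
  n <- 10
  mk <- static_pose_markers(n)
  ang0 <- segment_orientations(trial_record("A", "comfortable", mk, 100))
  expect_lt(max(abs(ang0$head_lab)), 1e-6)

  th <- 10 * pi / 180
  R <- rot_z(th)
  ctr <- colMeans((mk$LFHD + mk$RFHD + mk$LBHD + mk$RBHD) / 4)
  mk_yaw <- mk
  for (nm in c("LFHD", "RFHD", "LBHD", "RBHD"))
    mk_yaw[[nm]] <- sweep(sweep(mk[[nm]], 2, ctr) %*% t(R), 2, ctr, `+`)
  ang <- segment_orientations(trial_record("A", "comfortable", mk_yaw, 100))
  expect_equal(unname(ang$head_lab[1, "yaw"]), 10, tolerance = 1e-6)
  expect_lt(max(abs(ang$head_lab[, c("pitch", "roll")])), 1e-6)
})

test_that("a head rigidly attached to an oscillating trunk keeps constant relative angles", {
  n <- 200
  t <- (0:(n - 1)) / 100
  mk <- static_pose_markers(n)
  yaw <- 8 * pi / 180 * sin(2 * pi * 1 * t)
  for (nm in c("LFHD", "RFHD", "LBHD", "RBHD", "C7", "CLAV", "T10", "STRN")) {
    p <- mk[[nm]]
    mk[[nm]] <- cbind(p[, 1] * cos(yaw) - p[, 2] * sin(yaw),
                      p[, 1] * sin(yaw) + p[, 2] * cos(yaw), p[, 3])
  }
  ang <- segment_orientations(trial_record("R", "comfortable", mk, 100))
  expect_gt(stats::sd(ang$head_lab[, "yaw"]), 1)
  expect_lt(stats::sd(ang$head_trunk[, "yaw"]), 1e-6)
})

test_that("the anchoring index hits its boundaries and the sinusoid closed form", {
  n <- 400
  t <- (0:(n - 1)) / 100
  osc <- cbind(5 * sin(2 * pi * t), 0, 0)
  # head locked to the trunk: no relative movement -> -1
  ai_block <- head_anchoring_index(make_angles(osc, head_trunk = osc * 0),
                                   "yaw")
  expect_identical(ai_block, -1)
  # head fixed in space while the trunk oscillates -> +1
  ai_space <- head_anchoring_index(make_angles(osc * 0, head_trunk = osc),
                                   "yaw")
  expect_identical(ai_space, 1)
  # amplitudes 2 and 8 at the same frequency -> (8-2)/(8+2)
  a2 <- cbind(2 * sin(2 * pi * t), 0, 0)
  a8 <- cbind(8 * sin(2 * pi * t), 0, 0)
  ai <- head_anchoring_index(make_angles(a2, head_trunk = a8), "yaw")
  expect_equal(ai, 0.6, tolerance = 1e-9)
  # scaling both amplitudes by a common factor leaves the index unchanged
  ai_scaled <- head_anchoring_index(make_angles(3 * a2, head_trunk = 3 * a8),
                                    "yaw")
  expect_equal(ai_scaled, ai, tolerance = 1e-12)
  # no movement at all -> undefined
  expect_true(is.na(head_anchoring_index(make_angles(osc * 0), "yaw")))
})

test_that("angular-velocity RMS matches the sinusoid closed form and removes cadence", {
  n <- 801
  t <- (0:(n - 1)) / 100
  A <- 12; w <- 2 * pi * 1.2
  ang <- make_angles(cbind(A * sin(w * t), 0, 0))
  expect_identical(angular_velocity_rms(make_angles(cbind(0 * t, 0, 0)),
                                        "head", cycle_duration = 1), 0)
  rms <- angular_velocity_rms(ang, "head", normalization = "none")
  expect_equal(rms, A * w / sqrt(2), tolerance = 1e-2)
  # same per-cycle curve at cadences 90 vs 120 steps/min: identical after
  # per-percent-of-cycle normalisation
  cyc90 <- 2 * 60 / 90; cyc120 <- 2 * 60 / 120
  t90 <- seq(0, 10 * cyc90, by = 0.01); t120 <- seq(0, 10 * cyc120, by = 0.01)
  a90 <- make_angles(cbind(A * sin(2 * pi * t90 / cyc90), 0, 0))
  a120 <- make_angles(cbind(A * sin(2 * pi * t120 / cyc120), 0, 0))
  r90 <- angular_velocity_rms(a90, "head", cycle_duration = cyc90)
  r120 <- angular_velocity_rms(a120, "head", cycle_duration = cyc120)
  expect_equal(r90, r120, tolerance = 1e-3)
})

test_that("GaitSD recovers injected noise and scales with it", {
  base <- sapply(1:9, function(k) 10 * sin(2 * pi * (0:100) / 100 + k))
  identical_cycles <- replicate(20, base, simplify = FALSE)
  expect_identical(gait_sd(identical_cycles), 0)
  set.seed(99)
  noise <- replicate(50, matrix(rnorm(101 * 9, 0, 2), 101, 9),
                     simplify = FALSE)
  noisy <- lapply(noise, function(e) base + e)
  g1 <- gait_sd(noisy)
  expect_equal(g1, 2, tolerance = 0.2)
  doubled <- lapply(noise, function(e) base + 2 * e)
  expect_equal(gait_sd(doubled), 2 * g1, tolerance = 1e-12)
  # invariances: cycle order and constant offsets
  expect_identical(gait_sd(rev(noisy)), g1)
  shifted <- lapply(noisy, function(m) sweep(m, 2, seq_len(9) * 5, `+`))
  expect_equal(gait_sd(shifted), g1, tolerance = 1e-12)
  expect_true(is.na(gait_sd(noisy[1])))
})

test_that("joint-angle cycles deliver nine 101-point curves per gait cycle", {
  tr <- generate_trial(quick_subject("HS", 95), "comfortable", 96)
  res <- compute_trial_parameters(tr, "left")
  trf <- add_virtual_markers(lowpass(tr))
  cyc <- joint_angle_cycles(trf, res$events, "left", c(1, 0))
  expect_gte(length(cyc), 2)
  expect_identical(dim(cyc[[1]]), c(101L, 9L))
  expect_identical(colnames(cyc[[1]])[c(1, 7, 9)],
                   c("pelvis_tilt", "knee_flexion", "foot_progression"))
})
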