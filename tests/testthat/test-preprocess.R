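test_that("gap filling is the identity on complete data and never touches observed samples", {
  tr <- generate_trial(quick_subject("HS", 5), "comfortable", 6)
  expect_identical(fill_gaps(tr)$markers, tr$markers)

  gap <- tr
  gap$markers$RKNE[40:69, ] <- NaN
  filled <- fill_gaps(gap)
  expect_false(anyNA(filled$markers$RKNE))
  obs <- setdiff(seq_len(n_frames(tr)), 40:69)
  expect_identical(filled$markers$RKNE[obs, ], gap$markers$RKNE[obs, ])
  for (nm in setdiff(names(tr$markers), "RKNE"))
    expect_identical(filled$markers[[nm]], gap$markers[[nm]])
})

test_that("a 30-frame gap in a co-moving marker is reconstructed within 5 mm", {
  tr <- generate_trial(quick_subject("HS", 7), "comfortable", 8)
  truth <- tr$markers$RKNE[40:69, ]
  gap <- tr
  gap$markers$RKNE[40:69, ] <- NaN
  filled <- fill_gaps(gap)
  expect_lt(max(abs(filled$markers$RKNE[40:69, ] - truth)), 0.005)
})

test_that("gaps beyond max_gap are reported, not silently filled", {
  tr <- generate_trial(quick_subject("HS", 9), "slow", 10)
  stopifnot(n_frames(tr) > 450)
  gap <- tr
  gap$markers$LTHI[21:420, 1] <- NaN
  out <- fill_gaps(gap, max_gap = 100)
  expect_true(anyNA(out$markers$LTHI))
  unfilled <- attr(out, "unfilled")
  expect_identical(unfilled$marker, "LTHI")
  expect_identical(c(unfilled$start, unfilled$end), c(21L, 420L))
})

test_that("the zero-phase low-pass filter has unit DC gain, kills 15 Hz and keeps 1 Hz", {
  n <- 600
  t <- (0:(n - 1)) / 100
  mk <- static_pose_markers(n)
  mk$LHEE[, 2] <- mk$LHEE[, 2] + 0.010 * sin(2 * pi * 15 * t)
  mk$RHEE[, 2] <- mk$RHEE[, 2] + 0.010 * sin(2 * pi * 1 * t)
  tr <- trial_record("F1", "comfortable", mk, 100)
  out <- lowpass(tr)
  # constant channels pass through exactly
  expect_lt(max(abs(out$markers$C7 - mk$C7)), 1e-9)
  interior <- 100:500
  hf <- out$markers$LHEE[interior, 2] - mean(mk$LHEE[, 2])
  expect_lt(max(abs(hf)), 0.001)
  lf <- out$markers$RHEE[interior, 2] - mean(mk$RHEE[, 2])
  expect_gt(max(abs(lf)), 0.010 * 0.98)
  expect_error(lowpass(tr, cutoff = 60), "Nyquist")
})

test_that("virtual joint centres mirror in a symmetric pose and use the stated offsets", {
  tr <- add_virtual_markers(static_trial(), geometry = list(knee_width = 0.10,
                                                            marker_radius = 0.007))
  lh <- tr$markers$LHJC[1, ]; rh <- tr$markers$RHJC[1, ]
  expect_lt(abs(lh[2] + rh[2]), 1e-3)       # mirrored about the sagittal plane
  expect_lt(max(abs(lh[c(1, 3)] - rh[c(1, 3)])), 1e-3)
  # knee centre sits marker radius + half joint width medial of the marker
  off <- sqrt(sum((tr$markers$LKJC[1, ] - tr$markers$LKNE[1, ])^2))
  expect_equal(off, 0.057, tolerance = 1e-9)
})

test_that("collinear pelvis markers raise a geometry error", {
  mk <- static_pose_markers(5)
  for (nm in c("LASI", "RASI", "LPSI", "RPSI"))
    mk[[nm]] <- matrix(rep(c(0.1 * match(nm, c("LASI", "RASI", "LPSI", "RPSI")),
                             0, 1), each = 5), 5, 3)
  tr <- trial_record("D1", "comfortable", mk, 100)
  expect_error(add_virtual_markers(tr), "collinear")
})

test_that("walking direction is recovered, rotation-equivariant, with a standing fallback", {
  t <- seq(0, 5, by = 0.01)
  path <- cbind(1.2 * t, 0.02 * sin(2 * pi * t))
  d0 <- estimate_walking_direction(path)
  expect_lt(acos(min(sum(d0 * c(1, 0)), 1)) * 180 / pi, 1)
  th <- 30 * pi / 180
  rot <- path %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
  d30 <- estimate_walking_direction(rot)
  expect_lt(abs(atan2(d30[2], d30[1]) * 180 / pi - 30), 1)
  expect_warning(d_stand <- estimate_walking_direction(cbind(rnorm(100, 0, 0.001),
                                                             rnorm(100, 0, 0.001))),
                 "falling back")
  expect_identical(d_stand, c(1, 0))
})

test_that("gait events hit the generator ground truth within 20 ms", {
  errs <- c()
  for (s in 1:3) {
    tr <- generate_trial(quick_subject("HS", 20 + s), "comfortable", 30 + s)
    trf <- add_virtual_markers(lowpass(tr))
    ev <- suppressWarnings(detect_gait_events(trf))
    truth <- tr$ground_truth$events
    for (sd0 in c("left", "right")) for (k in c("foot_strike", "foot_off")) {
      tt <- truth$time[truth$side == sd0 & truth$kind == k]
      dd <- ev$time[ev$side == sd0 & ev$kind == k]
      errs <- c(errs, vapply(tt, function(x) min(abs(dd - x)), numeric(1)))
    }
    expect_gte(nrow(ev), nrow(truth))
  }
  expect_lt(max(errs), 0.020)
  expect_lte(stats::median(errs), 0.010)   # one frame at 100 Hz
})

test_that("a stationary trial yields no gait events, with a warning attribute", {
  tr <- static_trial(300)
  tr <- add_virtual_markers(tr)
  ev <- suppressWarnings(detect_gait_events(tr))
  expect_identical(nrow(ev), 0L)
  expect_true(!is.null(attr(ev, "warning")))
})

test_that("time-reversing a trial mirrors its events, with strike/off roles swapped", {
  # played backwards, a foot lands (reversed strike) at the instant it
  # originally took off, and vice versa
  tr <- generate_trial(quick_subject("HS", 31), "comfortable", 32)
  trf <- add_virtual_markers(lowpass(tr))
  ev <- suppressWarnings(detect_gait_events(trf))
  rev_tr <- trf
  for (nm in names(rev_tr$markers))
    rev_tr$markers[[nm]] <- rev_tr$markers[[nm]][n_frames(trf):1, , drop = FALSE]
  ev_rev <- suppressWarnings(detect_gait_events(rev_tr))
  Tdur <- (n_frames(trf) - 1) / trf$rate
  for (sd0 in c("left", "right")) {
    orig_off <- sort(ev$time[ev$side == sd0 & ev$kind == "foot_off"])
    rev_strike <- sort(Tdur - ev_rev$time[ev_rev$side == sd0 &
                                            ev_rev$kind == "foot_strike"])
    matched <- vapply(orig_off, function(x) min(abs(rev_strike - x)),
                      numeric(1))
    expect_lt(stats::median(matched), 0.02)
  }
})
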