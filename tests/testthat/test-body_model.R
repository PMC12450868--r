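test_that("both anthropometric models conserve mass", {
  expect_equal(sum(body_model_9seg()$mass_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(body_model_13seg()$mass_fraction), 1, tolerance = 1e-12)
})

test_that("CoM of coincident markers is the common point, and translation is exact", {
  n <- 5
  p <- c(0.3, -0.2, 1.1)
  mk <- lapply(static_pose_markers(n), function(m) {
    m[] <- rep(p, each = n); m
  })
  tr <- add_virtual_markers(trial_record("C1", "comfortable",
                                         static_pose_markers(n), 100))
  # coincident-marker trial: virtual markers all collapse to p as well
  co_mk <- lapply(tr$markers, function(m) { m[] <- rep(p, each = n); m })
  tr_co <- tr; tr_co$markers <- co_mk
  com <- compute_com(tr_co)
  expect_lt(max(abs(sweep(com$position, 2, p))), 1e-12)

  base <- add_virtual_markers(static_trial(n))
  com0 <- compute_com(base)
  d <- c(1.5, -0.7, 0.2)
  shifted <- base
  shifted$markers <- lapply(base$markers, function(m) sweep(m, 2, d, `+`))
  com1 <- compute_com(shifted)
  expect_lt(max(abs(com1$position - sweep(com0$position, 2, d, `+`))), 1e-12)
})

test_that("a two-segment toy model yields the hand-computed weighted CoM", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("segment,proximal,distal,aux,mass_fraction,com_ratio,rg_t1,rg_t2,rg_l",
               "up,A,B,C,0.6,0.5,0.3,0.3,0.1",
               "down,B,D,C,0.4,0.5,0.3,0.3,0.1"), csv)
  model <- read_body_model(csv)
  n <- 4
  mk <- list(A = matrix(rep(c(0, 0, 1.0), each = n), n, 3),
             B = matrix(rep(c(0, 0, 1.0), each = n), n, 3),
             C = matrix(rep(c(1, 0, 1.0), each = n), n, 3),
             D = matrix(rep(c(0, 0, 0.0), each = n), n, 3))
  tr <- trial_record("T", "comfortable", mk, 100)
  com <- compute_com(tr, model)
  # segment CoMs at z = 1.0 (A-B) and z = 0.5 (B-D): 0.6*1 + 0.4*0.5 = 0.8
  expect_equal(com$position[1, 3], 0.8, tolerance = 1e-12)
})

test_that("angular momentum vanishes for static and uniformly translating bodies", {
  tr <- add_virtual_markers(static_trial(20))
  com <- compute_com(tr)
  L <- compute_wbam(tr, com = com, normalize = "none")
  expect_lt(max(abs(L)), 1e-9)

  v <- c(1.2, 0.3, 0)
  n <- 20
  mov <- tr
  mov$markers <- lapply(tr$markers, function(m)
    m + outer((0:(n - 1)) / 100, v))
  com_m <- compute_com(mov)
  Lm <- compute_wbam(mov, com = com_m, normalize = "none")
  expect_lt(max(abs(Lm)), 1e-8)
})

test_that("a single spinning segment carries momentum I*omega about its axis", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("segment,proximal,distal,aux,mass_fraction,com_ratio,rg_t1,rg_t2,rg_l",
               "rod,P,D,A,1.0,0.5,0.3,0.3,0.3"), csv)
  model <- read_body_model(csv)
  n <- 200
  t <- (0:(n - 1)) / 100
  omega <- 2                      # rad/s about the (vertical) long axis
  mk <- list(P = cbind(0, 0, rep(1, n)),
             D = cbind(0, 0, rep(0, n)),
             A = cbind(cos(omega * t), sin(omega * t), 1))
  tr <- trial_record("S", "comfortable", mk, 100, meta = list(mass = 70))
  com <- compute_com(tr, model)
  L <- compute_wbam(tr, model, com, body_mass = 70, normalize = "none")
  I3 <- 70 * (0.3 * 1)^2
  mid <- 50:150
  expect_equal(stats::median(L[mid, 3]), I3 * omega, tolerance = 1e-3)
  expect_lt(max(abs(L[mid, 1:2])), 1e-6 * I3 * omega + 1e-9)
})

test_that("rotating the lab frame rotates the angular momentum consistently", {
  tr <- add_virtual_markers(lowpass(
    generate_trial(quick_subject("HS", 40), "comfortable", 41)))
  com <- compute_com(tr)
  L <- compute_wbam(tr, com = com, normalize = "none")
  th <- 40 * pi / 180
  R <- rot_z(th)
  rot <- generate_trial(quick_subject("HS", 40), "comfortable", 41)
  rot$markers <- lapply(rot$markers, function(m) m %*% t(R))
  rot <- add_virtual_markers(lowpass(rot))
  com_r <- compute_com(rot)
  Lr <- compute_wbam(rot, com = com_r, normalize = "none")
  expect_lt(max(abs(Lr - L %*% t(R))) / max(abs(L)), 1e-4)
})

test_that("symmetric gait carries (time-averaged) no coronal angular momentum", {
  sj <- quick_subject("HS", 201)
  sj$catchup_rate <- 0
  tr <- generate_trial(sj, "comfortable", 301)
  trf <- add_virtual_markers(lowpass(tr))
  com <- compute_com(trf)
  L <- compute_wbam(trf, com = com)
  d <- suppressWarnings(estimate_walking_direction(marker(trf, "MIDPSIS")))
  pl <- wbam_planes(L, d)
  expect_lt(abs(mean(pl[, "coronal"])), 0.05 * diff(range(pl[, "coronal"])))
})

test_that("per-plane WBAM ranges follow the walking direction, not the lab axes", {
  tr0 <- generate_trial(quick_subject("HS", 43), "comfortable", 44)
  trf <- add_virtual_markers(lowpass(tr0))
  com <- compute_com(trf)
  L <- compute_wbam(trf, com = com)
  d <- suppressWarnings(estimate_walking_direction(marker(trf, "MIDPSIS")))
  pl <- wbam_planes(L, d)
  th <- 25 * pi / 180
  R <- rot_z(th)
  rot <- tr0
  rot$markers <- lapply(tr0$markers, function(m) m %*% t(R))
  rotf <- add_virtual_markers(lowpass(rot))
  com_r <- compute_com(rotf)
  Lr <- compute_wbam(rotf, com = com_r)
  dr <- suppressWarnings(estimate_walking_direction(marker(rotf, "MIDPSIS")))
  plr <- wbam_planes(Lr, dr)
  for (p in c("sagittal", "coronal", "transverse"))
    expect_equal(wbam_range(plr, p), wbam_range(pl, p), tolerance = 5e-3)
})
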