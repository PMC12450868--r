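#' Group-level impairment profile for the synthetic walker
#'
#' Describes the distribution of gait features in one group. Walking-speed
#' means and SDs default to the comfortable-gait group summaries of the
#' study population (BV 1.09 +/- 0.22, UV 1.05 +/- 0.17, HS 1.29 +/- 0.09
#' m/s); the remaining presets reproduce the qualitative group contrasts
#' (patients: wider steps, larger sway, more rigid head-trunk coupling,
#' lateral catch-up steps, noisier kinematics) and are synthetic choices,
#' not estimates.
#'
#' Subject-level draws couple every feature to a latent severity in [0, 1]
#' so that the Dizziness Handicap Inventory (generated from the same
#' severity) correlates with the gait deterioration.
#'
#' @param speed_mean,speed_sev_slope,speed_resid Comfortable walking speed
#'   (m/s): group mean, severity slope, residual SD.
#' @param width_mean,width_sev_slope,width_resid Step width (m).
#' @param cadence_mean,cadence_sd Cadence (steps/min).
#' @param sway_mean,sway_sev_slope ML CoM sway amplitude (m).
#' @param coupling_mean,coupling_sev_slope Head-trunk coupling in [0, 1]
#'   (1 = head rigidly follows trunk).
#' @param catchup_rate Lateral catch-up steps per minute (at mean severity).
#' @param catchup_mag Catch-up lateral displacement (m).
#' @param noise_mean,noise_sev_slope Kinematic noise SD (degrees).
#' @param wander_mean,wander_sev_slope Lateral path-wander SD (m).
#' @param ec_width_gain,ec_sway_gain Eyes-closed multipliers on width/sway.
#' @param sev_mean,sev_sd Latent severity distribution (truncated to [0,1]).
#' @param dhi_intercept,dhi_slope,dhi_noise DHI = intercept + slope *
#'   severity + N(0, noise), clipped to [0, 100]; `NA` to disable (controls).
#' @return An `impairment_profile` list.
#' @export
impairment_profile <- function(speed_mean = 1.29, speed_sev_slope = -0.2,
                               speed_resid = 0.089,
                               width_mean = 0.095, width_sev_slope = 0.08,
                               width_resid = 0.012,
                               cadence_mean = 112, cadence_sd = 4,
                               sway_mean = 0.018, sway_sev_slope = 0.02,
                               coupling_mean = 0.30,
                               coupling_sev_slope = 0.5,
                               catchup_rate = 0, catchup_mag = 0.12,
                               noise_mean = 1.5, noise_sev_slope = 2,
                               wander_mean = 0.02, wander_sev_slope = 0.08,
                               ec_width_gain = 1.05, ec_sway_gain = 1.2,
                               sev_mean = 0.10, sev_sd = 0.05,
                               dhi_intercept = NA, dhi_slope = NA,
                               dhi_noise = 8) {
  p <- as.list(environment())
  stopifnot(p$speed_mean > 0, p$speed_resid >= 0, p$width_resid >= 0,
            p$coupling_mean >= 0, p$coupling_mean <= 1, p$sev_sd >= 0)
  structure(p, class = "impairment_profile")
}

#' Default group presets (BV, UV, HS)
#'
#' @return Named list of three [impairment_profile()]s.
#' @export
group_presets <- function() {
  list(
    BV = impairment_profile(
      speed_mean = 1.09, speed_sev_slope = -1.2, speed_resid = 0.126,
      width_mean = 0.128, cadence_mean = 107,
      sway_mean = 0.035, coupling_mean = 0.75,
      catchup_rate = 2, noise_mean = 3.5, wander_mean = 0.08,
      ec_width_gain = 1.25, ec_sway_gain = 2.0,
      sev_mean = 0.70, sev_sd = 0.15,
      dhi_intercept = 5, dhi_slope = 55),
    UV = impairment_profile(
      speed_mean = 1.05, speed_sev_slope = -0.8, speed_resid = 0.120,
      width_mean = 0.105, cadence_mean = 108,
      sway_mean = 0.025, coupling_mean = 0.55,
      catchup_rate = 1, noise_mean = 2.5, wander_mean = 0.05,
      ec_width_gain = 1.2, ec_sway_gain = 1.6,
      sev_mean = 0.45, sev_sd = 0.15,
      dhi_intercept = 5, dhi_slope = 55),
    HS = impairment_profile())
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Draw one subject from a group profile
#'
#' Realises the subject's latent severity and the gait-feature values all
#' of that subject's trials will share; generates the DHI score from the
#' same severity.
#'
#' @param profile An [impairment_profile()].
#' @param id Subject identifier.
#' @param group Group label (BV/UV/HS).
#' @param seed Integer seed.
#' @return List of subject-level parameters (class `subject_draw`).
#' @export
draw_subject <- function(profile, id, group, seed) {
  set.seed(seed)
  p <- profile
  sev <- rtrunc_norm(1, p$sev_mean, p$sev_sd, 0, 1)
  ds <- sev - p$sev_mean
  speed <- max(0.4, p$speed_mean + p$speed_sev_slope * ds +
                 stats::rnorm(1, 0, p$speed_resid))
  width <- max(0.05, p$width_mean + p$width_sev_slope * ds +
                 stats::rnorm(1, 0, p$width_resid))
  dhi <- if (is.na(p$dhi_intercept)) NA_integer_ else
    as.integer(pmin(pmax(round(p$dhi_intercept + p$dhi_slope * sev +
                                 stats::rnorm(1, 0, p$dhi_noise)), 0), 100))
  structure(list(
    id = id, group = group, severity = sev,
    height = stats::rnorm(1, 1.70, 0.07), mass = stats::rnorm(1, 74, 9),
    speed = speed, width = width,
    cadence = max(80, stats::rnorm(1, p$cadence_mean, p$cadence_sd)),
    sway = max(0.005, p$sway_mean + p$sway_sev_slope * ds),
    coupling = min(1, max(0, p$coupling_mean + p$coupling_sev_slope * ds +
                            stats::rnorm(1, 0, 0.05))),
    catchup_rate = p$catchup_rate * (0.5 + sev),
    catchup_mag = p$catchup_mag,
    noise_sd = max(0.3, p$noise_mean + p$noise_sev_slope * ds),
    wander = max(0.005, p$wander_mean + p$wander_sev_slope * ds),
    ec_width_gain = p$ec_width_gain, ec_sway_gain = p$ec_sway_gain,
    tandem_hazard = min(0.6, 0.02 + 0.45 * sev^2),
    affected_side = if (group == "UV")
      sample(c("left", "right"), 1) else if (group == "BV") "both" else "none",
    dhi = dhi), class = "subject_draw")
}

# smooth noise curve: Gaussian knots every `knot_dt` seconds, spline-joined
smooth_noise <- function(t, sd, knot_dt = 0.25) {
  if (sd <= 0) return(numeric(length(t)))
  knots <- seq(min(t) - knot_dt, max(t) + knot_dt, by = knot_dt)
  stats::spline(knots, stats::rnorm(length(knots), 0, sd),
                xout = t, method = "natural")$y
}

# step plan in the unrolled (path) frame
plan_steps <- function(speed, cadence, width, n_steps, timing_sd,
                       placement_sd, catchup_prob, catchup_mag,
                       speed_mult = NULL, tandem = FALSE,
                       tandem_hazard = 0, step_len_override = NULL) {
  step_time <- 60 / cadence
  base_len <- step_len_override %||% (speed * step_time)
  mult <- speed_mult %||% rep(1, n_steps)
  side <- rep(c("left", "right"), length.out = n_steps)
  sgn <- ifelse(side == "left", 1, -1)
  dt_k <- rep(step_time, n_steps)   # cadence fixed; speed varies via length
  start_time <- max(0.8, 0.8 * step_time + 0.25)
  t_strike <- start_time + cumsum(c(0, dt_k[-1])) +
    c(0, stats::rnorm(n_steps - 1, 0, timing_sd))
  t_strike <- cummax(t_strike + 1e-6 * seq_len(n_steps))  # keep ordered
  s <- cumsum(c(0, base_len * mult[-1])) +
    c(0, stats::rnorm(n_steps - 1, 0, placement_sd))
  catch <- stats::runif(n_steps) < catchup_prob
  catch[1:2] <- FALSE
  lat <- sgn * width / 2 + stats::rnorm(n_steps, 0, placement_sd)
  offline <- rep(FALSE, n_steps)
  if (tandem) {
    lat <- stats::rnorm(n_steps, 0, 0.008)
    hazard_hit <- stats::runif(n_steps) < tandem_hazard
    hazard_hit[1] <- FALSE
    first_off <- if (any(hazard_hit)) which(hazard_hit)[1] else Inf
    if (is.finite(first_off)) {
      offline[first_off] <- TRUE
      lat[first_off:n_steps] <- lat[first_off:n_steps] +
        sgn[first_off] * 0.30
    }
  } else {
    lat[catch] <- lat[catch] + sgn[catch] * catchup_mag
  }
  data.frame(k = seq_len(n_steps), side = side, t = t_strike, s = s,
             lat = lat, catch = catch, offline = offline)
}

# Hermite swing interpolation for one foot coordinate
swing_hermite <- function(tau, a, b, m0, m1) {
  h01 <- tau^2 * (3 - 2 * tau)
  h10 <- tau * (1 - tau)^2
  h11 <- tau^2 * (tau - 1)
  a + (b - a) * h01 + m0 * h10 + m1 * h11
}

# per-frame foot (heel-origin) path for one side: s, lat, z.
# The foot starts in a standing stance at (start_s, start_lat) and swings
# into its first planned strike.
foot_path <- function(t, plan, side, ds_dur, clearance, v_nominal,
                      start_s, start_lat, swing_dur) {
  own <- plan[plan$side == side, , drop = FALSE]
  other <- plan[plan$side != side, , drop = FALSE]
  n <- length(t)
  s <- rep(start_s, n); lat <- rep(start_lat, n)
  z <- rep(0.03, n)
  # launch swing: standing stance -> first planned placement
  t_off0 <- max(own$t[1] - swing_dur, 0.05)
  sw0 <- t >= t_off0 & t < own$t[1]
  if (any(sw0)) {
    tau <- (t[sw0] - t_off0) / (own$t[1] - t_off0)
    m <- 2.0 * v_nominal * (own$t[1] - t_off0)
    s[sw0] <- swing_hermite(tau, start_s, own$s[1], m, m)
    lat[sw0] <- start_lat +
      (own$lat[1] - start_lat) * tau^2 * (3 - 2 * tau)
    z[sw0] <- 0.03 + clearance * sin(pi * tau)
  }
  aft0 <- t >= own$t[1]
  s[aft0] <- own$s[1]; lat[aft0] <- own$lat[1]
  if (nrow(own) >= 2) {
    for (i in seq_len(nrow(own) - 1)) {
      t_strike <- own$t[i]; t_next <- own$t[i + 1]
      contra <- other$t[other$t > t_strike & other$t < t_next]
      t_off <- if (length(contra)) contra[1] + ds_dur else
        t_strike + 0.6 * (t_next - t_strike)
      t_off <- min(t_off, t_next - 0.05)
      sw <- t >= t_off & t < t_next
      after <- t >= t_strike & t < t_off
      s[after] <- own$s[i]; lat[after] <- own$lat[i]
      if (any(sw)) {
        tau <- (t[sw] - t_off) / (t_next - t_off)
        # end slopes = 2x the body's speed, so after zero-phase smoothing
        # the heel-pelvis maximum (strike) and toe-pelvis minimum (off)
        # stay centred on the true event
        m <- 2.0 * v_nominal * (t_next - t_off)
        s[sw] <- swing_hermite(tau, own$s[i], own$s[i + 1], m, m)
        lat[sw] <- own$lat[i] +
          (own$lat[i + 1] - own$lat[i]) * tau^2 * (3 - 2 * tau)
        z[sw] <- 0.03 + clearance * sin(pi * tau)
      }
      if (i == nrow(own) - 1) {
        fin <- t >= t_next
        s[fin] <- own$s[i + 1]; lat[fin] <- own$lat[i + 1]
      }
    }
  }
  list(s = s, lat = lat, z = z)
}

# vectorised placement of rigid local offsets under ZYX rotation
place_offsets <- function(center, yaw, pitch, roll, offsets) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  out <- list()
  for (nm in names(offsets)) {
    o <- offsets[[nm]]
    # R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll) applied to o
    x1 <- cp * o[1] + sp * sr * o[2] + sp * cr * o[3]
    y1 <- cr * o[2] - sr * o[3]
    z1 <- -sp * o[1] + cp * sr * o[2] + cp * cr * o[3]
    out[[nm]] <- center + cbind(cy * x1 - sy * y1, sy * x1 + cy * y1, z1)
  }
  out
}

# map unrolled path coordinates (s, y) to the lab floor plane.
# For turn-pivot trials: straight out, half-circle of arc length turn_len,
# straight back. Other trials: identity.
path_map <- function(s, y, turn_at = NULL, turn_len = 0.8) {
  if (is.null(turn_at)) return(list(x = s, y = y, theta = rep(0, length(s))))
  R <- turn_len / pi
  theta <- pmin(pmax((s - turn_at) / R, 0), pi)
  x <- ifelse(s < turn_at, s,
              ifelse(s < turn_at + turn_len,
                     turn_at + R * sin(theta),
                     turn_at - (s - turn_at - turn_len)))
  yc <- ifelse(s < turn_at, 0,
               ifelse(s < turn_at + turn_len, R - R * cos(theta), 2 * R))
  h1 <- cos(theta); h2 <- sin(theta)
  list(x = x - y * h2, y = yc + y * h1, theta = theta)
}

#' Generate one synthetic marker-trajectory trial
#'
#' Kinematic walker: the full canonical marker set at 100 Hz, driven by a
#' sinusoidal CoM oscillation, alternating step placements with programmed
#' width/length/cadence plus Gaussian noise, Poisson-timed lateral catch-up
#' steps, lateral path wander, trunk oscillations, and head motion mixed as
#' coupling x trunk + (1 - coupling) x independently stabilised motion.
#' Task modifiers adjust speed, sway, width, head oscillation, tandem
#' placement and the turn-pivot path. A ground-truth sidecar records the
#' true events, placements and programmed values.
#'
#' @param subject A [draw_subject()] result (or an [impairment_profile()],
#'   from which a subject is drawn with the same seed).
#' @param task One of [task_set()].
#' @param seed Integer seed (all randomness in the trial derives from it).
#' @param rate Sampling rate, Hz (default 100).
#' @param distance Walkway length in metres for straight tasks (default 6).
#' @param measurement_noise Marker measurement noise SD in metres (5e-4).
#' @param placement_sd Step-placement noise SD in metres (0.008).
#' @param timing_sd Strike-timing noise SD in seconds (0.012).
#' @return A [trial_record()] with `ground_truth` sidecar.
#' @export
generate_trial <- function(subject, task, seed, rate = 100, distance = 6,
                           measurement_noise = 5e-4, placement_sd = 0.008,
                           timing_sd = 0.012) {
  if (!task %in% task_set()) stop("unknown task: ", task)
  if (inherits(subject, "impairment_profile"))
    subject <- draw_subject(subject, "S1", "HS", seed)
  set.seed(seed + 1L)
  sj <- subject
  H <- sj$height
  # task modifiers
  speed <- sj$speed; cadence <- sj$cadence; width <- sj$width
  sway <- sj$sway; wander <- sj$wander; noise_sd <- sj$noise_sd
  head_add_yaw <- 0; head_add_pitch <- 0
  speed_mult <- NULL; turn_at <- NULL
  clearance <- 0.05
  mod <- switch(task,
    comfortable = , backwards = , steps = NULL,
    slow = { speed <- speed * 0.72; cadence <- cadence * 0.88; NULL },
    fast = { speed <- speed * 1.25; cadence <- cadence * 1.12; NULL },
    dual_animal = , dual_letter = {
      speed <- speed * 0.93; noise_sd <- noise_sd * 1.3
      wander <- wander * 1.3; NULL },
    change_speed = NULL,
    head_turns_horizontal = {
      head_add_yaw <- 35 * (1 - 0.5 * sj$coupling)
      sway <- sway * 1.2; NULL },
    head_turns_vertical = {
      head_add_pitch <- 25 * (1 - 0.5 * sj$coupling)
      sway <- sway * 1.2; speed <- speed * 0.95; NULL },
    turn_pivot = { turn_at <- distance / 2; NULL },
    step_obstacle = { clearance <- 0.10; NULL },
    tandem = NULL,
    eyes_closed = {
      width <- width * sj$ec_width_gain; sway <- sway * sj$ec_sway_gain
      wander <- wander * 1.8; speed <- speed * 0.85; NULL })
  if (task %in% c("backwards", "steps")) { speed <- speed * 0.6 }

  tandem <- task == "tandem"
  if (tandem) {
    n_steps <- 10L
    cadence <- 55
    wander <- min(wander, 0.005)   # line-keeping failure is the hazard's job
    width <- 0                     # feet start on the tandem line
    plan <- plan_steps(speed, cadence, 0, n_steps, min(timing_sd * 1.7, 0.02),
                       min(placement_sd, 0.005), 0, 0,
                       tandem = TRUE, tandem_hazard = sj$tandem_hazard,
                       step_len_override = 0.25)
    speed <- 0.25 / (60 / cadence)
  } else {
    step_time <- 60 / cadence
    step_len <- speed * step_time
    total <- if (!is.null(turn_at)) distance + 0.8 else distance
    n_steps <- max(8L, ceiling(total / step_len) + 2L)
    if (task == "change_speed") {
      thirds <- ceiling(n_steps / 3)
      speed_mult <- rep(c(1, 1.3, 0.65), c(thirds, thirds,
                                           n_steps - 2 * thirds))
      n_steps <- length(speed_mult)
    }
    catchup_prob <- sj$catchup_rate * (60 / cadence) / 60
    plan <- plan_steps(speed, cadence, width, n_steps, timing_sd, placement_sd,
                       catchup_prob, sj$catchup_mag,
                       speed_mult = speed_mult)
  }
  dur <- max(plan$t) + 1.0
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate
  step_time <- 60 / cadence
  f_step <- 1 / step_time; f_stride <- f_step / 2
  ds_dur <- 0.24 * step_time

  # body starts standing over the initial stance (feet side by side half a
  # step behind the first placement), accelerates through mid-stance
  # anchors, and eases to a stop between the final two placements
  step_lens <- c(plan$s[2] - plan$s[1], diff(plan$s))
  start_s <- plan$s[1] - 0.5 * step_lens[1]
  anchor_s <- plan$s - 0.55 * step_lens
  anchor_t <- c(0, plan$t[-1])
  anchor_v <- c(start_s, anchor_s[-1])
  sp_fun <- stats::splinefun(anchor_t, anchor_v, method = "monoH.FC")
  s_p <- numeric(n)
  tN <- plan$t[nrow(plan)]
  inside <- t <= tN
  s_p[inside] <- sp_fun(t[inside])
  Fs <- function(x) x^3 - x^4 / 2            # integral of 3x^2 - 2x^3
  post <- t > tN
  tail_dur <- max(dur - tN, 0.2)
  tau <- pmin((t[post] - tN) / tail_dur, 1)
  L_last <- step_lens[length(step_lens)]
  s_p[post] <- anchor_v[length(anchor_v)] +
    0.7 * L_last * (tau - Fs(tau))

  wander_curve <- smooth_noise(t, wander, knot_dt = 2.5)
  lat_p <- sway * sin(2 * pi * f_stride * t) + wander_curve
  # catch-up steps drag the body laterally for a moment
  for (i in which(plan$catch)) {
    bump <- ifelse(plan$side[i] == "left", 1, -1) * 0.6 * sj$catchup_mag
    lat_p <- lat_p + bump * exp(-((t - plan$t[i]) / 0.25)^2)
  }
  pelvis_z <- 0.57 * H + 0.02 * sin(2 * pi * f_step * t)
  if (task == "steps") {
    ramp <- pmin(pmax((t - dur * 0.2) / (dur * 0.3), 0), 1)
    ramp <- ramp - pmin(pmax((t - dur * 0.6) / (dur * 0.3), 0), 1)
    pelvis_z <- pelvis_z + 0.60 * ramp
  }

  d2r <- pi / 180
  ang_noise <- function(sd) smooth_noise(t, sd) * d2r
  pel_yaw <- 4 * d2r * sin(2 * pi * f_stride * t) + ang_noise(noise_sd * 0.5)
  pel_pitch <- 1.5 * d2r * sin(2 * pi * f_step * t) + ang_noise(noise_sd * 0.3)
  pel_roll <- 2.5 * d2r * sin(2 * pi * f_stride * t + pi / 3) +
    ang_noise(noise_sd * 0.4)
  trunk_yaw <- -5 * d2r * sin(2 * pi * f_stride * t) + ang_noise(noise_sd * 0.6)
  trunk_pitch <- 2 * d2r * sin(2 * pi * f_step * t + pi / 4) +
    ang_noise(noise_sd * 0.4)
  trunk_roll <- 3 * d2r * sin(2 * pi * f_stride * t + pi / 2) +
    ang_noise(noise_sd * 0.5)
  # head: coupled share follows the trunk, the rest is stabilised in space
  ind_yaw <- 0.8 * d2r * sin(2 * pi * 0.7 * f_stride * t) + ang_noise(0.4)
  ind_pitch <- 0.6 * d2r * sin(2 * pi * 0.9 * f_step * t) + ang_noise(0.3)
  ind_roll <- 0.6 * d2r * sin(2 * pi * 0.8 * f_stride * t) + ang_noise(0.3)
  cpl <- sj$coupling
  head_yaw <- cpl * trunk_yaw + (1 - cpl) * ind_yaw +
    head_add_yaw * d2r * sin(2 * pi * 0.4 * t)
  head_pitch <- cpl * trunk_pitch + (1 - cpl) * ind_pitch +
    head_add_pitch * d2r * sin(2 * pi * 0.4 * t)
  head_roll <- cpl * trunk_roll + (1 - cpl) * ind_roll

  pelvis_c <- cbind(s_p, lat_p, pelvis_z)
  mk <- place_offsets(pelvis_c, pel_yaw, pel_pitch, pel_roll,
                      list(LASI = c(0.10, 0.12, 0), RASI = c(0.10, -0.12, 0),
                           LPSI = c(-0.12, 0.05, 0.02),
                           RPSI = c(-0.12, -0.05, 0.02)))
  trunk_sway <- -0.3 * (lat_p - wander_curve)   # mild counter-sway
  trunk_c <- cbind(s_p, lat_p + trunk_sway, pelvis_z)
  arm_swing <- 0.12 * sin(2 * pi * f_stride * t)
  mk <- c(mk, place_offsets(trunk_c, trunk_yaw, trunk_pitch, trunk_roll,
    list(C7 = c(-0.10, 0, 0.295 * H), CLAV = c(0.08, 0, 0.27 * H),
         T10 = c(-0.11, 0, 0.15 * H), STRN = c(0.09, 0, 0.13 * H),
         LSHO = c(0, 0.19, 0.27 * H), RSHO = c(0, -0.19, 0.27 * H))))
  # arms: swing opposite to the ipsilateral leg
  for (S in c("L", "R")) {
    sgn <- if (S == "L") 1 else -1
    sw <- sgn * arm_swing
    sho <- mk[[paste0(S, "SHO")]]
    mk[[paste0(S, "ELB")]] <- sho + cbind(sw, sgn * 0.02,
                                          rep(-0.17 * H, n))
    mk[[paste0(S, "WRI")]] <- sho + cbind(1.8 * sw, sgn * 0.03,
                                          rep(-0.31 * H, n))
  }
  head_c <- trunk_c + cbind(0, 0, rep(0.37 * H, n))
  mk <- c(mk, place_offsets(head_c, head_yaw, head_pitch, head_roll,
    list(LFHD = c(0.09, 0.06, 0.03), RFHD = c(0.09, -0.06, 0.03),
         LBHD = c(-0.08, 0.07, 0.04), RBHD = c(-0.08, -0.07, 0.04))))

  # feet and legs
  plan_lab <- plan
  plan_lab$lat <- plan$lat + stats::approx(t, wander_curve, xout = plan$t,
                                           rule = 2)$y
  v_nom <- speed
  for (side in c("left", "right")) {
    S <- if (side == "left") "L" else "R"
    sgn <- if (side == "left") 1 else -1
    fp <- foot_path(t, plan_lab, side, ds_dur, clearance, v_nom,
                    start_s = start_s,
                    start_lat = sgn * width / 2 + wander_curve[1],
                    swing_dur = 0.76 * step_time)
    heel <- cbind(fp$s, fp$lat, fp$z)
    toe <- cbind(fp$s + 0.13 * H, fp$lat + sgn * 0.01, fp$z * 0.6 + 0.012)
    ank <- cbind(fp$s + 0.02, fp$lat + sgn * 0.045, fp$z + 0.06)
    hip <- pelvis_c + cbind(0, rep(sgn * 0.09, n), rep(-0.04 * H, n))
    knee_fwd <- 0.05 + 1.2 * (fp$z - 0.03) +
      smooth_noise(t, noise_sd * 0.004)
    kne <- (hip + ank) / 2 + cbind(knee_fwd, rep(sgn * 0.055, n), 0)
    thi <- 0.4 * hip + 0.6 * kne + cbind(0, rep(sgn * 0.05, n), 0)
    tib <- 0.5 * kne + 0.5 * ank + cbind(0, rep(sgn * 0.04, n), 0)
    mk[[paste0(S, "HEE")]] <- heel; mk[[paste0(S, "TOE")]] <- toe
    mk[[paste0(S, "ANK")]] <- ank; mk[[paste0(S, "KNE")]] <- kne
    mk[[paste0(S, "THI")]] <- thi; mk[[paste0(S, "TIB")]] <- tib
  }

  # bend everything around the turn-pivot path, if any
  if (!is.null(turn_at)) {
    for (nm in names(mk)) {
      m <- mk[[nm]]
      pm <- path_map(m[, 1], m[, 2], turn_at = turn_at)
      mk[[nm]] <- cbind(pm$x, pm$y, m[, 3])
    }
  }
  if (task == "backwards") {
    for (nm in names(mk)) mk[[nm]][, 1] <- -mk[[nm]][, 1]
  }
  if (measurement_noise > 0) {
    for (nm in names(mk))
      mk[[nm]] <- mk[[nm]] + matrix(stats::rnorm(3 * n, 0,
                                                 measurement_noise), n, 3)
  }
  mk <- lapply(mk[marker_set()], function(m) { dimnames(m) <- NULL; m })

  # ground-truth events: strikes from the plan, offs from the stance rule
  ev_rows <- list()
  for (side in c("left", "right")) {
    own <- plan[plan$side == side, , drop = FALSE]
    other <- plan[plan$side != side, , drop = FALSE]
    for (i in seq_len(nrow(own))) {
      if (i > 1)
        ev_rows[[length(ev_rows) + 1L]] <-
          data.frame(time = own$t[i], side = side, kind = "foot_strike")
      if (i < nrow(own)) {
        contra <- other$t[other$t > own$t[i] & other$t < own$t[i + 1]]
        t_off <- if (length(contra)) min(contra[1] + ds_dur,
                                         own$t[i + 1] - 0.05) else
          own$t[i] + 0.6 * (own$t[i + 1] - own$t[i])
        ev_rows[[length(ev_rows) + 1L]] <-
          data.frame(time = t_off, side = side, kind = "foot_off")
      }
    }
  }
  ev <- do.call(rbind, ev_rows)
  ev <- ev[order(ev$time), ]

  # trim walking trials to the steady-state window (3rd placement to one
  # half-step past the second-to-last), emulating mid-walkway capture;
  # tandem trials keep their standing start, since the step count begins
  # at the first placement
  if (!tandem && nrow(plan) >= 6) {
    t_a <- plan$t[3] - 0.5 * step_time
    t_b <- plan$t[nrow(plan) - 1] + 0.5 * step_time
    ia <- max(1L, round(t_a * rate) + 1L)
    ib <- min(n, round(t_b * rate) + 1L)
    shift <- (ia - 1L) / rate
    mk <- lapply(mk, function(m) m[ia:ib, , drop = FALSE])
    keep <- ev$time >= shift + 0.01 & ev$time <= (ib - 1L) / rate - 0.01
    ev <- ev[keep, , drop = FALSE]
    ev$time <- ev$time - shift
    plan_lab$t <- plan_lab$t - shift
  }
  # the width actually laid down by the step plan (catch-up steps and path
  # wander included) - what a perfect measurement should recover
  plan_step_width <- if (nrow(plan_lab) >= 4) {
    stats::median(abs(diff(plan_lab$lat[3:(nrow(plan_lab) - 1)])))
  } else NA_real_
  truth <- list(
    events = ev,
    placements = plan_lab,
    programmed = list(speed = speed, step_width = width, cadence = cadence,
                      sway = sway, coupling = cpl, noise_sd = noise_sd,
                      wander = wander,
                      plan_step_width = plan_step_width,
                      n_catchup = sum(plan$catch)),
    tandem_n_online = if (tandem) {
      off <- which(abs(plan_lab$lat) > 0.05)
      if (length(off)) off[1] - 1L else nrow(plan_lab)
    } else NA_integer_,
    subject = unclass(sj), seed = seed)
  trial_record(sj$id, task, mk, rate,
               ground_truth = truth,
               meta = list(mass = sj$mass, height = sj$height,
                           group = sj$group))
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_group` subjects from each preset and generates one trial
#' per subject and task. Same seed, same cohort, bit for bit.
#'
#' @param presets Named list of [impairment_profile()]s
#'   (default [group_presets()]).
#' @param n_per_group Subjects per group (default 10).
#' @param tasks Task subset (default the full [task_set()]).
#' @param seed Master integer seed.
#' @param ... Passed to [generate_trial()] (e.g. `distance`).
#' @return List with `trials` (list of trial records) and `cohort`
#'   (data.frame: subject_id, group, affected_side, dhi, severity).
#' @export
generate_cohort <- function(presets = group_presets(), n_per_group = 10,
                            tasks = task_set(), seed = 1, ...) {
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  trials <- list()
  meta_rows <- list()
  idx <- 0L
  for (g in names(presets)) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g, i)
      s_seed <- (seed * 7919 + idx * 104729) %% 2147480000L
      sj <- draw_subject(presets[[g]], sid, g, s_seed)
      meta_rows[[idx]] <- data.frame(
        subject_id = sid, group = g, affected_side = sj$affected_side,
        dhi = sj$dhi, severity = sj$severity, stringsAsFactors = FALSE)
      for (k in seq_along(tasks)) {
        t_seed <- (s_seed + k * 131071) %% 2147480000L
        trials[[length(trials) + 1L]] <-
          generate_trial(sj, tasks[k], t_seed, ...)
      }
    }
  }
  list(trials = trials, cohort = do.call(rbind, meta_rows))
}
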