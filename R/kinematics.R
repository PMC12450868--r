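# Cardan ZYX decomposition (yaw about vertical, pitch about ML, roll about
# AP) of the rotation taking frame A to frame B, both given as lists of
# per-frame orthonormal basis rows (x fwd, y left, z up). Degrees, unwrapped.

frame_from_axes <- function(x, y, z) list(x = x, y = y, z = z)

relative_cardan <- function(A, B) {
  # R = A' B, elementwise per frame; returns yaw, pitch, roll in degrees
  r11 <- rowSums(A$x * B$x); r21 <- rowSums(A$y * B$x)
  r31 <- rowSums(A$z * B$x); r32 <- rowSums(A$z * B$y)
  r33 <- rowSums(A$z * B$z)
  yaw <- atan2(r21, r11)
  pitch <- -asin(pmin(pmax(r31, -1), 1))
  roll <- atan2(r32, r33)
  deg <- 180 / pi
  cbind(yaw = unwrap_angle(yaw) * deg,
        pitch = unwrap_angle(pitch) * deg,
        roll = unwrap_angle(roll) * deg)
}

unwrap_angle <- function(a) {
  d <- diff(a)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  a - 2 * pi * jumps
}

orthonormal_from <- function(primary, secondary) {
  # x = primary, z = secondary orthogonalised, y = z cross x
  x <- unit_rows(primary)
  z <- unit_rows(secondary - x * rowSums(secondary * x))
  y <- cross3(z, x)
  frame_from_axes(x, y, z)
}

heading_frame <- function(direction, n) {
  d <- if (is.matrix(direction)) direction else matrix(direction, n, 2,
                                                       byrow = TRUE)
  x <- cbind(d[, 1], d[, 2], 0)
  z <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  frame_from_axes(x, cross3(z, x), z)
}

head_frame <- function(trial) {
  require_markers(trial, c("LFHD", "RFHD", "LBHD", "RBHD"))
  front <- (marker(trial, "LFHD") + marker(trial, "RFHD")) / 2
  back <- (marker(trial, "LBHD") + marker(trial, "RBHD")) / 2
  left <- marker(trial, "LFHD") - marker(trial, "RFHD")
  fwd <- front - back
  if (stats::median(vec_norm(cross3(fwd, left))) < 1e-12)
    stop("degenerate head marker triad")
  up <- unit_rows(cross3(fwd, left))
  orthonormal_from(fwd, up)
}

trunk_frame <- function(trial) {
  require_markers(trial, c("C7", "T10", "CLAV", "STRN"))
  up_raw <- (marker(trial, "C7") + marker(trial, "CLAV")) / 2 -
    (marker(trial, "T10") + marker(trial, "STRN")) / 2
  fwd_raw <- (marker(trial, "CLAV") + marker(trial, "STRN")) / 2 -
    (marker(trial, "C7") + marker(trial, "T10")) / 2
  if (stats::median(vec_norm(cross3(fwd_raw, up_raw))) < 1e-12)
    stop("degenerate trunk marker set")
  orthonormal_from(fwd_raw, up_raw)
}

#' Head and trunk orientation angles
#'
#' Cardan (yaw-pitch-roll about walking-direction-aligned axes) angles of
#' the head-in-lab, trunk-in-lab, and head-relative-to-trunk orientations,
#' in degrees, unwrapped.
#'
#' @param trial Trial with the four head and four trunk markers.
#' @param direction Heading (unit 2-vector or per-frame matrix); defaults
#'   to the lab X axis.
#' @return A `segment_angles` list of three n-by-3 matrices (`head_lab`,
#'   `trunk_lab`, `head_trunk`, columns yaw/pitch/roll) plus `rate`.
#' @export
segment_orientations <- function(trial, direction = c(1, 0)) {
  n <- n_frames(trial)
  lab <- heading_frame(direction, n)
  hf <- head_frame(trial)
  tf <- trunk_frame(trial)
  structure(list(head_lab = relative_cardan(lab, hf),
                 trunk_lab = relative_cardan(lab, tf),
                 head_trunk = relative_cardan(tf, hf),
                 rate = trial$rate),
            class = "segment_angles")
}

#' Head anchoring index
#'
#' AI = (sd_rel - sd_abs) / (sd_rel + sd_abs), where sd_abs is the standard
#' deviation of the head orientation angle in the global frame and sd_rel
#' that of the head orientation relative to the trunk, per plane. +1 means
#' the head is stabilised in space while the trunk moves; -1 means head and
#' trunk move "in block".
#'
#' @param angles A `segment_angles` object.
#' @param plane `"yaw"`, `"pitch"` or `"roll"`.
#' @param min_duration Minimum data duration in seconds (default 2).
#' @return AI in [-1, 1]; `NA` when there is no movement at all or the
#'   series is shorter than `min_duration`.
#' @export
head_anchoring_index <- function(angles, plane = c("yaw", "pitch", "roll"),
                                 min_duration = 2) {
  plane <- match.arg(plane)
  n <- nrow(angles$head_lab)
  if (n / angles$rate < min_duration) return(NA_real_)
  s_a <- stats::sd(angles$head_lab[, plane])
  s_r <- stats::sd(angles$head_trunk[, plane])
  if (s_a + s_r == 0) return(NA_real_)
  (s_r - s_a) / (s_r + s_a)
}

#' RMS of the normalised segment angular velocity
#'
#' Angular-velocity magnitude of the head or trunk (root of the summed
#' squared Cardan angle rates, deg/s), expressed per percent of gait cycle
#' (multiplied by cycle duration / 100) so that cadence differences cancel;
#' the per-trial value is the RMS over all frames.
#'
#' @param angles A `segment_angles` object.
#' @param segment `"head"` or `"trunk"` (in-lab angles).
#' @param cycle_duration Mean gait-cycle duration in seconds; required for
#'   the default normalisation.
#' @param normalization `"per_percent_cycle"` (default), `"none"`.
#' @return RMS angular velocity (deg per %cycle, or deg/s when
#'   unnormalised); `NA` when no cycle duration is available.
#' @export
angular_velocity_rms <- function(angles, segment = c("head", "trunk"),
                                 cycle_duration = NULL,
                                 normalization = c("per_percent_cycle",
                                                   "none")) {
  segment <- match.arg(segment)
  normalization <- match.arg(normalization)
  a <- if (segment == "head") angles$head_lab else angles$trunk_lab
  dt <- 1 / angles$rate
  rates <- apply(a, 2, finite_diff, dt = dt)
  mag <- sqrt(rowSums(rates^2))
  scale <- switch(normalization,
                  per_percent_cycle = {
                    if (is.null(cycle_duration) || is.na(cycle_duration))
                      return(NA_real_)
                    cycle_duration / 100
                  },
                  none = 1)
  sqrt(mean(mag^2)) * scale
}

#' Gait standard deviation (GaitSD)
#'
#' Square root of the average across-cycle variance of the time-normalised
#' kinematic curves: for each variable and each of the 101 cycle time
#' points, the variance across cycles; GaitSD is the square root of the
#' grand mean of those variances. Higher values mean a more variable,
#' less stable gait.
#'
#' @param cycles List of per-cycle 101-by-V matrices (degrees), all with
#'   the same variables.
#' @return GaitSD in degrees; `NA` with fewer than 2 cycles.
#' @export
gait_sd <- function(cycles) {
  if (length(cycles) < 2) return(NA_real_)
  arr <- simplify2array(cycles)   # 101 x V x n_cycles
  v <- apply(arr, c(1, 2), stats::var)
  sqrt(mean(v))
}

#' The nine lower-body kinematic curves per gait cycle
#'
#' Pelvis tilt/obliquity/rotation, hip flexion/abduction/rotation, knee
#' flexion, ankle dorsiflexion and foot progression of the analysis side,
#' cut into gait cycles at consecutive same-side foot strikes and
#' time-normalised to 101 points each.
#'
#' @param trial Trial with virtual markers.
#' @param events Gait-event table.
#' @param side Analysis side ("left"/"right").
#' @param direction Heading for the pelvis/foot global angles.
#' @return List of 101-by-9 matrices, one per complete cycle (possibly
#'   empty).
#' @export
joint_angle_cycles <- function(trial, events, side = "left",
                               direction = c(1, 0)) {
  S <- if (side == "left") "L" else "R"
  require_markers(trial, c("MIDASIS", "MIDPSIS", "LASI", "RASI",
                           paste0(S, c("HJC", "KJC", "AJC", "KNE", "ANK",
                                       "HEE", "TOE"))))
  n <- n_frames(trial)
  lab <- heading_frame(direction, n)
  pelvis <- orthonormal_from(
    marker(trial, "MIDASIS") - marker(trial, "MIDPSIS"),
    cross3(marker(trial, "MIDASIS") - marker(trial, "MIDPSIS"),
           marker(trial, "LASI") - marker(trial, "RASI")))
  long_frame <- function(prox, dist, lateral) {
    z <- unit_rows(prox - dist)
    w <- lateral - dist
    y <- w - z * rowSums(w * z)
    if (S == "R") y <- -y
    y <- unit_rows(y)
    frame_from_axes(cross3(y, z), y, z)
  }
  thigh <- long_frame(marker(trial, paste0(S, "HJC")),
                      marker(trial, paste0(S, "KJC")),
                      marker(trial, paste0(S, "KNE")))
  shank <- long_frame(marker(trial, paste0(S, "KJC")),
                      marker(trial, paste0(S, "AJC")),
                      marker(trial, paste0(S, "ANK")))
  foot <- orthonormal_from(
    marker(trial, paste0(S, "TOE")) - marker(trial, paste0(S, "HEE")),
    marker(trial, paste0(S, "AJC")) - marker(trial, paste0(S, "HEE")))
  pel_lab <- relative_cardan(lab, pelvis)
  hip <- relative_cardan(pelvis, thigh)
  knee <- relative_cardan(thigh, shank)
  ankle <- relative_cardan(shank, foot)
  foot_lab <- relative_cardan(lab, foot)
  vars <- cbind(pelvis_tilt = pel_lab[, "pitch"],
                pelvis_obliquity = pel_lab[, "roll"],
                pelvis_rotation = pel_lab[, "yaw"],
                hip_flexion = hip[, "pitch"],
                hip_abduction = hip[, "roll"],
                hip_rotation = hip[, "yaw"],
                knee_flexion = knee[, "pitch"],
                ankle_dorsiflexion = ankle[, "pitch"],
                foot_progression = foot_lab[, "yaw"])
  st <- strike_times(events, side)
  if (length(st) < 2) return(list())
  t <- trial_times(trial)
  out <- list()
  for (k in seq_len(length(st) - 1)) {
    tt <- seq(st[k], st[k + 1], length.out = 101)
    out[[k]] <- interp_cols(t, vars, tt)
    colnames(out[[k]]) <- colnames(vars)
  }
  out
}
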