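#' Inverted-pendulum parameters for the extrapolated CoM
#'
#' @param l Pendulum length in metres: mean vertical CoM height (from a
#'   standing calibration when available, otherwise over the trial).
#' @param g Gravitational acceleration (m/s^2).
#' @return List with `l`, `g`, and the eigenfrequency `omega0 = sqrt(g/l)`.
#' @export
xcom_params <- function(l, g = GRAVITY) {
  if (!is.numeric(l) || l <= 0) stop("pendulum length l must be positive")
  list(l = l, g = g, omega0 = sqrt(g / l))
}

#' Medio-lateral range of motion of the CoM
#'
#' Max minus min of the detrended medio-lateral CoM coordinate (the
#' component normal to the walking direction, after removing the
#' least-squares linear trend that absorbs slow path drift).
#'
#' @param com A `com_trajectory`.
#' @param direction Unit 2-vector or n-by-2 per-frame headings.
#' @param detrend Remove the linear trend first (default TRUE).
#' @return Range in metres.
#' @export
ml_com_rom <- function(com, direction, detrend = TRUE) {
  ml <- ml_coordinate(com$position, direction)
  if (detrend) ml <- stats::residuals(stats::lm(ml ~ seq_along(ml)))
  max(ml) - min(ml)
}

ml_coordinate <- function(pos, direction) {
  n <- nrow(pos)
  d <- if (is.matrix(direction)) direction else matrix(direction, n, 2,
                                                       byrow = TRUE)
  -pos[, 1] * d[, 2] + pos[, 2] * d[, 1]
}

ap_coordinate <- function(pos, direction) {
  n <- nrow(pos)
  d <- if (is.matrix(direction)) direction else matrix(direction, n, 2,
                                                       byrow = TRUE)
  pos[, 1] * d[, 1] + pos[, 2] * d[, 2]
}

#' Extrapolated centre of mass
#'
#' Hof's inverted-pendulum extrapolation: the vertical projection of the
#' CoM displaced along its horizontal velocity, xCoM = CoM_h + v_h / omega0
#' with omega0 = sqrt(g / l).
#'
#' @param com A `com_trajectory`.
#' @param params [xcom_params()]; defaults to l = mean CoM height.
#' @return n-by-2 matrix of floor-plane xCoM positions (m).
#' @export
extrapolated_com <- function(com, params = xcom_params(com$mean_height)) {
  com$position[, 1:2, drop = FALSE] +
    com$velocity[, 1:2, drop = FALSE] / params$omega0
}

#' Margin of stability at leading-foot strikes
#'
#' At each foot strike of the chosen side, the signed distance from the
#' extrapolated CoM to the lateral malleolar marker of the leading foot
#' (the reduced base of support), along the requested axis. Medio-lateral:
#' positive when the xCoM lies medial to the malleolus. Antero-posterior:
#' positive when the xCoM lies behind the malleolus along the progression
#' direction. The per-trial value is the median over cycles.
#'
#' @param trial Trial with lateral malleolus markers (LANK/RANK).
#' @param events Gait-event table.
#' @param com A `com_trajectory`.
#' @param params [xcom_params()]; defaults to l = mean CoM height.
#' @param side `"left"` or `"right"` (the analysis side).
#' @param plane `"ML"` or `"AP"`.
#' @param direction Heading (unit 2-vector or per-frame matrix).
#' @return List with `per_cycle` values (m), `median`, `times`, `side`,
#'   `plane`. `median` is `NA` with zero cycles.
#' @export
margin_of_stability <- function(trial, events, com,
                                params = xcom_params(com$mean_height),
                                side = "left", plane = c("ML", "AP"),
                                direction) {
  plane <- match.arg(plane)
  mal <- marker(trial, paste0(if (side == "left") "L" else "R", "ANK"))
  st <- strike_times(events, side)
  if (!length(st))
    return(list(per_cycle = numeric(), median = NA_real_,
                times = numeric(), side = side, plane = plane))
  idx <- pmin(pmax(round(st * trial$rate) + 1L, 1L), n_frames(trial))
  xcom <- extrapolated_com(com, params)
  n <- n_frames(trial)
  d <- if (is.matrix(direction)) direction else matrix(direction, n, 2,
                                                       byrow = TRUE)
  vals <- vapply(idx, function(i) {
    di <- d[i, ]
    if (plane == "ML") {
      mal_ml <- -mal[i, 1] * di[2] + mal[i, 2] * di[1]
      xcom_ml <- -xcom[i, 1] * di[2] + xcom[i, 2] * di[1]
      com_ml <- -com$position[i, 1] * di[2] + com$position[i, 2] * di[1]
      sgn <- if (mal_ml >= com_ml) 1 else -1  # toward the stance side
      sgn * (mal_ml - xcom_ml)
    } else {
      mal_ap <- mal[i, 1] * di[1] + mal[i, 2] * di[2]
      xcom_ap <- xcom[i, 1] * di[1] + xcom[i, 2] * di[2]
      mal_ap - xcom_ap
    }
  }, numeric(1))
  list(per_cycle = vals, median = stats::median(vals), times = st,
       side = side, plane = plane)
}

#' Range of an angular-momentum plane component
#'
#' @param wbam_by_plane Output of [wbam_planes()].
#' @param plane `"sagittal"`, `"coronal"` or `"transverse"`.
#' @return max - min of the component over the trial.
#' @export
wbam_range <- function(wbam_by_plane,
                       plane = c("sagittal", "coronal", "transverse")) {
  plane <- match.arg(plane)
  x <- wbam_by_plane[, plane]
  max(x) - min(x)
}
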