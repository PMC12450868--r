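#' @keywords internal
"_PACKAGE"

# Lab frame convention used throughout: X = nominal progression (AP),
# Y = medio-lateral (ML), Z = vertical (up). Right-handed; Z along gravity.

#' Gravitational acceleration used by the inverted-pendulum model (m/s^2)
#' @keywords internal
GRAVITY <- 9.81

#' The 14 task labels of the measurement protocol
#'
#' Three self-selected walking speeds (three repetitions each in the original
#' protocol), two cognitive dual tasks, and the instrumented items of the
#' Functional Gait Assessment battery.
#'
#' @return Character vector of canonical task identifiers.
#' @export
task_set <- function() {
  c("comfortable", "slow", "fast",
    "dual_animal", "dual_letter",
    "change_speed", "head_turns_horizontal", "head_turns_vertical",
    "turn_pivot", "step_obstacle", "tandem", "eyes_closed",
    "backwards", "steps")
}

#' Canonical marker set
#'
#' CGM 1.0-style lower-body labels plus four head markers, four trunk
#' markers, pelvis, and bilateral shoulder/elbow/wrist markers needed by the
#' 13-segment angular-momentum model.
#'
#' @return Character vector of marker labels.
#' @export
marker_set <- function() {
  c("LFHD", "RFHD", "LBHD", "RBHD",
    "C7", "T10", "CLAV", "STRN",
    "LASI", "RASI", "LPSI", "RPSI",
    "LTHI", "LKNE", "LTIB", "LANK", "LHEE", "LTOE",
    "RTHI", "RKNE", "RTIB", "RANK", "RHEE", "RTOE",
    "LSHO", "LELB", "LWRI", "RSHO", "RELB", "RWRI")
}

# numeric gradient with central differences (forward/backward at the ends)
finite_diff <- function(x, dt) {
  n <- NROW(x)
  if (is.matrix(x)) {
    v <- x
    if (n >= 3) {
      v[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
    }
    v[1, ] <- (x[2, ] - x[1, ]) / dt
    v[n, ] <- (x[n, ] - x[n - 1, ]) / dt
    v
  } else {
    v <- numeric(n)
    if (n >= 3) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    v[1] <- (x[2] - x[1]) / dt
    v[n] <- (x[n] - x[n - 1]) / dt
    v
  }
}

vec_norm <- function(m) sqrt(rowSums(m^2))

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

unit_rows <- function(m) {
  n <- vec_norm(m)
  n[n == 0] <- 1
  m / n
}

# linear 1-d interpolation of each column of a matrix onto new abscissae
interp_cols <- function(t_old, m, t_new) {
  apply(m, 2, function(col) stats::approx(t_old, col, xout = t_new, rule = 2)$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
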