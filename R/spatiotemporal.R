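#' Zone specification for the floor deviation scores
#'
#' Four nested medio-lateral zones about the walkway midline. Defaults are
#' the 6/10/15-inch deviation half-widths of level-surface gait scoring
#' (0.1524, 0.254, 0.381 m) with weights 0, 1, 2, 3 from the innermost zone
#' outwards.
#'
#' @param boundaries Strictly increasing half-widths (m) separating zone 0
#'   from 1, 1 from 2, 2 from 3.
#' @param weights Non-negative per-zone weights; weight of zone 0 must be 0.
#' @return A `zone_spec` list.
#' @export
zone_spec <- function(boundaries = c(0.1524, 0.254, 0.381),
                      weights = c(0, 1, 2, 3)) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("zone boundaries must be strictly increasing")
  if (length(weights) != length(boundaries) + 1L)
    stop("need one weight per zone (boundaries + 1)")
  if (weights[1] != 0) stop("weight of zone 0 must be 0")
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(boundaries = boundaries, weights = weights),
            class = "zone_spec")
}

zone_index <- function(ml_dev, zones) {
  # zone 0 innermost; zone k when |dev| exceeds boundary k
  findInterval(abs(ml_dev), zones$boundaries)
}

#' Fit the walkway midline and return signed ML deviations
#'
#' The midline is the least-squares line through the floor-plane path
#' (steady-state portion); deviations are signed normal distances to it.
#'
#' @param pos n-by-2/3 floor-plane trajectory.
#' @param trim Fraction of frames trimmed at each end before fitting (0.1).
#' @return Numeric vector of signed ML deviations (m); attribute `"line"`
#'   holds the point/direction of the fitted midline.
#' @export
midline_deviation <- function(pos, trim = 0.1) {
  xy <- pos[, 1:2, drop = FALSE]
  n <- nrow(xy)
  keep <- max(1, floor(n * trim)):min(n, ceiling(n * (1 - trim)))
  ctr <- colMeans(xy[keep, , drop = FALSE])
  d <- svd(sweep(xy[keep, , drop = FALSE], 2, ctr))$v[, 1]
  dev <- -(xy[, 1] - ctr[1]) * d[2] + (xy[, 2] - ctr[2]) * d[1]
  attr(dev, "line") <- list(point = ctr, direction = d)
  dev
}

#' CoM zone score
#'
#' Counts the outward boundary crossings of the CoM: every time the CoM
#' moves into a more lateral zone, the weight of the zone entered is added.
#' The more the CoM visits the outer zones, the higher the score; a CoM
#' that never leaves the innermost zone scores 0. Computed over the entire
#' trial.
#'
#' @param com A `com_trajectory` (or n-by-2/3 position matrix).
#' @param zones A [zone_spec()].
#' @param ml_dev Optional precomputed signed ML deviations; defaults to
#'   [midline_deviation()] of the CoM path.
#' @return Non-negative score (dimensionless).
#' @export
com_zone_score <- function(com, zones = zone_spec(), ml_dev = NULL) {
  pos <- if (inherits(com, "com_trajectory")) com$position else com
  if (is.null(ml_dev)) ml_dev <- midline_deviation(pos)
  z <- zone_index(ml_dev, zones)
  up <- which(diff(z) > 0) + 1L
  sum(zones$weights[z[up] + 1L])
}

#' Foot zone score
#'
#' Integrates the time both heel markers spend in the lateral zones:
#' score = sum over zones z >= 1 of weight(z) * (time both heels lie in
#' zone >= z) / trial duration. Zero whenever at least one foot stays in
#' the innermost zone.
#'
#' @param trial Trial with LHEE/RHEE markers.
#' @param zones A [zone_spec()].
#' @param ml_dev_l,ml_dev_r Optional precomputed signed deviations of each
#'   heel from the walkway midline.
#' @return Score (weighted fraction of trial time).
#' @export
foot_zone_score <- function(trial, zones = zone_spec(),
                            ml_dev_l = NULL, ml_dev_r = NULL) {
  if (is.null(ml_dev_l) || is.null(ml_dev_r)) {
    lh <- marker(trial, "LHEE"); rh <- marker(trial, "RHEE")
    mid <- midline_deviation((lh + rh) / 2)
    line <- attr(mid, "line")
    devof <- function(m)
      -(m[, 1] - line$point[1]) * line$direction[2] +
        (m[, 2] - line$point[2]) * line$direction[1]
    ml_dev_l <- devof(lh); ml_dev_r <- devof(rh)
  }
  zl <- zone_index(ml_dev_l, zones)
  zr <- zone_index(ml_dev_r, zones)
  both <- pmin(zl, zr)
  n <- length(both)
  score <- 0
  for (z in seq_along(zones$boundaries)) {
    score <- score + zones$weights[z + 1] * sum(both >= z) / n
  }
  score
}

#' Per-strike step series
#'
#' Heel positions at each foot strike with side and time, the raw material
#' for step width and medio-lateral step distance.
#'
#' @param trial Trial with heel markers.
#' @param events Gait-event table.
#' @return Data frame: time, side, x, y (heel position at strike).
#' @export
step_series <- function(trial, events) {
  rows <- lapply(c("left", "right"), function(side) {
    st <- strike_times(events, side)
    if (!length(st)) return(NULL)
    hee <- marker(trial, paste0(if (side == "left") "L" else "R", "HEE"))
    idx <- pmin(pmax(round(st * trial$rate) + 1L, 1L), n_frames(trial))
    data.frame(time = st, side = side, x = hee[idx, 1], y = hee[idx, 2])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Step width
#'
#' For each leading-foot strike, the medio-lateral distance between the
#' leading heel (at its strike) and the contralateral heel (at its own
#' previous strike), measured normal to the walking direction; the
#' per-trial value is the median across cycles.
#'
#' @param steps A [step_series()].
#' @param direction Unit 2-vector heading (or per-step n-by-2 matrix).
#' @return Median step width (m); `NA` when no complete pair exists.
#' @export
step_width <- function(steps, direction) {
  if (is.null(steps) || nrow(steps) < 2) return(NA_real_)
  d <- if (is.matrix(direction)) direction
       else matrix(direction, nrow(steps), 2, byrow = TRUE)
  ml <- -steps$x * d[, 2] + steps$y * d[, 1]
  widths <- numeric()
  for (i in 2:nrow(steps)) {
    prev <- max(which(steps$side[1:(i - 1)] != steps$side[i]), -Inf)
    if (is.finite(prev)) widths <- c(widths, abs(ml[i] - ml[prev]))
  }
  if (!length(widths)) return(NA_real_)
  stats::median(widths)
}

#' Maximum medio-lateral distance between ipsilateral steps
#'
#' For each consecutive pair of same-side strikes, the absolute difference
#' of their medio-lateral offsets; the parameter is the maximum over the
#' analysis side's pairs. Sensitive to lateral catch-up steps that displace
#' a single placement without deviating the overall path.
#'
#' @param steps A [step_series()].
#' @param direction Heading as in [step_width()].
#' @param side Analysis side (`"left"`/`"right"`).
#' @return Maximum ML offset difference (m); `NA` with < 2 same-side strikes.
#' @export
ml_step_distance <- function(steps, direction, side = "left") {
  if (is.null(steps)) return(NA_real_)
  keep <- steps$side == side
  sub <- steps[keep, , drop = FALSE]
  if (nrow(sub) < 2) return(NA_real_)
  d <- if (is.matrix(direction)) direction[keep, , drop = FALSE]
       else matrix(direction, nrow(sub), 2, byrow = TRUE)
  ml <- -sub$x * d[, 2] + sub$y * d[, 1]
  max(abs(diff(ml)))
}

#' Tandem-walk step count
#'
#' Number of consecutive heel-to-toe placements whose heel lands within
#' `line_tolerance` of the tandem line, counted up to the first off-line
#' placement (or trial end).
#'
#' @param trial Tandem-task trial.
#' @param events Gait-event table.
#' @param line_tolerance Lateral heel tolerance in metres (default 0.05).
#' @param line The tandem line as list(point, direction). The taped line is
#'   a lab fixture, so the default is the lab X axis through the origin;
#'   override with the measured tape position when it differs.
#' @return Integer step count.
#' @export
tandem_step_count <- function(trial, events, line_tolerance = 0.05,
                              line = list(point = c(0, 0),
                                          direction = c(1, 0))) {
  if (trial$task != "tandem")
    stop("tandem_step_count requires a tandem-task trial, got: ", trial$task)
  steps <- step_series(trial, events)
  if (is.null(steps) || !nrow(steps)) return(0L)
  dev <- -(steps$x - line$point[1]) * line$direction[2] +
    (steps$y - line$point[2]) * line$direction[1]
  ok <- abs(dev) <= line_tolerance
  if (!ok[1]) return(0L)
  run <- which(!ok)
  if (!length(run)) nrow(steps) else run[1] - 1L
}

#' Walking speed
#'
#' Horizontal CoM path distance between the first and last foot strike,
#' divided by the elapsed time.
#'
#' @param com A `com_trajectory`.
#' @param events Gait-event table (needs >= 2 strikes).
#' @return Speed in m/s; `NA` with fewer than 2 strikes.
#' @export
walking_speed <- function(com, events) {
  st <- sort(events$time[events$kind == "foot_strike"])
  if (length(st) < 2) return(NA_real_)
  i0 <- max(1L, round(st[1] * com$rate) + 1L)
  i1 <- min(nrow(com$position), round(st[length(st)] * com$rate) + 1L)
  if (i1 <= i0) return(NA_real_)
  path <- sum(vec_norm(diff(com$position[i0:i1, 1:2, drop = FALSE])))
  path / (st[length(st)] - st[1])
}

#' Double-support time
#'
#' Per gait cycle of the analysis side, the summed duration of the two
#' double-support intervals (both feet on the ground); the per-trial value
#' is the median across cycles. Running-style cycles (foot off before the
#' contralateral strike) contribute zero.
#'
#' @param events Gait-event table with complete strike/off sequences.
#' @param side Analysis side defining the cycles (default "left").
#' @return List with `per_cycle` (s) and `median`.
#' @export
double_support_time <- function(events, side = "left") {
  st <- strike_times(events, side)
  if (length(st) < 2) return(list(per_cycle = numeric(), median = NA_real_))
  vals <- vapply(seq_len(length(st) - 1), function(k) {
    a <- st[k]; b <- st[k + 1]
    stance_overlap_in_window(events, a, b)
  }, numeric(1))
  list(per_cycle = vals, median = stats::median(vals))
}

# total time within [a, b) during which both feet are in stance, from the
# event table's stance indicator
stance_overlap_in_window <- function(events, a, b) {
  times <- sort(unique(c(a, b, events$time[events$time > a & events$time < b])))
  tot <- 0
  for (j in seq_len(length(times) - 1)) {
    mid <- (times[j] + times[j + 1]) / 2
    if (in_stance(events, "left", mid) && in_stance(events, "right", mid))
      tot <- tot + (times[j + 1] - times[j])
  }
  tot
}

in_stance <- function(events, side, t) {
  sub <- events[events$side == side & events$time <= t, , drop = FALSE]
  if (!nrow(sub)) {
    # before the first event: in stance iff the first event is a foot off
    nxt <- events[events$side == side, , drop = FALSE]
    return(nrow(nxt) > 0 && nxt$kind[1] == "foot_off")
  }
  sub$kind[nrow(sub)] == "foot_strike"
}

#' Task time
#'
#' Time needed to perform the task: last event minus first event when an
#' event table is given, otherwise the trial duration.
#'
#' @param trial A trial.
#' @param events Optional gait-event table.
#' @return Seconds.
#' @export
task_time <- function(trial, events = NULL) {
  if (!is.null(events) && nrow(events) >= 2)
    max(events$time) - min(events$time)
  else trial_duration(trial)
}

#' Aggregate per-cycle values to a single per-trial value
#'
#' @param values Numeric per-cycle values.
#' @return List with `value` (median; `NA` when empty) and `n_cycles`.
#' @export
aggregate_per_trial <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(list(value = NA_real_, n_cycles = 0L))
  list(value = stats::median(values), n_cycles = length(values))
}
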