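#' Fill marker gaps
#'
#' Gaps are frames flagged `NaN`. Short gaps (up to `spline_max` frames) are
#' filled per coordinate by cubic-spline interpolation. Longer gaps are
#' reconstructed from marker inter-correlations by iterated low-rank
#' (principal-component) estimation over the full marker matrix,
#' initialised with the spline fill; observed samples are never modified.
#' Gaps longer than `max_gap` are reported and left unfilled.
#'
#' @param trial A [trial_record()] whose gaps are NaN runs.
#' @param max_gap Longest fillable gap, in frames (default 100).
#' @param spline_max Gap length up to which plain spline fill is used (10).
#' @param rank Rank of the low-rank reconstruction (default 15, near the
#'   effective rank of a full-body gait marker matrix; higher ranks start
#'   reproducing the spline initialisation instead of the shared motion).
#' @param tol Convergence tolerance on imputed positions, metres (1e-6).
#' @param max_iter Iteration cap for the low-rank pass (30).
#' @return The trial with gaps filled; attribute `"unfilled"` lists any
#'   (marker, start, end) runs beyond `max_gap`.
#' @export
fill_gaps <- function(trial, max_gap = 100, spline_max = 10,
                      rank = 15, tol = 1e-6, max_iter = 30) {
  Y <- do.call(cbind, trial$markers)
  colnames(Y) <- NULL
  if (!anyNA(Y)) return(trial)
  n <- nrow(Y)
  miss_marker <- vapply(trial$markers, function(m) rowSums(is.na(m)) > 0,
                        logical(n))
  if (any(rowSums(!miss_marker) == 0))
    stop("unfillable gap: all markers simultaneously missing in some frames")
  if (sum(colSums(is.na(Y)) == 0) < 3 * 3)
    stop("gap filling needs at least 3 fully observed markers")

  gap_runs <- function(isna) {
    r <- rle(isna)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }
  unfilled <- list()
  fill_mask <- matrix(FALSE, n, ncol(Y))
  long_mask <- matrix(FALSE, n, ncol(Y))
  labs <- rep(names(trial$markers), each = 3)
  for (j in seq_len(ncol(Y))) {
    isna <- is.na(Y[, j])
    if (!any(isna)) next
    runs <- gap_runs(isna)
    for (k in seq_len(nrow(runs))) {
      len <- runs[k, 2] - runs[k, 1] + 1L
      idx <- runs[k, 1]:runs[k, 2]
      if (len > max_gap) {
        unfilled[[length(unfilled) + 1L]] <-
          data.frame(marker = labs[j], start = runs[k, 1], end = runs[k, 2])
      } else {
        fill_mask[idx, j] <- TRUE
        if (len > spline_max) long_mask[idx, j] <- TRUE
      }
    }
  }
  # spline initialisation for every fillable entry
  for (j in seq_len(ncol(Y))) {
    tofill <- fill_mask[, j]
    if (!any(tofill)) next
    obs <- which(!is.na(Y[, j]))
    Y[tofill, j] <- stats::spline(obs, Y[obs, j], xout = which(tofill),
                                  method = "natural")$y
  }
  # low-rank refinement for entries beyond the spline regime
  if (any(long_mask)) {
    Ywork <- Y
    Ywork[is.na(Ywork)] <- 0   # entries beyond max_gap: excluded below anyway
    r_use <- min(rank, ncol(Y) - 1L, n - 1L)
    for (it in seq_len(max_iter)) {
      mu <- colMeans(Ywork)
      Yc <- sweep(Ywork, 2, mu)
      sv <- svd(Yc, nu = r_use, nv = r_use)
      approxY <- sweep(sv$u %*% (diag(sv$d[seq_len(r_use)], r_use) %*%
                                   t(sv$v)), 2, mu, `+`)
      delta <- max(abs(approxY[long_mask] - Ywork[long_mask]))
      Ywork[long_mask] <- approxY[long_mask]
      if (delta < tol) break
    }
    Y[long_mask] <- Ywork[long_mask]
  }
  out <- trial
  for (k in seq_along(out$markers))
    out$markers[[k]] <- Y[, (3 * k - 2):(3 * k), drop = FALSE]
  if (length(unfilled))
    attr(out, "unfilled") <- do.call(rbind, unfilled)
  out
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies the configured Butterworth design forward and backward
#' (zero phase, the gait-laboratory norm: event timing is not shifted) to
#' every marker coordinate.
#'
#' @param trial A [trial_record()] with no NaNs.
#' @param cutoff Cut-off frequency in Hz (default 6).
#' @param order Filter order of each pass (default 4).
#' @param zero_phase Apply bidirectionally (default TRUE).
#' @return Filtered trial.
#' @export
lowpass <- function(trial, cutoff = 6, order = 4, zero_phase = TRUE) {
  nyq <- trial$rate / 2
  if (cutoff >= nyq)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  Y <- do.call(cbind, trial$markers)
  colnames(Y) <- NULL
  if (anyNA(Y)) stop("lowpass requires gap-filled (NaN-free) trajectories")
  bw <- signal::butter(order, cutoff / nyq, type = "low")
  Yf <- if (zero_phase) zero_phase_filter(Y, bw$b, bw$a)
        else apply(Y, 2, function(col) as.numeric(signal::filter(bw, col)))
  out <- trial
  for (k in seq_along(out$markers))
    out$markers[[k]] <- Yf[, (3 * k - 2):(3 * k), drop = FALSE]
  out
}

# forward-backward IIR filtering of every column at once, with odd
# (mirror) end padding to suppress edge transients
zero_phase_filter <- function(Y, b, a, npad = NULL) {
  Y <- as.matrix(Y)
  colnames(Y) <- NULL
  n <- nrow(Y)
  npad <- npad %||% min(n - 1L, 50L)
  pad_top <- 2 * matrix(Y[1, ], npad, ncol(Y), byrow = TRUE) -
    Y[(npad + 1L):2L, , drop = FALSE]
  pad_bot <- 2 * matrix(Y[n, ], npad, ncol(Y), byrow = TRUE) -
    Y[(n - 1L):(n - npad), , drop = FALSE]
  one_pass <- function(X) {
    # remove the initial level first: the recursion starts from zero state,
    # so filtering the deviation kills the start-up transient
    x0 <- X[1, ]
    X <- sweep(X, 2, x0)
    v <- stats::filter(X, b, method = "convolution", sides = 1)
    # the convolution is undefined for the first length(b)-1 samples (deep
    # in the pad); substitute the steady-state MA response there
    head_i <- seq_len(length(b) - 1L)
    v[head_i, ] <- sum(b) * X[head_i, , drop = FALSE]
    y <- stats::filter(v, -a[-1], method = "recursive")
    sweep(matrix(as.numeric(y), nrow(X), ncol(X)), 2, x0, `+`)
  }
  Z <- rbind(pad_top, Y, pad_bot)
  Z <- one_pass(Z)
  Z <- one_pass(Z[nrow(Z):1L, , drop = FALSE])
  Z <- Z[nrow(Z):1L, , drop = FALSE]
  Z[(npad + 1L):(npad + n), , drop = FALSE]
}

#' Add virtual joint-centre markers
#'
#' Adds pelvis mid-points (MIDASIS, MIDPSIS), regression-based hip joint
#' centres, and medially offset knee, ankle and elbow centres (offset =
#' marker radius + half joint width along the segment-normal medial
#' direction), plus shoulder and wrist centres, to the trial. Constants are
#' overridable through `geometry`.
#'
#' @param trial A [trial_record()] with the canonical surface markers.
#' @param geometry Named list of constants: `marker_radius` (m, 0.007),
#'   `knee_width` (0.10), `ankle_width` (0.07), `elbow_width` (0.07),
#'   `shoulder_offset` (0.04), and the hip-regression fractions
#'   `hip_ap`, `hip_ml`, `hip_down` of the inter-ASIS distance
#'   (0.19, 0.36, 0.30).
#' @return Trial with the virtual markers appended.
#' @export
add_virtual_markers <- function(trial, geometry = list()) {
  g <- utils::modifyList(list(marker_radius = 0.007, knee_width = 0.10,
                              ankle_width = 0.07, elbow_width = 0.07,
                              shoulder_offset = 0.04,
                              hip_ap = 0.19, hip_ml = 0.36, hip_down = 0.30),
                         geometry)
  require_markers(trial, c("LASI", "RASI", "LPSI", "RPSI"))
  lasi <- marker(trial, "LASI"); rasi <- marker(trial, "RASI")
  lpsi <- marker(trial, "LPSI"); rpsi <- marker(trial, "RPSI")
  midasis <- (lasi + rasi) / 2
  midpsis <- (lpsi + rpsi) / 2
  y_left <- lasi - rasi                       # toward the left
  fwd_raw <- midasis - midpsis
  if (stats::median(vec_norm(cross3(y_left, fwd_raw))) <
      1e-9 * stats::median(vec_norm(y_left) * vec_norm(fwd_raw)) ||
      stats::median(vec_norm(fwd_raw)) < 1e-9)
    stop("degenerate pelvis geometry: ASIS/PSIS markers are collinear")
  y_left <- unit_rows(y_left)
  fwd <- unit_rows(fwd_raw - y_left * rowSums(fwd_raw * y_left))
  z_up <- cross3(fwd, y_left)
  d <- vec_norm(lasi - rasi)                  # inter-ASIS distance
  hip <- function(sgn)
    midasis - fwd * (g$hip_ap * d) + y_left * (sgn * g$hip_ml * d) -
      z_up * (g$hip_down * d)
  add <- list(MIDASIS = midasis, MIDPSIS = midpsis,
              LHJC = hip(+1), RHJC = hip(-1))

  medial_offset <- function(lat, prox, dist, off) {
    # push the lateral marker toward the proximal-distal line by `off`
    axis <- unit_rows(dist - prox)
    w <- prox - lat
    medial <- unit_rows(w - axis * rowSums(w * axis))
    lat + medial * off
  }
  for (s in c("L", "R")) {
    kne <- marker(trial, paste0(s, "KNE"))
    ank <- marker(trial, paste0(s, "ANK"))
    hjc <- add[[paste0(s, "HJC")]]
    kjc <- medial_offset(kne, hjc, ank,
                         g$marker_radius + g$knee_width / 2)
    ajc <- medial_offset(ank, kjc, marker(trial, paste0(s, "TOE")),
                         g$marker_radius + g$ankle_width / 2)
    add[[paste0(s, "KJC")]] <- kjc
    add[[paste0(s, "AJC")]] <- ajc
    if (all(c(paste0(s, "SHO"), paste0(s, "ELB"), paste0(s, "WRI")) %in%
            names(trial$markers))) {
      sho <- marker(trial, paste0(s, "SHO"))
      elb <- marker(trial, paste0(s, "ELB"))
      wri <- marker(trial, paste0(s, "WRI"))
      sjc <- sho - cbind(0, 0, rep(g$shoulder_offset, nrow(sho)))
      add[[paste0(s, "SJC")]] <- sjc
      add[[paste0(s, "EJC")]] <- medial_offset(elb, sjc, wri,
                                               g$marker_radius +
                                                 g$elbow_width / 2)
      add[[paste0(s, "WJC")]] <- wri
    }
  }
  out <- trial
  out$markers <- c(out$markers, add[setdiff(names(add), names(out$markers))])
  out
}

#' Estimate the overall walking direction in the floor plane
#'
#' Unit vector maximising the progression variance of the horizontal
#' trajectory (first principal component of the floor-plane path), sign-
#' aligned with the net displacement. Trials with net displacement below
#' `min_displacement` fall back to the lab X axis with a warning.
#'
#' @param traj n-by-2 or n-by-3 matrix (CoM or mid-pelvis path, m).
#' @param min_displacement Fallback threshold in metres (default 0.5).
#' @return Unit 2-vector (X, Y components).
#' @export
estimate_walking_direction <- function(traj, min_displacement = 0.5) {
  xy <- traj[, 1:2, drop = FALSE]
  disp <- xy[nrow(xy), ] - xy[1, ]
  if (sqrt(sum(disp^2)) < min_displacement) {
    warning("net displacement below ", min_displacement,
            " m; falling back to the lab X axis")
    return(c(1, 0))
  }
  pc <- svd(sweep(xy, 2, colMeans(xy)))$v[, 1]
  if (sum(pc * disp) < 0) pc <- -pc
  pc / sqrt(sum(pc^2))
}

#' Per-frame local walking direction
#'
#' Heading from the low-pass-filtered horizontal velocity of the reference
#' trajectory; frames where the speed is below `min_speed` inherit the last
#' valid heading (or the overall direction). Needed for the
#' medio-lateral/antero-posterior decomposition on tasks with turns.
#'
#' @param traj n-by-2/3 horizontal trajectory (m).
#' @param rate Sampling rate (Hz).
#' @param cutoff Heading smoothing cut-off (Hz, default 1).
#' @param min_speed Speed floor in m/s (default 0.2).
#' @return n-by-2 matrix of unit heading vectors.
#' @export
walking_direction_series <- function(traj, rate, cutoff = 1, min_speed = 0.2) {
  xy <- traj[, 1:2, drop = FALSE]
  n <- nrow(xy)
  v <- finite_diff(xy, 1 / rate)
  if (n > 12 && cutoff < rate / 2) {
    b <- signal::butter(2, cutoff / (rate / 2), type = "low")
    v <- apply(v, 2, function(col) signal::filtfilt(b, col))
  }
  sp <- vec_norm(v)
  dir <- v / pmax(sp, 1e-12)
  fallback <- tryCatch(estimate_walking_direction(xy),
                       warning = function(w) c(1, 0))
  ok <- sp >= min_speed
  if (!any(ok)) return(matrix(fallback, n, 2, byrow = TRUE))
  last <- fallback
  for (i in seq_len(n)) {
    if (ok[i]) last <- dir[i, ] else dir[i, ] <- last
  }
  # frames before the first valid heading inherit the first valid one
  first_ok <- which(ok)[1]
  if (first_ok > 1)
    dir[seq_len(first_ok - 1), ] <- matrix(dir[first_ok, ],
                                           first_ok - 1, 2, byrow = TRUE)
  dir
}

#' Detect gait events from marker kinematics
#'
#' Coordinate-based detection: foot strikes at local maxima of the
#' (heel - mid-PSIS) progression coordinate, foot offs at local minima of
#' the (toe - mid-PSIS) progression coordinate, both along the local walking
#' direction. When the trial's progression displacement is small (turning,
#' tandem, standing) a vertical-coordinate fallback is used: strikes at heel-
#' height minima, offs at toe-velocity upward zero crossings.
#'
#' @param trial Preprocessed trial with heel/toe markers and MIDPSIS (run
#'   [add_virtual_markers()] first).
#' @param min_period Minimum same-side event separation in seconds (0.6).
#' @return A [gait_event_table()]; attribute `"warning"` carries an
#'   insufficient-cycles note when fewer than 2 strikes are found on a side.
#' @export
detect_gait_events <- function(trial, min_period = 0.6) {
  require_markers(trial, c("LHEE", "RHEE", "LTOE", "RTOE", "MIDPSIS"))
  rate <- trial$rate
  t <- trial_times(trial)
  pelvis <- marker(trial, "MIDPSIS")
  net <- sqrt(sum((pelvis[nrow(pelvis), 1:2] - pelvis[1, 1:2])^2))
  path_len <- sum(vec_norm(diff(pelvis[, 1:2, drop = FALSE])))
  use_vertical <- path_len < 1.0
  dirs <- if (!use_vertical) walking_direction_series(pelvis, rate) else NULL
  min_sep <- max(3L, round(min_period * rate))
  # pelvis speed mask: low-pass the horizontal velocity, then require at
  # least 30% of the trial's cruising (80th-percentile) speed
  v_pel <- finite_diff(pelvis[, 1:2, drop = FALSE], 1 / rate)
  if (n_frames(trial) > 24) {
    bw <- signal::butter(2, min(1 / (rate / 2), 0.99), type = "low")
    v_pel <- zero_phase_filter(v_pel, bw$b, bw$a)
  }
  sp_pel <- vec_norm(v_pel)
  moving <- sp_pel >= 0.3 * stats::quantile(sp_pel, 0.8)

  local_extrema <- function(x, sep, maxima = TRUE) {
    s <- if (maxima) x else -x
    n <- length(s)
    cand <- which(diff(sign(diff(s))) < 0) + 1L
    # order by height, greedily keep peaks separated by sep
    cand <- cand[order(s[cand], decreasing = TRUE)]
    keep <- integer()
    for (i in cand) {
      if (!length(keep) || all(abs(keep - i) >= sep)) keep <- c(keep, i)
    }
    sort(keep)
  }
  prog <- function(mk) rowSums((mk[, 1:2, drop = FALSE] -
                                  pelvis[, 1:2, drop = FALSE]) * dirs)
  ev_t <- numeric(); ev_s <- character(); ev_k <- character()
  warn <- NULL
  for (side in c("left", "right")) {
    S <- if (side == "left") "L" else "R"
    hee <- marker(trial, paste0(S, "HEE"))
    toe <- marker(trial, paste0(S, "TOE"))
    if (!use_vertical) {
      ph <- prog(hee); pt <- prog(toe)
      str_idx <- local_extrema(ph, min_sep, maxima = TRUE)
      off_idx <- local_extrema(pt, min_sep, maxima = FALSE)
      # ignore extrema while the body is (nearly) standing still: the
      # start/end plateaus of a trial produce noise extrema, not gait events
      str_idx <- str_idx[moving[str_idx]]
      off_idx <- off_idx[moving[off_idx]]
    } else {
      hz <- hee[, 3]
      if (max(hz) - min(hz) < 0.01) { str_idx <- off_idx <- integer() }
      else {
        str_idx <- local_extrema(-hz, min_sep, maxima = TRUE)
        str_idx <- str_idx[hz[str_idx] < min(hz) + 0.3 * (max(hz) - min(hz))]
        vz <- finite_diff(toe[, 3], 1 / rate)
        off_idx <- local_extrema(vz, min_sep, maxima = TRUE)
        off_idx <- off_idx[vz[off_idx] > 0.05]
      }
    }
    if (length(str_idx) < 2)
      warn <- c(warn, paste0("fewer than 2 foot strikes detected on the ",
                             side, " side"))
    kinds <- c(rep("foot_strike", length(str_idx)),
               rep("foot_off", length(off_idx)))
    times <- t[c(str_idx, off_idx)]
    o <- order(times)
    times <- times[o]; kinds <- kinds[o]
    # enforce alternation: drop the later of two consecutive same-kind events
    keep <- rep(TRUE, length(times))
    if (length(times) > 1)
      for (i in 2:length(times))
        if (kinds[i] == kinds[max(which(keep[1:(i - 1)]))]) keep[i] <- FALSE
    ev_t <- c(ev_t, times[keep])
    ev_s <- c(ev_s, rep(side, sum(keep)))
    ev_k <- c(ev_k, kinds[keep])
  }
  ev <- gait_event_table(ev_t, ev_s, ev_k)
  if (!is.null(warn)) attr(ev, "warning") <- warn
  ev
}
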