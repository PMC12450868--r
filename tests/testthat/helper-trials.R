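# Shared test builders and independent oracles.

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# neutral standing pose for the full canonical marker set (n static frames)
static_pose_markers <- function(n = 10, H = 1.70) {
  pz <- 0.57 * H
  base <- list(
    LFHD = c(0.09, 0.06, 0.94 * H + 0.03), RFHD = c(0.09, -0.06, 0.94 * H + 0.03),
    LBHD = c(-0.08, 0.07, 0.94 * H + 0.03), RBHD = c(-0.08, -0.07, 0.94 * H + 0.03),
    C7 = c(-0.10, 0, pz + 0.295 * H), CLAV = c(0.08, 0, pz + 0.27 * H),
    T10 = c(-0.11, 0, pz + 0.15 * H), STRN = c(0.09, 0, pz + 0.13 * H),
    LASI = c(0.10, 0.12, pz), RASI = c(0.10, -0.12, pz),
    LPSI = c(-0.12, 0.05, pz + 0.02), RPSI = c(-0.12, -0.05, pz + 0.02),
    LSHO = c(0, 0.19, pz + 0.27 * H), RSHO = c(0, -0.19, pz + 0.27 * H),
    LELB = c(0, 0.21, pz + 0.10 * H), RELB = c(0, -0.21, pz + 0.10 * H),
    LWRI = c(0, 0.22, pz - 0.04 * H), RWRI = c(0, -0.22, pz - 0.04 * H),
    LTHI = c(0.02, 0.15, 0.40 * H), RTHI = c(0.02, -0.15, 0.40 * H),
    LKNE = c(0.02, 0.14, 0.28 * H), RKNE = c(0.02, -0.14, 0.28 * H),
    LTIB = c(0.02, 0.12, 0.18 * H), RTIB = c(0.02, -0.12, 0.18 * H),
    LANK = c(0.02, 0.11, 0.07), RANK = c(0.02, -0.11, 0.07),
    LHEE = c(-0.04, 0.09, 0.03), RHEE = c(-0.04, -0.09, 0.03),
    LTOE = c(0.18, 0.10, 0.02), RTOE = c(0.18, -0.10, 0.02))
  lapply(base, function(p) matrix(rep(p, each = n), n, 3))
}

static_trial <- function(n = 10, H = 1.70, task = "comfortable") {
  trial_record("T1", task, static_pose_markers(n, H), 100,
               meta = list(height = H, mass = 70))
}

make_com <- function(position, velocity = NULL, rate = 100) {
  if (is.null(velocity)) {
    velocity <- vestgait:::finite_diff(position, 1 / rate)
  }
  structure(list(position = position, velocity = velocity,
                 mean_height = mean(position[, 3]), rate = rate),
            class = "com_trajectory")
}

quick_subject <- function(group = "HS", seed = 42) {
  draw_subject(group_presets()[[group]], paste0(group, "T"), group, seed)
}

# --- independent statistical oracles (deliberately separate code paths) ---

oracle_kw <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (i in seq_along(groups)) {
    ni <- sum(g == i)
    H <- H + ni * (mean(r[g == i]) - (N + 1) / 2)^2
  }
  H <- 12 / (N * (N + 1)) * H
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

oracle_holm <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- numeric(k)
  running <- 0
  for (i in seq_len(k)) {
    running <- max(running, (k - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

oracle_dunn <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  corr <- sum(ties^3 - ties) / (12 * (N - 1))
  nm <- names(groups)
  out <- list()
  for (i in 1:(length(nm) - 1)) for (j in (i + 1):length(nm)) {
    a <- nm[i]; b <- nm[j]
    na <- sum(g == a); nb <- sum(g == b)
    z <- (mean(r[g == a]) - mean(r[g == b])) /
      sqrt((N * (N + 1) / 12 - corr) * (1 / na + 1 / nb))
    out[[paste0(a, "-", b)]] <- 2 * (1 - pnorm(abs(z)))
  }
  unlist(out)
}

# dense-grid double-support oracle from an event table
oracle_double_support <- function(events, side, dt = 1e-4) {
  stance_fun <- function(sd0) {
    ev <- events[events$side == sd0, , drop = FALSE]
    function(t) {
      if (!nrow(ev)) return(rep(FALSE, length(t)))
      idx <- findInterval(t, ev$time)
      out <- logical(length(t))
      out[idx > 0] <- ev$kind[idx[idx > 0]] == "foot_strike"
      out[idx == 0] <- ev$kind[1] == "foot_off"
      out
    }
  }
  sl <- stance_fun("left"); sr <- stance_fun("right")
  st <- strike_times(events, side)
  vapply(seq_len(length(st) - 1), function(k) {
    tt <- seq(st[k], st[k + 1] - dt, by = dt)
    sum(sl(tt) & sr(tt)) * dt
  }, numeric(1))
}
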