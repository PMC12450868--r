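# Anthropometric segment tables (adult averages from the standard published
# inertia tables, mass fractions renormalised to sum exactly to 1 within
# each model). com_ratio = fractional CoM position from the proximal
# landmark; rg_t1/rg_t2/rg_l = gyration radii as fractions of segment
# length about the two transverse axes and the long axis.

seg_row <- function(name, proximal, distal, aux, mass, com, rg) {
  data.frame(segment = name, proximal = proximal, distal = distal,
             aux = aux, mass_fraction = mass, com_ratio = com,
             rg_t1 = rg[1], rg_t2 = rg[2], rg_l = rg[3],
             stringsAsFactors = FALSE)
}

#' 9-segment centre-of-mass model
#'
#' Reduced whole-body model driven by 13 markers/joint centres: combined
#' head+trunk segment, pelvis, both thighs, both shanks, both feet, and the
#' two arms lumped into a single segment. Sufficient for an accurate
#' whole-body CoM without a full-body marker set.
#'
#' @return A `body_model` object (data.frame of segment specs).
#' @export
body_model_9seg <- function() {
  tb <- rbind(
    seg_row("head_trunk", "HEADC", "MIDHJC", "C7",  0.504, 0.55, c(0.35, 0.32, 0.19)),
    seg_row("pelvis",  "MIDASIS", "MIDPSIS", "LASI", 0.112, 0.50, c(0.31, 0.30, 0.30)),
    seg_row("arms",    "MIDSJC", "MIDWJC", "LSJC",  0.099, 0.45, c(0.30, 0.29, 0.12)),
    seg_row("thigh_L", "LHJC", "LKJC", "LKNE", 0.1416, 0.41, c(0.33, 0.33, 0.15)),
    seg_row("thigh_R", "RHJC", "RKJC", "RKNE", 0.1416, 0.41, c(0.33, 0.33, 0.15)),
    seg_row("shank_L", "LKJC", "LAJC", "LANK", 0.0433, 0.44, c(0.28, 0.28, 0.10)),
    seg_row("shank_R", "RKJC", "RAJC", "RANK", 0.0433, 0.44, c(0.28, 0.28, 0.10)),
    seg_row("foot_L",  "LHEE", "LTOE", "LANK", 0.0137, 0.44, c(0.25, 0.12, 0.25)),
    seg_row("foot_R",  "RHEE", "RTOE", "RANK", 0.0137, 0.44, c(0.25, 0.12, 0.25)))
  new_body_model(tb, "9seg")
}

#' 13-segment whole-body angular-momentum model
#'
#' Splits head, thorax and pelvis, and models each arm as upper arm and
#' forearm+hand, so that segment rotations contribute their own inertia.
#'
#' @return A `body_model` object.
#' @export
body_model_13seg <- function() {
  tb <- rbind(
    seg_row("head",    "HEADC", "C7",  "LFHD", 0.0694, 0.50, c(0.36, 0.36, 0.31)),
    seg_row("thorax",  "C7", "MIDPELV", "STRN", 0.3229, 0.45, c(0.35, 0.32, 0.19)),
    seg_row("pelvis",  "MIDPELV", "MIDHJC", "LASI", 0.1117, 0.50, c(0.31, 0.30, 0.30)),
    seg_row("uparm_L", "LSJC", "LEJC", "LELB", 0.0271, 0.577, c(0.28, 0.27, 0.16)),
    seg_row("uparm_R", "RSJC", "REJC", "RELB", 0.0271, 0.577, c(0.28, 0.27, 0.16)),
    seg_row("forearm_L", "LEJC", "LWJC", "LELB", 0.0223, 0.57, c(0.30, 0.29, 0.12)),
    seg_row("forearm_R", "REJC", "RWJC", "RELB", 0.0223, 0.57, c(0.30, 0.29, 0.12)),
    seg_row("thigh_L", "LHJC", "LKJC", "LKNE", 0.1416, 0.41, c(0.33, 0.33, 0.15)),
    seg_row("thigh_R", "RHJC", "RKJC", "RKNE", 0.1416, 0.41, c(0.33, 0.33, 0.15)),
    seg_row("shank_L", "LKJC", "LAJC", "LANK", 0.0433, 0.44, c(0.28, 0.28, 0.10)),
    seg_row("shank_R", "RKJC", "RAJC", "RANK", 0.0433, 0.44, c(0.28, 0.28, 0.10)),
    seg_row("foot_L",  "LHEE", "LTOE", "LANK", 0.0137, 0.44, c(0.25, 0.12, 0.25)),
    seg_row("foot_R",  "RHEE", "RTOE", "RANK", 0.0137, 0.44, c(0.25, 0.12, 0.25)))
  new_body_model(tb, "13seg")
}

new_body_model <- function(tb, kind) {
  tb$mass_fraction <- tb$mass_fraction / sum(tb$mass_fraction)
  stopifnot(abs(sum(tb$mass_fraction) - 1) < 1e-9,
            all(tb$com_ratio >= 0 & tb$com_ratio <= 1),
            all(tb[, c("rg_t1", "rg_t2", "rg_l")] > 0))
  attr(tb, "kind") <- kind
  class(tb) <- c("body_model", "data.frame")
  tb
}

#' Read a body model from a delimited text file
#'
#' The file must carry the columns of the built-in models (`segment`,
#' `proximal`, `distal`, `aux`, `mass_fraction`, `com_ratio`, `rg_t1`,
#' `rg_t2`, `rg_l`); mass fractions are renormalised to sum to 1.
#'
#' @param path CSV path.
#' @return A `body_model` object.
#' @export
read_body_model <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "proximal", "distal", "aux", "mass_fraction",
            "com_ratio", "rg_t1", "rg_t2", "rg_l")
  absent <- setdiff(need, names(tb))
  if (length(absent))
    stop("body-model file missing column(s): ", paste(absent, collapse = ", "))
  new_body_model(tb[, need], "custom")
}

# composite landmarks derived from markers already on the trial
resolve_landmark <- function(trial, label) {
  composite <- list(
    HEADC = c("LFHD", "RFHD", "LBHD", "RBHD"),
    MIDHJC = c("LHJC", "RHJC"), MIDSJC = c("LSJC", "RSJC"),
    MIDWJC = c("LWJC", "RWJC"),
    MIDPELV = c("MIDASIS", "MIDPSIS"))
  if (label %in% names(trial$markers)) return(marker(trial, label))
  if (label %in% names(composite)) {
    parts <- composite[[label]]
    require_markers(trial, parts)
    return(Reduce(`+`, lapply(parts, marker, trial = trial)) / length(parts))
  }
  stop("unresolvable landmark: ", label)
}

#' Whole-body centre of mass
#'
#' Mass-fraction-weighted sum of the segment CoMs, per frame; velocity by
#' central differences at the trial rate.
#'
#' @param trial Trial with virtual markers added.
#' @param model A `body_model` (default [body_model_9seg()]).
#' @return A `com_trajectory`: list with `position` (n x 3, m), `velocity`
#'   (n x 3, m/s), `mean_height` (m), `rate`.
#' @export
compute_com <- function(trial, model = body_model_9seg()) {
  pos <- 0
  for (i in seq_len(nrow(model))) {
    p <- tryCatch(resolve_landmark(trial, model$proximal[i]),
                  error = function(e) stop("segment ", model$segment[i],
                                           ": ", conditionMessage(e)))
    d <- tryCatch(resolve_landmark(trial, model$distal[i]),
                  error = function(e) stop("segment ", model$segment[i],
                                           ": ", conditionMessage(e)))
    pos <- pos + model$mass_fraction[i] *
      (p + model$com_ratio[i] * (d - p))
  }
  structure(list(position = pos,
                 velocity = finite_diff(pos, 1 / trial$rate),
                 mean_height = mean(pos[, 3]),
                 rate = trial$rate),
            class = "com_trajectory")
}

# orthonormal triad per frame for a segment: e3 = long axis (distal ->
# proximal), e1 = aux direction orthogonalised, e2 = e3 x e1
segment_basis <- function(prox, dist, aux) {
  e3 <- prox - dist
  len <- vec_norm(e3)
  if (any(len < 1e-9)) stop("segment with zero length")
  e3 <- e3 / len
  w <- aux - prox
  e1 <- w - e3 * rowSums(w * e3)
  n1 <- vec_norm(e1)
  if (any(n1 < 1e-12)) {
    # aux collinear with the long axis: pick any orthogonal direction
    ref <- matrix(rep(c(1, 0, 0), each = nrow(e3)), ncol = 3)
    swap <- abs(rowSums(e3 * ref)) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    e1 <- ref - e3 * rowSums(ref * e3)
    n1 <- vec_norm(e1)
  }
  e1 <- e1 / n1
  list(e1 = e1, e2 = cross3(e3, e1), e3 = e3, length = len)
}

# angular velocity of a moving triad: omega = 0.5 * sum_k e_k x de_k/dt
basis_angular_velocity <- function(basis, dt) {
  0.5 * (cross3(basis$e1, finite_diff(basis$e1, dt)) +
           cross3(basis$e2, finite_diff(basis$e2, dt)) +
           cross3(basis$e3, finite_diff(basis$e3, dt)))
}

#' Whole-body angular momentum about the CoM
#'
#' Sum over the model's segments of the remote (transfer) and local (spin)
#' terms, each transferred to the whole-body CoM:
#' L_i = m_i (r_i - r_com) x (v_i - v_com) + R_i I_i R_i' w_i.
#' Segment orientations come from marker triads; segment inertias from the
#' gyration-radius table scaled by subject mass and per-frame segment
#' length. By default the result is normalised to be dimensionless by
#' body mass x height x mean CoM speed.
#'
#' @param trial Trial with virtual markers.
#' @param model A `body_model` (default [body_model_13seg()]).
#' @param com A `com_trajectory` (by convention the 9-segment CoM).
#' @param body_mass Subject mass in kg (default from `trial$meta$mass`, else 70).
#' @param height Subject height in m (default from `trial$meta$height`, else 1.70).
#' @param normalize `"mass_height_speed"` (default: divide by M*H*mean CoM
#'   speed), or `"none"` (kg m^2/s).
#' @return n-by-3 matrix of lab-frame angular momentum; attribute
#'   `"normalizer"` records the divisor used.
#' @export
compute_wbam <- function(trial, model = body_model_13seg(), com,
                         body_mass = NULL, height = NULL,
                         normalize = c("mass_height_speed", "none")) {
  normalize <- match.arg(normalize)
  body_mass <- body_mass %||% trial$meta$mass %||% 70
  height <- height %||% trial$meta$height %||% 1.70
  dt <- 1 / trial$rate
  L <- 0
  for (i in seq_len(nrow(model))) {
    prox <- resolve_landmark(trial, model$proximal[i])
    dist <- resolve_landmark(trial, model$distal[i])
    aux <- resolve_landmark(trial, model$aux[i])
    m_i <- model$mass_fraction[i] * body_mass
    r_i <- prox + model$com_ratio[i] * (dist - prox)
    v_i <- finite_diff(r_i, dt)
    rel_r <- r_i - com$position
    rel_v <- v_i - com$velocity
    remote <- m_i * cross3(rel_r, rel_v)
    basis <- segment_basis(prox, dist, aux)
    w <- basis_angular_velocity(basis, dt)
    len <- basis$length
    I1 <- m_i * (model$rg_t1[i] * len)^2
    I2 <- m_i * (model$rg_t2[i] * len)^2
    I3 <- m_i * (model$rg_l[i] * len)^2
    spin <- basis$e1 * (I1 * rowSums(w * basis$e1)) +
      basis$e2 * (I2 * rowSums(w * basis$e2)) +
      basis$e3 * (I3 * rowSums(w * basis$e3))
    L <- L + remote + spin
  }
  normalizer <- switch(normalize,
                       mass_height_speed = body_mass * height *
                         max(mean(vec_norm(com$velocity[, 1:2, drop = FALSE])),
                             0.1),
                       none = 1)
  out <- L / normalizer
  attr(out, "normalizer") <- normalizer
  attr(out, "normalization") <- normalize
  out
}

#' Decompose angular momentum into walking-direction planes
#'
#' Sagittal-plane momentum is the component about the medio-lateral axis,
#' coronal (frontal) about the progression axis, transverse about the
#' vertical — axes tied to the supplied heading.
#'
#' @param wbam n-by-3 lab-frame angular-momentum matrix.
#' @param direction Unit 2-vector (overall heading) or n-by-2 matrix of
#'   per-frame headings.
#' @return n-by-3 matrix with columns `sagittal`, `coronal`, `transverse`.
#' @export
wbam_planes <- function(wbam, direction) {
  n <- nrow(wbam)
  d <- if (is.matrix(direction)) direction
       else matrix(direction, n, 2, byrow = TRUE)
  ap <- cbind(d[, 1], d[, 2], 0)
  ml <- cbind(-d[, 2], d[, 1], 0)
  out <- cbind(sagittal = rowSums(wbam * ml),
               coronal = rowSums(wbam * ap),
               transverse = wbam[, 3])
  out
}
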