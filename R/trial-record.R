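#' Construct a trial record
#'
#' A trial record bundles the named 3-D marker trajectories of one recorded
#' (or generated) walking trial with its sampling rate, task label, optional
#' gait-event table and, for synthetic trials, a ground-truth sidecar.
#' Positions are in metres in the lab frame (X = progression, Y =
#' medio-lateral, Z = vertical).
#'
#' @param subject_id Subject identifier.
#' @param task One of [task_set()].
#' @param markers Named list of n-by-3 numeric matrices (equal n).
#' @param rate Sampling rate in Hz (> 0).
#' @param events Optional gait-event table, see [gait_event_table()].
#' @param ground_truth Optional list carried by synthetic trials.
#' @param meta Optional list of free-form metadata (e.g. body mass, height).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, task, markers, rate,
                         events = NULL, ground_truth = NULL, meta = list()) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (!task %in% task_set())
    stop("unknown task label: ", task)
  if (!length(markers) || is.null(names(markers)))
    stop("markers must be a non-empty named list")
  n <- nrow(markers[[1]])
  for (lab in names(markers)) {
    m <- markers[[lab]]
    if (!is.matrix(m) || ncol(m) != 3L)
      stop("marker ", lab, " is not an n-by-3 matrix")
    if (nrow(m) != n)
      stop("marker series have unequal lengths (", lab, ")")
  }
  x <- structure(list(subject_id = subject_id, task = task,
                      markers = markers, rate = rate,
                      events = events, ground_truth = ground_truth,
                      meta = meta),
                 class = "trial_record")
  if (!is.null(events)) validate_events(events, duration = n / rate)
  x
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s, task %s: %d markers x %d frames @ %g Hz\n",
              x$subject_id, x$task, length(x$markers),
              n_frames(x), x$rate))
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%d strikes)\n", nrow(x$events),
                sum(x$events$kind == "foot_strike")))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial A `trial_record`.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) nrow(trial$markers[[1]])

#' Trial duration in seconds
#' @param trial A `trial_record`.
#' @return Duration (n_frames / rate).
#' @export
trial_duration <- function(trial) n_frames(trial) / trial$rate

#' Time stamps of a trial's frames (seconds from trial start, frame 0 at t = 0)
#' @param trial A `trial_record`.
#' @return Numeric vector of times.
#' @export
trial_times <- function(trial) (seq_len(n_frames(trial)) - 1) / trial$rate

#' Extract one marker trajectory
#' @param trial A `trial_record`.
#' @param label Marker label.
#' @return n-by-3 matrix of positions (m).
#' @export
marker <- function(trial, label) {
  m <- trial$markers[[label]]
  if (is.null(m)) stop("missing marker: ", label)
  m
}

#' Check that required markers are present
#' @param trial A `trial_record`.
#' @param labels Character vector of required labels.
#' @return Invisibly `TRUE`; errors listing absent labels otherwise.
#' @export
require_markers <- function(trial, labels) {
  absent <- setdiff(labels, names(trial$markers))
  if (length(absent))
    stop("missing marker(s): ", paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Construct a gait-event table
#'
#' Ordered foot-strike / foot-off events per side. Within each side times
#' must be strictly increasing and kinds must alternate.
#'
#' @param time Event times in seconds from trial start.
#' @param side `"left"` or `"right"`.
#' @param kind `"foot_strike"` or `"foot_off"`.
#' @return A `data.frame` with class `gait_event_table`, sorted by time.
#' @export
gait_event_table <- function(time = numeric(), side = character(),
                             kind = character()) {
  ev <- data.frame(time = as.numeric(time), side = as.character(side),
                   kind = as.character(kind), stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("gait_event_table", "data.frame")
  validate_events(ev)
  ev
}

validate_events <- function(ev, duration = NULL) {
  stopifnot(all(ev$side %in% c("left", "right")),
            all(ev$kind %in% c("foot_strike", "foot_off")))
  for (s in unique(ev$side)) {
    sub <- ev[ev$side == s, , drop = FALSE]
    if (is.unsorted(sub$time, strictly = TRUE))
      stop("event times not strictly increasing on side ", s)
    if (nrow(sub) > 1 && any(sub$kind[-1] == sub$kind[-nrow(sub)]))
      stop("event kinds do not alternate on side ", s)
  }
  if (!is.null(duration) && nrow(ev) &&
      (min(ev$time) < 0 || max(ev$time) > duration))
    stop("event times outside trial bounds")
  invisible(TRUE)
}

#' Foot-strike times for one side
#' @param events A gait-event table.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of strike times.
#' @export
strike_times <- function(events, side) {
  events$time[events$side == side & events$kind == "foot_strike"]
}
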