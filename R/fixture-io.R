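#' Write a trial to the plain-text fixture format
#'
#' The fixture format is a diffable text serialisation of a trial: a header
#' block (`key: value` lines), an optional `[EVENTS]` CSV block, an optional
#' `[META]` block, and a `[DATA]` block with one CSV row per frame holding
#' x,y,z for every marker in header order. Positions are printed with 12
#' significant digits, so a round trip is stable well below 1e-9 m.
#'
#' @param trial A [trial_record()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fixture <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  labs <- names(trial$markers)
  writeLines(c("#VESTGAIT-TRIAL 1",
               paste0("subject_id: ", trial$subject_id),
               paste0("task: ", trial$task),
               paste0("rate: ", format(trial$rate, digits = 12)),
               paste0("n_frames: ", n_frames(trial)),
               paste0("markers: ", paste(labs, collapse = " "))), con)
  if (length(trial$meta)) {
    writeLines("[META]", con)
    for (k in names(trial$meta))
      writeLines(paste0(k, ": ", format(trial$meta[[k]], digits = 12)), con)
  }
  if (!is.null(trial$events)) {
    writeLines("[EVENTS]", con)
    writeLines("time,side,kind", con)
    ev <- trial$events
    if (nrow(ev))
      writeLines(sprintf("%.9f,%s,%s", ev$time, ev$side, ev$kind), con)
  }
  writeLines("[DATA]", con)
  dat <- do.call(cbind, trial$markers)
  writeLines(apply(dat, 1, function(r)
    paste(formatC(r, digits = 12, format = "g"), collapse = ",")), con)
  invisible(path)
}

#' Read a trial from the plain-text fixture format
#'
#' @param path Fixture file written by [write_fixture()].
#' @return A [trial_record()]. NaN positions (unfilled gaps) are preserved.
#' @export
read_fixture <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#VESTGAIT-TRIAL"))
    stop("not a vestgait trial fixture: ", path)
  hdr <- list()
  i <- 2L
  get_kv <- function(line) {
    p <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    list(key = p[1], value = p[2])
  }
  while (i <= length(lines) && !startsWith(lines[i], "[")) {
    kv <- get_kv(lines[i]); hdr[[kv$key]] <- kv$value; i <- i + 1L
  }
  for (k in c("subject_id", "task", "rate", "n_frames", "markers"))
    if (is.null(hdr[[k]])) stop("fixture header missing field: ", k)
  labs <- strsplit(hdr$markers, " ", fixed = TRUE)[[1]]
  nfr <- as.integer(hdr$n_frames)
  meta <- list(); events <- NULL
  while (i <= length(lines) && lines[i] != "[DATA]") {
    if (lines[i] == "[META]") {
      i <- i + 1L
      while (i <= length(lines) && !startsWith(lines[i], "[")) {
        kv <- get_kv(lines[i])
        v <- suppressWarnings(as.numeric(kv$value))
        meta[[kv$key]] <- if (is.na(v)) kv$value else v
        i <- i + 1L
      }
    } else if (lines[i] == "[EVENTS]") {
      j <- i + 2L
      while (j <= length(lines) && !startsWith(lines[j], "[")) j <- j + 1L
      ev_lines <- lines[(i + 1L):(j - 1L)]
      ev <- utils::read.csv(text = paste(ev_lines, collapse = "\n"),
                            stringsAsFactors = FALSE)
      events <- gait_event_table(ev$time, ev$side, ev$kind)
      i <- j
    } else stop("unrecognised fixture section: ", lines[i])
  }
  if (i > length(lines)) stop("fixture has no [DATA] section")
  dat_lines <- lines[(i + 1L):length(lines)]
  dat_lines <- dat_lines[nzchar(dat_lines)]
  if (length(dat_lines) != nfr)
    stop("fixture data rows (", length(dat_lines),
         ") disagree with n_frames (", nfr, ")")
  dat <- matrix(as.numeric(unlist(strsplit(dat_lines, ",", fixed = TRUE))),
                nrow = nfr, byrow = TRUE)
  if (ncol(dat) != 3L * length(labs)) stop("fixture data width mismatch")
  markers <- stats::setNames(
    lapply(seq_along(labs), function(k) dat[, (3 * k - 2):(3 * k), drop = FALSE]),
    labs)
  trial_record(hdr$subject_id, hdr$task, markers, as.numeric(hdr$rate),
               events = events, meta = meta)
}
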