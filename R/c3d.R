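# Minimal C3D support (Intel processor type, floating-point point data, no
# analog channels): enough to exchange marker trajectories with standard
# motion-capture tooling. The plain-text fixture format remains the
# package's primary serialisation.

#' Read marker trajectories from a C3D file
#'
#' Supports Intel-format C3D files with floating-point 3-D point data and
#' no analog channels. Labels are trimmed; positions are converted to
#' metres when POINT:UNITS is mm; the sampling rate is taken from the file
#' header; invalid points (negative residual) become NaN.
#'
#' @param path C3D file path.
#' @param task Task label to attach (C3D carries none; default
#'   "comfortable").
#' @param subject_id Subject identifier to attach (default the file name).
#' @param required_markers Labels that must be present; a missing-marker
#'   error lists the absent ones.
#' @return A [trial_record()].
#' @export
read_c3d <- function(path, task = "comfortable",
                     subject_id = tools::file_path_sans_ext(basename(path)),
                     required_markers = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 512) stop("not a C3D file (too short): ", path)
  if (as.integer(raw[2]) != 0x50)
    stop("not a C3D file (bad magic byte): ", path)
  u16 <- function(off) as.integer(raw[off + 1]) +
    256L * as.integer(raw[off + 2])
  f32 <- function(off) readBin(raw[(off + 1):(off + 4)], "numeric",
                               size = 4, endian = "little")
  param_block <- as.integer(raw[1])
  n_points <- u16(2)
  n_analog <- u16(4)
  first_frame <- u16(6)
  last_frame <- u16(8)
  scale <- f32(12)
  data_block <- u16(16)
  rate <- f32(20)
  n_frames <- last_frame - first_frame + 1L
  if (scale >= 0)
    stop("integer-scaled C3D data not supported (POINT:SCALE >= 0)")
  if (n_analog > 0)
    stop("C3D files with analog channels are not supported")

  # parameter section: find POINT:LABELS and POINT:UNITS
  poff <- 512L * (param_block - 1L)
  proc <- as.integer(raw[poff + 4])
  if (proc != 84)
    stop("only Intel-processor C3D files are supported (type ", proc - 83, ")")
  labels <- NULL; units <- "mm"
  pos <- poff + 4L
  group_ids <- list()
  repeat {
    if (pos + 2 > length(raw)) break
    nname <- readBin(raw[pos + 1], "integer", size = 1, signed = TRUE)
    id <- readBin(raw[pos + 2], "integer", size = 1, signed = TRUE)
    if (nname == 0 || id == 0 && nname == 0) break
    nch <- abs(nname)
    name <- rawToChar(raw[(pos + 3):(pos + 2 + nch)])
    off_pos <- pos + 2L + nch
    offset <- u16(off_pos)
    if (offset == 0) break
    if (id < 0) {
      group_ids[[as.character(-id)]] <- name
    } else {
      grp <- group_ids[[as.character(id)]] %||% ""
      body <- off_pos + 2L
      type <- readBin(raw[body + 1], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[body + 2])
      dims <- if (ndim > 0)
        as.integer(raw[(body + 3):(body + 2 + ndim)]) else integer()
      dstart <- body + 2L + ndim
      if (grp == "POINT" && name == "LABELS" && type == -1 && ndim == 2) {
        w <- dims[1]; k <- dims[2]
        chars <- rawToChar(raw[(dstart + 1):(dstart + w * k)], multiple = FALSE)
        labels <- trimws(substring(chars, (seq_len(k) - 1) * w + 1,
                                   seq_len(k) * w))
      }
      if (grp == "POINT" && name == "UNITS" && type == -1)
        units <- trimws(rawToChar(raw[(dstart + 1):(dstart + prod(dims))]))
    }
    pos <- off_pos + offset
  }
  if (is.null(labels))
    stop("C3D parameter section lacks POINT:LABELS")
  labels <- labels[seq_len(n_points)]

  doff <- 512L * (data_block - 1L)
  nvals <- n_frames * n_points * 4L
  vals <- readBin(raw[(doff + 1):(doff + 4L * nvals)], "numeric",
                  n = nvals, size = 4, endian = "little")
  arr <- array(vals, dim = c(4, n_points, n_frames))
  conv <- if (tolower(units) == "mm") 0.001 else 1
  markers <- stats::setNames(vector("list", n_points), labels)
  for (j in seq_len(n_points)) {
    m <- t(arr[1:3, j, ]) * conv
    m[arr[4, j, ] < 0, ] <- NaN
    markers[[labels[j]]] <- m
  }
  if (!is.null(required_markers)) {
    absent <- setdiff(required_markers, labels)
    if (length(absent))
      stop("missing marker(s): ", paste(absent, collapse = ", "))
  }
  trial_record(subject_id, task, markers, rate)
}

#' Write a trial to a C3D file
#'
#' Emits an Intel-format, floating-point C3D file (units mm, no analog
#' channels) with POINT:LABELS/USED/SCALE/RATE/FRAMES/UNITS parameters.
#'
#' @param trial A [trial_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_c3d <- function(trial, path) {
  labs <- names(trial$markers)
  np <- length(labs)
  nf <- n_frames(trial)
  width <- max(4L, max(nchar(labs)))
  pad <- function(s) formatC(s, width = -width)

  i8 <- function(x) as.raw(bitwAnd(as.integer(x), 255L))
  u16r <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")
  f32r <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                               endian = "little")
  param_rec <- function(name, id, type, dims, data, group = FALSE) {
    nm <- charToRaw(name)
    body <- if (group) raw() else {
      c(i8(type), i8(length(dims)), i8(dims), data)
    }
    rec <- c(i8(length(nm)), i8(id), nm)
    tail <- c(body, i8(0))                       # zero-length description
    offset <- length(tail) + 2L
    c(rec, u16r(offset), tail)
  }
  params <- c(
    param_rec("POINT", -1, group = TRUE, type = 0, dims = NULL, data = NULL),
    param_rec("USED", 1, 2, 0, u16r(np)),
    param_rec("FRAMES", 1, 2, 0, u16r(nf)),
    param_rec("SCALE", 1, 4, 0, f32r(-1)),
    param_rec("RATE", 1, 4, 0, f32r(trial$rate)),
    param_rec("UNITS", 1, -1, 2, charToRaw(pad("mm"))),
    param_rec("LABELS", 1, -1, c(width, np),
              charToRaw(paste(vapply(labs, pad, ""), collapse = ""))))
  params <- c(params, i8(0), i8(0))              # terminator
  n_param_blocks <- ceiling((4 + length(params)) / 512)
  param_bytes <- c(i8(1), i8(0x50), i8(n_param_blocks), i8(84), params)
  param_bytes <- c(param_bytes,
                   raw(512L * n_param_blocks - length(param_bytes)))
  data_block <- 2L + n_param_blocks

  hdr <- c(i8(2), i8(0x50), u16r(np), u16r(0), u16r(1), u16r(nf),
           u16r(0), f32r(-1), u16r(data_block), u16r(0), f32r(trial$rate))
  hdr <- c(hdr, raw(512L - length(hdr)))

  arr <- array(0, dim = c(4, np, nf))
  for (j in seq_len(np)) {
    m <- trial$markers[[j]] * 1000          # metres -> mm
    bad <- !is.finite(m[, 1]) | !is.finite(m[, 2]) | !is.finite(m[, 3])
    m[bad, ] <- 0
    arr[1:3, j, ] <- t(m)
    arr[4, j, ] <- ifelse(bad, -1, 0)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, param_bytes), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}
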