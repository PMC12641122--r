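# Minimal EDF (European Data Format) I/O for continuous multichannel LFP.
# EDF stores 16-bit integers with per-signal physical/digital calibration in a
# fixed-width ASCII header; this reader/writer covers plain continuous EDF
# (one signal per channel, identical sampling rate, physical unit uV), which
# is all the pipeline needs. No R EDF package is available, so the format is
# handled directly; the writer/reader pair is round-trip tested.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Continuous EDF with one signal per channel, physical dimension uV, and
#' 1-second data records. The recording is truncated to a whole number of
#' seconds (EDF data records are fixed-duration).
#'
#' @param rec an [lfp_recording()]; `fs` must be a whole number.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_edf <- function(rec, file) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf: fs must be an integer number of Hz")
  fs <- as.integer(fs)
  ns <- ncol(rec$data)
  n_rec <- nrow(rec$data) %/% fs
  if (n_rec < 1) stop("write_edf: recording shorter than one data record (1 s)")
  x <- rec$data[seq_len(n_rec * fs), , drop = FALSE]

  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(file, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste("week", rec$age_week, "month", rec$age_month), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  sig <- paste0(
    paste(vapply(colnames(x), edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.8g", pmin), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.8g", pmax), edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      d <- round((x[rows, j] - pmin[j]) / scale[j]) + dmin
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(file)
}

#' Read a continuous EDF file
#'
#' Supports plain EDF with identical per-signal sampling rates (the format
#' written by [write_edf()] and by common acquisition systems for LFP).
#'
#' @param file EDF path.
#' @param channels optional channel metadata (see [lfp_recording()]).
#' @param ... passed to [lfp_recording()].
#' @return an [lfp_recording()].
#' @export
read_edf <- function(file, channels = NULL, ...) {
  con <- file(file, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                              # version
  subject <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)      # transducer
  for (i in seq_len(ns)) rd(8)       # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)      # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) stop("read_edf: per-signal sampling rates differ")
  fs <- spr[1] / rec_dur

  scale <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns,
                dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2,
                   endian = "little", signed = TRUE)
      out[rows, j] <- (d - dmin[j]) * scale[j] + pmin[j]
    }
  }
  lfp_recording(out, fs = fs, channels = channels, subject_id = subject, ...)
}
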