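#' Construct an LFP recording object
#'
#' Container for a multichannel LFP recording: a samples-by-channels voltage
#' matrix (uV), the sampling rate, per-channel region metadata, and subject /
#' session labels. All downstream stages (fE/I, PAC, event detection,
#' vigilance scoring) consume this object.
#'
#' @param data numeric matrix, samples x channels; column names are channel
#'   names (set from `channels$name` if missing).
#' @param fs sampling rate in Hz (> 0).
#' @param channels data.frame with columns `name`, `region`
#'   (`"PFC"`, `"PTC"`, `"HC"`), `hc_layer` (`"supra_pyramidal"`,
#'   `"pyramidal"`, `"infra_pyramidal"`, or `"none"` for non-HC channels)
#'   and `hemisphere` (`"left"`, `"right"`, `"unknown"`). One row per column
#'   of `data`.
#' @param subject_id opaque subject label.
#' @param age_week,age_month session age labels (integers).
#' @return an object of class `lfp_recording` with fields `data`, `fs`,
#'   `channels`, `duration_s`, `subject_id`, `age_week`, `age_month`.
#' @export
lfp_recording <- function(data, fs, channels = NULL, subject_id = "subject",
                          age_week = NA_integer_, age_month = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (fs <= 0) stop("lfp_recording: fs must be positive")
  if (any(!is.finite(data))) stop("lfp_recording: samples must be finite (clean the data first)")
  if (is.null(channels)) {
    nm <- colnames(data)
    if (is.null(nm)) nm <- paste0("ch", seq_len(ncol(data)))
    channels <- data.frame(name = nm, region = "PTC", hc_layer = "none",
                           hemisphere = "unknown", stringsAsFactors = FALSE)
  }
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  need <- c("name", "region", "hc_layer", "hemisphere")
  for (cn in setdiff(need, names(channels))) {
    channels[[cn]] <- if (cn == "hc_layer") "none" else "unknown"
  }
  channels <- channels[, need]
  if (nrow(channels) != ncol(data)) {
    stop("lfp_recording: channels metadata rows (", nrow(channels),
         ") != data columns (", ncol(data), ")")
  }
  bad <- xor(channels$region == "HC", channels$hc_layer != "none")
  if (any(bad)) stop("lfp_recording: hc_layer must be set exactly for HC channels")
  colnames(data) <- channels$name
  structure(
    list(data = data, fs = fs, channels = channels,
         duration_s = nrow(data) / fs, subject_id = subject_id,
         age_week = as.integer(age_week), age_month = as.integer(age_month)),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> subject %s, week %s / month %s\n",
              x$subject_id, x$age_week, x$age_month))
  cat(sprintf("  %d channels x %.1f s @ %g Hz\n",
              ncol(x$data), x$duration_s, x$fs))
  reg <- table(x$channels$region)
  cat("  regions:", paste(names(reg), reg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel's trace
#'
#' @param rec an [lfp_recording()].
#' @param channel channel name or column index.
#' @return numeric vector of samples (uV).
#' @export
channel_data <- function(rec, channel) {
  stopifnot(inherits(rec, "lfp_recording"))
  as.numeric(rec$data[, channel])
}

#' Read a recording from a delimited text file
#'
#' Expects a header row of channel names, a first column `time_s`, and one
#' column per channel in uV. The sampling rate is inferred from the time
#' column unless given.
#'
#' @param file path to a tab- or comma-delimited file.
#' @param fs sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @param channels optional channel metadata (see [lfp_recording()]).
#' @param ... passed to [lfp_recording()] (subject/session labels).
#' @return an [lfp_recording()].
#' @export
read_recording_delim <- function(file, fs = NULL, channels = NULL, ...) {
  df <- utils::read.delim(file, sep = guess_sep(file), check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s")
  if (is.null(fs)) {
    dt <- diff(df$time_s)
    fs <- 1 / stats::median(dt)
  }
  lfp_recording(as.matrix(df[, -1, drop = FALSE]), fs = fs,
                channels = channels, ...)
}

#' Write a recording as a delimited text file
#'
#' @param rec an [lfp_recording()].
#' @param file output path; tab-delimited, first column `time_s`.
#' @export
write_recording_delim <- function(rec, file) {
  stopifnot(inherits(rec, "lfp_recording"))
  t <- (seq_len(nrow(rec$data)) - 1L) / rec$fs
  df <- data.frame(time_s = t, rec$data, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a cohort manifest
#'
#' One row per (recording file, channel): columns `subject_id`, `genotype`,
#' `age_week`, `age_month`, `file`, `channel`, `region`, `hc_layer`,
#' `hemisphere`.
#'
#' @param file delimited manifest path.
#' @return data.frame of manifest rows.
#' @export
read_cohort_manifest <- function(file) {
  df <- utils::read.delim(file, sep = guess_sep(file), stringsAsFactors = FALSE)
  need <- c("subject_id", "genotype", "age_week", "age_month", "file",
            "channel", "region", "hc_layer", "hemisphere")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_cohort_manifest
#' @param manifest manifest data.frame to write.
#' @export
write_cohort_manifest <- function(manifest, file) {
  utils::write.table(manifest, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

guess_sep <- function(file) {
  line <- readLines(file, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}
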