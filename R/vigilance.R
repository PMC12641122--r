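#' Vigilance track: one behavioural state per 5-s epoch
#'
#' Epoch `i` (0-based) covers `[5*i, 5*(i+1))` seconds from recording start.
#' States are `active_wake`, `quiet_wake` and `sleep`.
#'
#' @param states character vector of epoch states.
#' @param epoch_s epoch length in seconds (default 5).
#' @param delta_theta,velocity optional per-epoch delta/theta power ratio and
#'   locomotion velocity (cm/s) used for scoring.
#' @return a data.frame of class `vigilance_track` with columns
#'   `epoch_index` (0-based), `state`, `delta_theta`, `velocity`;
#'   attribute `epoch_s`.
#' @export
vigilance_track <- function(states, epoch_s = 5,
                            delta_theta = NA_real_, velocity = NA_real_) {
  ok <- c("active_wake", "quiet_wake", "sleep")
  if (!all(states %in% ok)) {
    stop("vigilance_track: states must be one of ", paste(ok, collapse = ", "))
  }
  tr <- data.frame(epoch_index = seq_along(states) - 1L, state = states,
                   delta_theta = delta_theta, velocity = velocity,
                   stringsAsFactors = FALSE)
  attr(tr, "epoch_s") <- epoch_s
  class(tr) <- c("vigilance_track", "data.frame")
  tr
}

#' Read / write a vigilance annotation file
#'
#' Delimited file with columns `epoch_index` (0-based) and `state`.
#'
#' @param file annotation path.
#' @return a [vigilance_track()].
#' @export
read_vigilance_annotation <- function(file) {
  df <- utils::read.delim(file, sep = guess_sep(file), stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "state") %in% names(df))) {
    stop("annotation needs columns epoch_index, state")
  }
  df <- df[order(df$epoch_index), ]
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    stop("annotation epochs must be consecutive from 0")
  }
  vigilance_track(df$state)
}

#' @rdname read_vigilance_annotation
#' @param track a [vigilance_track()] to write.
#' @export
write_vigilance_annotation <- function(track, file) {
  utils::write.table(track[, c("epoch_index", "state")], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Delta/theta power ratio per epoch
#'
#' Band power is measured as the mean squared amplitude envelope of the
#' zero-phase filtered trace (delta 1-4 Hz over theta 4-10 Hz), computed on
#' the whole trace once and then averaged per epoch.
#'
#' @param x numeric vector, one channel's trace (uV).
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch length in seconds (default 5).
#' @param delta,theta band edges in Hz.
#' @return numeric vector, one ratio per complete epoch.
#' @export
delta_theta_ratio <- function(x, fs, epoch_s = 5,
                              delta = c(1, 4), theta = c(4, 10)) {
  n_ep <- floor(length(x) / (epoch_s * fs))
  if (n_ep < 1) stop("delta_theta_ratio: trace shorter than one epoch")
  pd <- amplitude_envelope(bandpass(x, fs, delta[1], delta[2]))^2
  pt <- amplitude_envelope(bandpass(x, fs, theta[1], theta[2]))^2
  ep <- rep(seq_len(n_ep), each = epoch_s * fs)
  idx <- seq_along(ep)
  as.numeric(tapply(pd[idx], ep, mean) / tapply(pt[idx], ep, mean))
}

#' Score vigilance states from delta/theta ratio and velocity
#'
#' Per-epoch rule: velocity above `v_hi` is active wake; otherwise a
#' delta/theta ratio at or above `r_sleep` is sleep, below it quiet wake.
#' The thresholds are configurable stand-ins; synthetic cohorts carry
#' ground-truth states so downstream analyses need not rely on them.
#'
#' @param ratios per-epoch delta/theta ratios (see [delta_theta_ratio()]).
#' @param velocity per-epoch velocity in cm/s.
#' @param v_hi active-wake velocity threshold (cm/s, default 1).
#' @param r_sleep sleep delta/theta threshold (default 1.5).
#' @param epoch_s epoch length in seconds.
#' @return a [vigilance_track()].
#' @export
score_epochs <- function(ratios, velocity, v_hi = 1, r_sleep = 1.5,
                         epoch_s = 5) {
  if (length(ratios) != length(velocity)) {
    stop("score_epochs: ratios and velocity must have equal length")
  }
  states <- ifelse(velocity > v_hi, "active_wake",
                   ifelse(ratios >= r_sleep, "sleep", "quiet_wake"))
  vigilance_track(states, epoch_s = epoch_s,
                  delta_theta = ratios, velocity = velocity)
}

#' Read / write a per-epoch velocity trace
#'
#' Delimited file with columns `epoch_index` and `cm_s`.
#' @param file path.
#' @return numeric vector of velocities.
#' @export
read_velocity <- function(file) {
  df <- utils::read.delim(file, sep = guess_sep(file))
  df$cm_s[order(df$epoch_index)]
}

#' @rdname read_velocity
#' @param velocity numeric vector of per-epoch velocities (cm/s).
#' @export
write_velocity <- function(velocity, file) {
  utils::write.table(
    data.frame(epoch_index = seq_along(velocity) - 1L, cm_s = velocity),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
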