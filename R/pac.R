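#' Kullback-Leibler modulation index
#'
#' Quantifies phase-amplitude coupling: the phase series is binned into
#' `n_bins` equal bins of `[-pi, pi)` (18 bins of 20 degrees by default), the
#' mean amplitude per bin is normalized to a distribution `P`, and the
#' Kullback-Leibler distance of `P` from uniform, `KL = log(N) + sum P log P`
#' (natural log; `0 log 0 := 0`), is normalized by `log(N)`. MI is 0 for
#' amplitude independent of phase and 1 when all amplitude mass falls in one
#' bin.
#'
#' @param phase numeric vector of phases in radians (`[-pi, pi)`).
#' @param amplitude nonnegative numeric vector, same length.
#' @param n_bins number of phase bins (default 18).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) {
    stop("modulation_index: phase and amplitude lengths differ")
  }
  bins <- phase_bin(phase, n_bins)
  if (length(unique(bins)) < n_bins) {
    stop("modulation_index: empty phase bin (duration too short for this phase frequency)")
  }
  m <- as.numeric(tapply(amplitude, factor(bins, levels = seq_len(n_bins)), mean))
  P <- m / sum(m)
  pl <- ifelse(P > 0, P * log(P), 0)
  (log(n_bins) + sum(pl)) / log(n_bins)
}

# Half-open phase bins starting at -pi: bin j covers [-pi + (j-1)*w, -pi + j*w).
phase_bin <- function(phase, n_bins) {
  w <- 2 * pi / n_bins
  j <- floor((phase + pi) / w) + 1L
  j[j > n_bins] <- n_bins   # phase == pi maps into the last bin
  j[j < 1L] <- 1L
  j
}

#' Phase and amplitude frequency grids for comodulograms
#'
#' Printed grid ranges are centre frequencies; each band is centre +/- half
#' the bandwidth. Phase: 2-14 Hz centres in 1-Hz steps with 2-Hz bandwidth.
#' Amplitude: cortical channels 40-200 Hz centres in 1-Hz steps with 2-Hz
#' bandwidth; hippocampal channels 40-300 Hz centres in 2-Hz steps with 4-Hz
#' bandwidth.
#'
#' @param region `"cortical"` or `"hippocampal"`.
#' @param fs sampling rate in Hz; amplitude bands reaching Nyquist are
#'   truncated with a warning.
#' @param phase_step,amp_step optional coarser grid steps (Hz) for faster
#'   exploratory runs; centre sets are thinned, bandwidths unchanged.
#' @return list with data.frames `phase` and `amp`, each with columns
#'   `center`, `lo`, `hi`.
#' @export
pac_grids <- function(region = c("cortical", "hippocampal"), fs = 1000,
                      phase_step = 1, amp_step = NULL) {
  region <- match.arg(region)
  ph_c <- seq(2, 14, by = phase_step); ph_bw <- 2
  if (region == "cortical") {
    am_c <- seq(40, 200, by = if (is.null(amp_step)) 1 else amp_step); am_bw <- 2
  } else {
    am_c <- seq(40, 300, by = if (is.null(amp_step)) 2 else amp_step); am_bw <- 4
  }
  keep <- am_c + am_bw / 2 < fs / 2
  if (!all(keep)) {
    warning("pac_grids: ", sum(!keep),
            " amplitude bands above Nyquist truncated (fs = ", fs, " Hz)")
    am_c <- am_c[keep]
  }
  list(phase = data.frame(center = ph_c, lo = ph_c - ph_bw / 2,
                          hi = ph_c + ph_bw / 2),
       amp = data.frame(center = am_c, lo = am_c - am_bw / 2,
                        hi = am_c + am_bw / 2))
}

#' Phase-amplitude comodulogram
#'
#' For every (phase band, amplitude band) pair on the grids, the signal is
#' zero-phase band-pass filtered, the Hilbert phase (phase band) and Hilbert
#' amplitude (amplitude band) are extracted, and the modulation index is
#' computed. Signal segments (vigilance-state intervals) are filtered
#' individually and their phase/amplitude samples pooled.
#'
#' @param x numeric vector or list of vectors (per-interval segments).
#' @param fs sampling rate in Hz.
#' @param grids a [pac_grids()] list (or equivalent).
#' @param n_bins phase bins for the MI (default 18).
#' @return object of class `comodulogram`: list with `phase_centers`,
#'   `amp_centers`, `mi` (phase x amplitude matrix), `minutes_used`.
#' @export
comodulogram <- function(x, fs, grids = pac_grids("cortical", fs),
                         n_bins = 18) {
  segs <- if (is.list(x)) x else list(x)
  np <- nrow(grids$phase); na <- nrow(grids$amp)
  all_bands <- rbind(grids$phase[, c("lo", "hi")], grids$amp[, c("lo", "hi")])
  # phase and amplitude samples must stay time-aligned, so every band of a
  # segment is trimmed by the same margin (the largest edge trim in play)
  k_common <- max(edge_trim_samples(all_bands$lo[all_bands$lo > 0], fs))
  phases <- rep(list(numeric(0)), np)
  amps <- rep(list(numeric(0)), na)
  used <- 0
  for (s in segs) {
    n <- length(s)
    if (n <= 2L * k_common + 2L) next
    # phase bands use the selective filter design; amplitude bands use the
    # loose cycle-rule design so the modulation sidebands (centre +/-
    # f_phase) pass into the measured envelope
    an_p <- band_analytic(s, fs, grids$phase, trim = FALSE)
    an_a <- band_analytic(s, fs, grids$amp, trim = FALSE, sharp = FALSE)
    idx <- (k_common + 1L):(n - k_common)
    for (i in seq_len(np)) {
      if (!is.null(an_p[[i]])) phases[[i]] <- c(phases[[i]], Arg(an_p[[i]][idx]))
    }
    for (j in seq_len(na)) {
      if (!is.null(an_a[[j]])) amps[[j]] <- c(amps[[j]], Mod(an_a[[j]][idx]))
    }
    used <- used + n
  }
  mi <- matrix(NA_real_, nrow = np, ncol = na,
               dimnames = list(grids$phase$center, grids$amp$center))
  for (i in seq_len(np)) {
    for (j in seq_len(na)) {
      if (length(phases[[i]]) && length(phases[[i]]) == length(amps[[j]])) {
        mi[i, j] <- modulation_index(phases[[i]], amps[[j]], n_bins)
      }
    }
  }
  structure(list(phase_centers = grids$phase$center,
                 amp_centers = grids$amp$center, mi = mi,
                 minutes_used = used / fs / 60),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d phase x %d amplitude bands, %.1f min used; max MI = %.4f\n",
              length(x$phase_centers), length(x$amp_centers),
              x$minutes_used, max(x$mi, na.rm = TRUE)))
  invisible(x)
}

#' Band-averaged PAC summaries
#'
#' Arithmetic mean of comodulogram cells whose phase centre lies in the
#' theta range and amplitude centre in the gamma range (bounds inclusive).
#' Standard summaries: theta (4-10 Hz) x low gamma (40-90 Hz), theta x high
#' gamma (90-160 Hz), and - for hippocampal channels only - theta x total
#' gamma (40-300 Hz).
#'
#' @param com a [comodulogram()].
#' @param theta phase range in Hz (default `c(4, 10)`).
#' @param gamma amplitude range in Hz.
#' @return mean MI over the selected cells.
#' @export
pac_band_average <- function(com, theta = c(4, 10), gamma = c(40, 90)) {
  pi_ <- com$phase_centers >= theta[1] & com$phase_centers <= theta[2]
  ai <- com$amp_centers >= gamma[1] & com$amp_centers <= gamma[2]
  if (!any(pi_) || !any(ai)) stop("pac_band_average: empty range selection")
  mean(com$mi[pi_, ai, drop = FALSE], na.rm = TRUE)
}

#' PAC summary for one comodulogram
#'
#' @param com a [comodulogram()].
#' @param region `"cortical"` (low/high gamma only) or `"hippocampal"`
#'   (adds the theta x total-gamma summary).
#' @return named list: `theta_low_gamma`, `theta_high_gamma`, and for
#'   hippocampal channels `theta_total_gamma`.
#' @export
pac_summary <- function(com, region = c("cortical", "hippocampal")) {
  region <- match.arg(region)
  out <- list(
    theta_low_gamma = pac_band_average(com, c(4, 10), c(40, 90)),
    theta_high_gamma = tryCatch(pac_band_average(com, c(4, 10), c(90, 160)),
                                error = function(e) NA_real_))
  if (region == "hippocampal") {
    out$theta_total_gamma <- tryCatch(
      pac_band_average(com, c(4, 10), c(40, 300)), error = function(e) NA_real_)
  }
  out
}

#' Monthly PAC from weekly recordings
#'
#' Concatenates a month's weekly active-wake intervals in chronological
#' order, truncates the pooled signal to `target_minutes` (default 10), and
#' computes one comodulogram plus summaries per channel. A shortfall (less
#' than the target) is flagged, not dropped.
#'
#' @param recordings list of [lfp_recording()]s for one subject-month, in
#'   chronological order.
#' @param tracks list of matching [vigilance_track()]s.
#' @param channel channel name.
#' @param grids a [pac_grids()] list.
#' @param target_minutes minutes of active wake to use (default 10).
#' @param state vigilance state (default `"active_wake"`).
#' @return list with `comodulogram`, `summary`, `minutes_used`,
#'   `shortfall` (logical), or `NULL` when no active-wake data exist.
#' @export
monthly_pac <- function(recordings, tracks, channel,
                        grids = pac_grids("cortical", recordings[[1]]$fs),
                        target_minutes = 10, state = "active_wake") {
  segs <- list()
  fs <- recordings[[1]]$fs
  region <- NULL
  for (k in seq_along(recordings)) {
    rec <- recordings[[k]]
    ci <- match(channel, rec$channels$name)
    if (is.na(ci)) next
    if (is.null(region)) {
      region <- if (rec$channels$region[ci] == "HC") "hippocampal" else "cortical"
    }
    cc <- concatenate_state(rec, tracks[[k]], state, min_total_s = 0)
    for (seg in cc$segments) segs[[length(segs) + 1L]] <- seg[, ci]
  }
  if (!length(segs)) return(NULL)
  target_n <- round(target_minutes * 60 * fs)
  used <- 0L; kept <- list()
  for (s in segs) {
    if (used >= target_n) break
    take <- min(length(s), target_n - used)
    kept[[length(kept) + 1L]] <- s[seq_len(take)]
    used <- used + take
  }
  com <- comodulogram(kept, fs, grids)
  list(comodulogram = com,
       summary = pac_summary(com, region),
       minutes_used = com$minutes_used,
       shortfall = com$minutes_used < target_minutes - 1e-9)
}
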