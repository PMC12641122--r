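#' Nonlinear energy operator
#'
#' `psi[n] = x[n]^2 - x[n-k]*x[n+k]`; the `k` end samples are padded with 0.
#' With the canonical lag `k = 1` the NEO responds to transients with both
#' high amplitude and high frequency content; the lagged (multiresolution)
#' form tunes the operator's frequency response to slower transients —
#' `psi_k` of a tone at frequency `f` is `A^2 sin^2(2 pi f k / fs)`, so a
#' lag near a quarter period maximizes the response.
#'
#' @param x numeric vector (length >= 2k + 1).
#' @param lag operator lag `k` in samples (default 1, the classic NEO).
#' @return numeric vector, same length.
#' @export
neo <- function(x, lag = 1L) {
  n <- length(x); k <- as.integer(lag)
  if (n < 2L * k + 1L) stop("neo: need at least 2*lag + 1 samples")
  psi <- numeric(n)
  idx <- (k + 1L):(n - k)
  psi[idx] <- x[idx]^2 - x[idx - k] * x[idx + k]
  psi
}

# Bartlett (triangular) smoothing of the NEO output, window in seconds.
neo_smooth <- function(psi, fs, smooth_s = 0.008) {
  w <- signal::bartlett(max(3L, round(smooth_s * fs)))
  w <- w / sum(w)
  m <- (length(w) - 1L) %/% 2L
  n <- length(psi)
  xp <- c(rep(psi[1], m), psi, rep(psi[n], m + 1L))
  y <- fft_conv(xp, w)
  y[(2L * m + 1L):(2L * m + n)]
}

#' NEO spike-candidate detection with automatic thresholding
#'
#' The trace is band-pass filtered (default 5-200 Hz, capped below Nyquist),
#' its smoothed NEO is thresholded at `k_thresh` times its robust mean
#' (top percentile excluded, so sparse large events cannot inflate the
#' threshold; classic automatic-NEO practice otherwise), supra-threshold
#' runs closer than the refractory
#' gap are merged, and each run becomes one candidate at its NEO peak.
#' Polarity, width (duration above half the peak magnitude) and amplitude in
#' robust-SD units (1.4826 * MAD of the filtered trace excluding candidate
#' windows) are measured on the band-passed trace.
#'
#' @param x numeric vector, one channel (uV).
#' @param fs sampling rate in Hz.
#' @param k_thresh threshold multiplier on the mean smoothed NEO (default 8).
#' @param detect_band band for detection filtering in Hz (default 5-200).
#' @param refractory_s merge gap between runs in seconds (default 0.03).
#' @param smooth_s Bartlett smoothing window in seconds (default 0.008).
#' @param neo_lag_s NEO lag in seconds (default 0.01, matching the
#'   tens-of-ms transients of LFP interictal spikes).
#' @param min_amplitude_sd minimum candidate amplitude in robust-SD units
#'   (default 5). The NEO stage proposes transients with high recall; for
#'   the slow (tens of ms) transients typical of LFP interictal spikes its
#'   energy overlaps the colored-noise background, so candidates below this
#'   amplitude are discarded, mirroring the amplitude-referenced definitions
#'   of the downstream event classes.
#' @return data.frame of candidates: `time_s`, `polarity`, `width_ms`,
#'   `amplitude`, `amplitude_sd`, `type = "candidate"`.
#' @export
neo_detect <- function(x, fs, k_thresh = 8, detect_band = c(5, 200),
                       refractory_s = 0.03, smooth_s = 0.008,
                       neo_lag_s = 0.01, min_amplitude_sd = 5) {
  hi <- min(detect_band[2], 0.45 * fs)
  xf <- bandpass(x, fs, detect_band[1], hi)
  psi <- neo_smooth(neo(xf, lag = max(1L, round(neo_lag_s * fs))), fs, smooth_s)
  # automatic threshold on a robust mean: the top percentile is excluded so
  # that large events (SWD trains, giant spikes) do not inflate the
  # threshold and mask weaker transients in the same recording
  thr <- k_thresh * mean(psi[psi <= stats::quantile(psi, 0.99)])
  empty <- data.frame(time_s = numeric(0), polarity = character(0),
                      width_ms = numeric(0), amplitude = numeric(0),
                      amplitude_sd = numeric(0), type = character(0))
  if (thr <= 0 || !any(psi > thr)) return(empty)
  above <- psi > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by less than the refractory gap
  gap <- round(refractory_s * fs)
  if (nrow(runs) > 1L) {
    keep_start <- runs$start; keep_end <- runs$end
    merged <- list(); cur <- c(keep_start[1], keep_end[1])
    for (i in 2:nrow(runs)) {
      if (keep_start[i] - cur[2] <= gap) cur[2] <- keep_end[i]
      else { merged[[length(merged) + 1L]] <- cur; cur <- c(keep_start[i], keep_end[i]) }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- as.data.frame(do.call(rbind, merged))
    names(runs) <- c("start", "end")
  }
  half_w <- round(0.05 * fs)   # +/-50 ms characterization window
  peaks <- integer(nrow(runs)); pol <- character(nrow(runs))
  amp <- numeric(nrow(runs)); width <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs$start[i]:runs$end[i]
    pk <- seg[which.max(psi[seg])]
    lo_i <- max(1L, pk - half_w); hi_i <- min(length(xf), pk + half_w)
    win <- xf[lo_i:hi_i]
    ex <- which.max(abs(win))
    a <- win[ex]
    pol[i] <- if (a < 0) "negative" else "positive"
    amp[i] <- a
    peaks[i] <- lo_i + ex - 1L
    # width: contiguous time around the extremum with |x| >= |a|/2
    h <- abs(a) / 2
    l <- ex; while (l > 1L && abs(win[l - 1L]) >= h) l <- l - 1L
    rr <- ex; while (rr < length(win) && abs(win[rr + 1L]) >= h) rr <- rr + 1L
    width[i] <- (rr - l + 1L) / fs * 1000
  }
  # robust baseline SD excluding candidate windows
  mask <- rep(TRUE, length(xf))
  for (p in peaks) {
    mask[max(1L, p - half_w):min(length(xf), p + half_w)] <- FALSE
  }
  base <- if (sum(mask) > 100L) xf[mask] else xf
  rsd <- 1.4826 * stats::mad(base, constant = 1)
  if (rsd <= 0) rsd <- stats::sd(base)
  out <- data.frame(time_s = (peaks - 1L) / fs, polarity = pol,
                    width_ms = width, amplitude = amp,
                    amplitude_sd = abs(amp) / rsd,
                    type = "candidate", stringsAsFactors = FALSE)
  # adjacent runs can converge on the same waveform extremum; keep one
  out <- out[!duplicated(peaks), , drop = FALSE]
  out[out$amplitude_sd >= min_amplitude_sd, , drop = FALSE]
}

#' Spike-wave discharge detection on a prefrontal channel
#'
#' Candidate cycle peaks (sharp negative local minima of the 1-80 Hz trace
#' exceeding `min_amplitude_sd` robust SDs) are grouped into runs whose
#' inter-peak intervals sustain at least `min_rate_hz`; runs with at
#' least `min_cycles` cycles, duration at least `min_duration_s` and
#' peak-to-peak amplitude more than `p2p_factor` times background are
#' accepted, and accepted episodes separated by less than
#' `merge_gap_s` are merged. Episode duration counts one full cycle period
#' beyond the first-to-last peak span, so an 8-cycle train at 7 Hz lasts
#' 8/7 s. Background is the median 1-s-window peak-to-peak amplitude over
#' the surrounding 60 s, excluding detected events.
#'
#' @param x numeric vector, a PFC channel (uV).
#' @param fs sampling rate in Hz.
#' @param min_cycles minimum spike-wave cycles (default 3).
#' @param min_rate_hz minimum discharge frequency (default 6).
#' @param min_duration_s minimum episode duration (default 1).
#' @param p2p_factor peak-to-peak threshold vs background (default 2).
#' @param merge_gap_s inter-episode merge gap (default 1).
#' @param min_amplitude_sd minimum cycle-peak depth in robust-SD units of
#'   the 1-80 Hz trace (default 3; permissive, the episode rules carry the
#'   specificity).
#' @param min_sep_s minimum separation between cycle peaks in seconds
#'   (default 0.06, just under the period of the fastest plausible
#'   discharge).
#' @return data.frame of episodes: `start_s`, `end_s`, `n_cycles`,
#'   `rate_hz`, `peak_to_peak_ratio`, plus attribute `member_times_s`
#'   (list of per-episode member spike times).
#' @export
detect_swd <- function(x, fs, min_cycles = 3, min_rate_hz = 6,
                       min_duration_s = 1, p2p_factor = 2, merge_gap_s = 1,
                       min_amplitude_sd = 3, min_sep_s = 0.06) {
  hi <- min(80, 0.45 * fs)
  xf <- bandpass(x, fs, 1, hi)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_cycles = integer(0), rate_hz = numeric(0),
                      peak_to_peak_ratio = numeric(0))
  attr(empty, "member_times_s") <- list()
  # cycle-peak candidates: sharp negative local minima of the 1-80 Hz trace
  rsd <- 1.4826 * stats::mad(xf, constant = 1)
  if (rsd <= 0) return(empty)
  nn <- length(xf)
  deep <- which(xf < -min_amplitude_sd * rsd)
  deep <- deep[deep > 1L & deep < nn]
  deep <- deep[xf[deep] <= xf[deep - 1L] & xf[deep] <= xf[deep + 1L]]
  if (length(deep) < min_cycles) return(empty)
  # enforce minimum separation, keeping the deeper peak
  keep <- integer(0); last <- -Inf
  for (i in deep) {
    if ((i - last) / fs >= min_sep_s) { keep <- c(keep, i); last <- i }
    else if (xf[i] < xf[keep[length(keep)]]) { keep[length(keep)] <- i; last <- i }
  }
  if (length(keep) < min_cycles) return(empty)
  t <- (keep - 1L) / fs
  dt_max <- 1 / min_rate_hz
  grp <- cumsum(c(1, diff(t) > dt_max))
  runs <- split(t, grp)

  # background: median 1-s peak-to-peak excluding candidate neighborhoods
  mask <- rep(TRUE, length(xf))
  for (tt in t) {
    i0 <- max(1L, round((tt - 0.25) * fs)); i1 <- min(length(xf), round((tt + 0.25) * fs))
    mask[i0:i1] <- FALSE
  }
  wlen <- round(fs)
  nwin <- floor(length(xf) / wlen)
  p2p_bg <- vapply(seq_len(nwin), function(w) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    idx <- idx[mask[idx]]
    if (length(idx) < wlen / 2) return(NA_real_)
    diff(range(xf[idx]))
  }, 0)
  bg <- stats::median(p2p_bg, na.rm = TRUE)
  if (!is.finite(bg) || bg <= 0) bg <- stats::median(abs(xf)) * 4

  eps <- list()
  for (rn in runs) {
    n <- length(rn)
    if (n < min_cycles) next
    period <- mean(diff(rn))
    dur <- (rn[n] - rn[1]) + period
    rate <- n / dur
    if (dur < min_duration_s || rate < min_rate_hz) next
    i0 <- max(1L, round(rn[1] * fs)); i1 <- min(length(xf), round((rn[n] + period) * fs))
    p2p <- diff(range(xf[i0:i1]))
    if (p2p <= p2p_factor * bg) next
    eps[[length(eps) + 1L]] <- list(start_s = rn[1], end_s = rn[1] + dur,
                                    n_cycles = n, rate_hz = rate,
                                    peak_to_peak_ratio = p2p / bg,
                                    members = rn)
  }
  if (!length(eps)) return(empty)
  # merge episodes separated by less than merge_gap_s
  merged <- list(eps[[1]])
  if (length(eps) > 1L) {
    for (i in 2:length(eps)) {
      last <- merged[[length(merged)]]
      if (eps[[i]]$start_s - last$end_s < merge_gap_s) {
        mem <- c(last$members, eps[[i]]$members)
        dur <- eps[[i]]$end_s - last$start_s
        merged[[length(merged)]] <- list(
          start_s = last$start_s, end_s = eps[[i]]$end_s,
          n_cycles = length(mem), rate_hz = length(mem) / dur,
          peak_to_peak_ratio = max(last$peak_to_peak_ratio,
                                   eps[[i]]$peak_to_peak_ratio),
          members = mem)
      } else merged[[length(merged) + 1L]] <- eps[[i]]
    }
  }
  out <- do.call(rbind, lapply(merged, function(e) {
    data.frame(start_s = e$start_s, end_s = e$end_s, n_cycles = e$n_cycles,
               rate_hz = e$rate_hz, peak_to_peak_ratio = e$peak_to_peak_ratio)
  }))
  attr(out, "member_times_s") <- lapply(merged, function(e) e$members)
  out
}

#' Classify giant spikes across channels
#'
#' A candidate time is a giant spike iff a candidate exists on *every*
#' channel within the simultaneity tolerance, its amplitude exceeds
#' `sd_thresh` robust SDs on at least one hippocampal channel, and the mean
#' of the raw trace over `(t, t + ahp_s]` (the after-hyperpolarization,
#' a sustained positive deflection) is positive on all channels.
#'
#' @param candidates named list of candidate data.frames (one per channel,
#'   from [neo_detect()]).
#' @param rec the parent [lfp_recording()] (raw traces for the AHP test).
#' @param tol_s simultaneity tolerance in seconds (default 0.01).
#' @param sd_thresh amplitude threshold in SD units (default 10).
#' @param ahp_s after-hyperpolarization window in seconds (default 0.2).
#' @return data.frame of giant events (`time_s`, `channel`, `polarity`,
#'   `width_ms`, `amplitude_sd`, `type = "giant"`) plus attribute
#'   `member_index`: list mapping channel name -> candidate row indices
#'   consumed by giants.
#' @export
classify_giant <- function(candidates, rec, tol_s = 0.01, sd_thresh = 10,
                           ahp_s = 0.2) {
  chans <- names(candidates)
  hc <- rec$channels$name[rec$channels$region == "HC"]
  empty <- data.frame(time_s = numeric(0), channel = character(0),
                      polarity = character(0), width_ms = numeric(0),
                      amplitude_sd = numeric(0), type = character(0))
  attr(empty, "member_index") <- lapply(candidates, function(d) integer(0))
  if (length(chans) < 2L || !length(intersect(hc, chans))) return(empty)
  ref <- candidates[[1]]
  if (!nrow(ref)) return(empty)
  consumed <- lapply(candidates, function(d) integer(0))
  out <- list()
  last_t <- -Inf
  for (i in seq_len(nrow(ref))) {
    t0 <- ref$time_s[i]
    # adjacent reference candidates can describe the same physical event
    if (t0 - last_t <= 2 * tol_s) next
    match_idx <- vapply(chans, function(ch) {
      d <- candidates[[ch]]
      if (!nrow(d)) return(NA_integer_)
      j <- which.min(abs(d$time_s - t0))
      if (abs(d$time_s[j] - t0) <= tol_s) j else NA_integer_
    }, 0L)
    if (any(is.na(match_idx))) next
    amps <- vapply(seq_along(chans), function(k) {
      candidates[[chans[k]]]$amplitude_sd[match_idx[k]]
    }, 0)
    hc_k <- which(chans %in% hc)
    if (!any(amps[hc_k] > sd_thresh)) next
    # AHP: positive mean over (t, t + ahp_s] on all channels (raw trace)
    i0 <- round(t0 * rec$fs) + 2L
    i1 <- min(nrow(rec$data), round((t0 + ahp_s) * rec$fs) + 1L)
    if (i1 <= i0) next
    tails <- colMeans(rec$data[i0:i1, chans, drop = FALSE])
    if (!all(tails > 0)) next
    best <- hc_k[which.max(amps[hc_k])]
    d <- candidates[[chans[best]]][match_idx[best], ]
    out[[length(out) + 1L]] <- data.frame(
      time_s = t0, channel = chans[best], polarity = d$polarity,
      width_ms = d$width_ms, amplitude_sd = d$amplitude_sd, type = "giant",
      stringsAsFactors = FALSE)
    for (k in seq_along(chans)) {
      consumed[[chans[k]]] <- c(consumed[[chans[k]]], match_idx[k])
    }
    last_t <- t0
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "member_index") <- consumed
  res
}

#' Classify isolated hippocampal / cortical spikes
#'
#' A hippocampal candidate is an isolated HC spike iff it is brief
#' (width < 100 ms), negative-going, and has no corresponding candidate on a
#' contralateral HC channel within +/-100 ms; the same rule applied to PTC
#' channels yields isolated cortical spikes. When no contralateral channel
#' exists the pairing rule passes vacuously (flagged via the
#' `pairing_caveat` attribute).
#'
#' @param candidates named list of remaining candidate data.frames (giants
#'   and SWD members already removed).
#' @param channels channel metadata (see [lfp_recording()]).
#' @param max_width_ms width criterion in ms (default 100).
#' @param pair_window_s contralateral pairing window in seconds
#'   (default 0.1).
#' @return data.frame of isolated events (`time_s`, `channel`, `polarity`,
#'   `width_ms`, `amplitude_sd`, `type` in `isolated_hc` / `isolated_ctx`).
#' @export
classify_isolated <- function(candidates, channels, max_width_ms = 100,
                              pair_window_s = 0.1) {
  out <- list(); caveat <- character(0)
  for (region in c("HC", "PTC")) {
    type <- if (region == "HC") "isolated_hc" else "isolated_ctx"
    reg_ch <- channels[channels$region == region, , drop = FALSE]
    for (ci in seq_len(nrow(reg_ch))) {
      ch <- reg_ch$name[ci]
      d <- candidates[[ch]]
      if (is.null(d) || !nrow(d)) next
      contra <- reg_ch$name[reg_ch$hemisphere != reg_ch$hemisphere[ci] &
                              reg_ch$hemisphere != "unknown" &
                              reg_ch$name != ch]
      if (!length(contra)) caveat <- union(caveat, ch)
      contra_t <- unlist(lapply(contra, function(cc) {
        dd <- candidates[[cc]]
        if (is.null(dd)) numeric(0) else dd$time_s
      }))
      keep <- d$width_ms < max_width_ms & d$polarity == "negative"
      if (length(contra_t)) {
        paired <- vapply(d$time_s, function(tt) {
          any(abs(contra_t - tt) <= pair_window_s)
        }, TRUE)
        keep <- keep & !paired
      }
      if (any(keep)) {
        dd <- d[keep, c("time_s", "polarity", "width_ms", "amplitude_sd")]
        dd$channel <- ch; dd$type <- type
        out[[length(out) + 1L]] <- dd
      }
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)[, c("time_s", "channel", "polarity", "width_ms",
                            "amplitude_sd", "type")]
  } else {
    data.frame(time_s = numeric(0), channel = character(0),
               polarity = character(0), width_ms = numeric(0),
               amplitude_sd = numeric(0), type = character(0))
  }
  attr(res, "pairing_caveat") <- caveat
  res
}

#' Full epileptiform event detection for one recording
#'
#' Runs candidate detection on every channel, extracts giant spikes (removed
#' from the candidate pool), detects SWD episodes on PFC channels (their
#' member spikes typed `swd_member`), and classifies the remaining HC/PTC
#' candidates as isolated spikes. Detection is vigilance-agnostic: the whole
#' recording is used.
#'
#' @param rec an [lfp_recording()].
#' @param k_thresh NEO threshold multiplier (default 8).
#' @param ... further arguments to [neo_detect()].
#' @return object of class `event_catalog`: list with `events` (typed,
#'   time-sorted data.frame), `episodes` (SWD data.frame),
#'   `recording_duration_s`, and `candidates` (per-channel raw candidates).
#' @export
detect_events <- function(rec, k_thresh = 8, ...) {
  stopifnot(inherits(rec, "lfp_recording"))
  chans <- rec$channels$name
  candidates <- lapply(chans, function(ch) {
    neo_detect(channel_data(rec, ch), rec$fs, k_thresh = k_thresh, ...)
  })
  names(candidates) <- chans

  giants <- classify_giant(candidates, rec)
  consumed <- attr(giants, "member_index")
  pool <- candidates
  for (ch in names(consumed)) {
    if (length(consumed[[ch]])) pool[[ch]] <- pool[[ch]][-consumed[[ch]], , drop = FALSE]
  }

  pfc <- rec$channels$name[rec$channels$region == "PFC"]
  episodes <- NULL; swd_members <- list()
  for (ch in pfc) {
    ep <- detect_swd(channel_data(rec, ch), rec$fs)
    if (nrow(ep)) {
      ep$channel <- ch
      episodes <- rbind(episodes, ep)
      mt <- unlist(attr(ep, "member_times_s"))
      if (length(mt)) {
        swd_members[[ch]] <- data.frame(
          time_s = mt, channel = ch, polarity = "negative",
          width_ms = NA_real_, amplitude_sd = NA_real_, type = "swd_member",
          stringsAsFactors = FALSE)
      }
      # drop pool candidates inside SWD episodes on that channel
      if (!is.null(pool[[ch]]) && nrow(pool[[ch]])) {
        inside <- vapply(pool[[ch]]$time_s, function(tt) {
          any(tt >= ep$start_s - 0.1 & tt <= ep$end_s + 0.1)
        }, TRUE)
        pool[[ch]] <- pool[[ch]][!inside, , drop = FALSE]
      }
    }
  }
  if (is.null(episodes)) {
    episodes <- data.frame(start_s = numeric(0), end_s = numeric(0),
                           n_cycles = integer(0), rate_hz = numeric(0),
                           peak_to_peak_ratio = numeric(0),
                           channel = character(0))
  }

  isolated <- classify_isolated(pool, rec$channels)
  events <- rbind(
    giants[, c("time_s", "channel", "polarity", "width_ms", "amplitude_sd", "type")],
    isolated,
    if (length(swd_members)) do.call(rbind, swd_members))
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, episodes = episodes,
                 recording_duration_s = rec$duration_s,
                 candidates = candidates),
            class = "event_catalog")
}

#' @export
print.event_catalog <- function(x, ...) {
  tb <- table(x$events$type)
  cat(sprintf("<event_catalog> %.0f s; %d events (%s); %d SWD episodes\n",
              x$recording_duration_s, nrow(x$events),
              paste(names(tb), tb, sep = "=", collapse = ", "),
              nrow(x$episodes)))
  invisible(x)
}

#' Event rate in Hz
#'
#' Count of events of one type (or all types) normalized to recording
#' duration; `type = "swd"` counts SWD episodes.
#'
#' @param catalog an `event_catalog`.
#' @param type event type or `"all"`.
#' @return events per second (Hz).
#' @export
event_rate <- function(catalog, type = "all") {
  if (catalog$recording_duration_s <= 0) stop("event_rate: zero duration")
  n <- if (type == "swd") nrow(catalog$episodes)
  else if (type == "all") nrow(catalog$events)
  else sum(catalog$events$type == type)
  n / catalog$recording_duration_s
}

#' Log-binned inter-spike-interval histogram
#'
#' Successive differences of sorted event times binned over logarithmically
#' spaced edges. Log binning stabilizes the sparse long-interval tail.
#' Intervals outside `range_s` are clamped into the end bins, so counts
#' always sum to `n - 1`.
#'
#' @param times_s sorted event times in seconds (>= 2 events).
#' @param n_bins number of bins (default 24).
#' @param range_s histogram range in seconds (default 0.05-200).
#' @return list with `bin_edges_s` (length `n_bins + 1`), `counts`,
#'   `intervals_s`.
#' @export
isi_histogram <- function(times_s, n_bins = 24, range_s = c(0.05, 200)) {
  if (length(times_s) < 2L) {
    return(list(bin_edges_s = numeric(0), counts = integer(0),
                intervals_s = numeric(0)))
  }
  isi <- diff(sort(times_s))
  edges <- exp(seq(log(range_s[1]), log(range_s[2]), length.out = n_bins + 1))
  clamped <- pmin(pmax(isi, edges[1] * (1 + 1e-12)), edges[n_bins + 1])
  idx <- findInterval(clamped, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(bin_edges_s = edges, counts = counts, intervals_s = isi)
}
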