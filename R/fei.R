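#' Windowed amplitude and normalized fluctuation for the fE/I ratio
#'
#' The amplitude envelope's signal profile is divided into `window_s`-second
#' windows with `overlap_frac` overlap (defaults: 5 s, 80%, i.e. 1-s steps).
#' For each window, `w_amp` is the mean amplitude envelope in the window; the
#' signal-profile segment of that window is divided by `w_amp`, linearly
#' detrended, and the RMS of the residual is the normalized fluctuation
#' `nF`. When the envelope comes in several vigilance-state segments,
#' windows are laid within segments, never across seams.
#'
#' @param envelope numeric vector or list of vectors (per-interval envelope
#'   segments).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 5).
#' @param overlap_frac window overlap fraction (default 0.8).
#' @return object of class `fei_windows`: list with `starts_s` (window start
#'   offsets in the concatenated envelope), `w_amp`, `nF`, `window_s`,
#'   `overlap_frac`, `n_windows`. Zero windows when every segment is shorter
#'   than `window_s`.
#' @export
fei_windows <- function(envelope, fs, window_s = 5, overlap_frac = 0.8) {
  segs <- if (is.list(envelope)) envelope else list(envelope)
  L <- round(window_s * fs)
  step <- max(1L, round(window_s * (1 - overlap_frac) * fs))
  n_total <- sum(lengths(segs))
  mu <- sum(vapply(segs, sum, 0)) / n_total

  t1 <- seq_len(L); tbar <- (L + 1) / 2
  Stt <- L * (L^2 - 1) / 12
  w_amp <- numeric(0); nF <- numeric(0); starts_s <- numeric(0)
  offset <- 0
  for (s in segs) {
    n <- length(s)
    if (n >= L) {
      prof <- cumsum(s - mu)
      starts <- seq(1L, n - L + 1L, by = step)
      idx <- outer(t1 - 1L, starts, "+")
      E <- matrix(s[idx], nrow = L)
      P <- matrix(prof[idx], nrow = L)
      wa <- colMeans(E)
      Pn <- sweep(P, 2, wa, "/")
      Sx <- colSums(Pn)
      slope <- (colSums(Pn * t1) - tbar * Sx) / Stt
      rss <- colSums(Pn^2) - Sx^2 / L - slope^2 * Stt
      rss[rss < 0] <- 0
      w_amp <- c(w_amp, wa)
      nF <- c(nF, sqrt(rss / L))
      starts_s <- c(starts_s, offset + (starts - 1L) / fs)
    }
    offset <- offset + n / fs
  }
  structure(list(starts_s = starts_s, w_amp = w_amp, nF = nF,
                 window_s = window_s, overlap_frac = overlap_frac,
                 n_windows = length(w_amp)),
            class = "fei_windows")
}

#' The functional excitation-inhibition ratio
#'
#' `fE/I = 1 - r`, where `r` is the Pearson correlation between the windowed
#' amplitude `w_amp` and the normalized fluctuation `nF`. Values near 1
#' indicate balanced excitation/inhibition, above 1 excitation dominance,
#' below 1 inhibition dominance. The ratio is only interpretable in the
#' presence of long-range temporal correlations, so it is reported as
#' typed-missing whenever the envelope's DFA exponent is below
#' `beta_threshold` (default 0.6), the window count is below `min_windows`,
#' or either window series is degenerate (zero variance).
#'
#' @param windows a [fei_windows()] object.
#' @param dfa_beta DFA exponent of the same envelope (see [dfa()]).
#' @param beta_threshold DFA gate (default 0.6).
#' @param min_windows minimum windows for a stable Pearson correlation
#'   (default 40, about the count a 2-minute minimum yields at 1-s steps).
#' @return object of class `fei_result`: list with `fei` (or `NA`),
#'   `missing_reason` (`"none"`, `"low_dfa"`, `"too_short"`,
#'   `"degenerate"`), `r`, `dfa_beta`, `n_windows`.
#' @export
compute_fei <- function(windows, dfa_beta, beta_threshold = 0.6,
                        min_windows = 40) {
  res <- list(fei = NA_real_, missing_reason = "none", r = NA_real_,
              dfa_beta = dfa_beta, n_windows = windows$n_windows)
  if (windows$n_windows < min_windows) {
    res$missing_reason <- "too_short"
  } else if (is.na(dfa_beta) || dfa_beta < beta_threshold) {
    res$missing_reason <- "low_dfa"
  } else if (stats::var(windows$w_amp) == 0 || stats::var(windows$nF) == 0) {
    res$missing_reason <- "degenerate"
  } else {
    r <- stats::cor(windows$w_amp, windows$nF)
    res$r <- r
    res$fei <- 1 - r
  }
  structure(res, class = "fei_result")
}

#' @export
print.fei_result <- function(x, ...) {
  if (x$missing_reason == "none") {
    cat(sprintf("<fei_result> fE/I = %.3f (r = %.3f, beta = %.3f, %d windows)\n",
                x$fei, x$r, x$dfa_beta, x$n_windows))
  } else {
    cat(sprintf("<fei_result> missing (%s; beta = %.3f, %d windows)\n",
                x$missing_reason, x$dfa_beta, x$n_windows))
  }
  invisible(x)
}

#' fE/I from a raw envelope
#'
#' Convenience path: DFA gate plus windowed correlation in one call.
#'
#' @inheritParams fei_windows
#' @inheritParams compute_fei
#' @param fit_range_s DFA fit range in seconds.
#' @return a [compute_fei()] result.
#' @export
fei_from_envelope <- function(envelope, fs, window_s = 5, overlap_frac = 0.8,
                              beta_threshold = 0.6, min_windows = 40,
                              fit_range_s = c(0.4, 30)) {
  beta <- tryCatch(dfa(envelope, fs, fit_range_s)$beta,
                   error = function(e) NA_real_)
  compute_fei(fei_windows(envelope, fs, window_s, overlap_frac),
              dfa_beta = beta, beta_threshold = beta_threshold,
              min_windows = min_windows)
}

#' Band-resolved fE/I spectrum for one channel of a recording
#'
#' Applies the full per-band flow of the fE/I algorithm to the quiet-wake
#' portion of a recording: per-interval zero-phase band-pass filtering,
#' amplitude envelope with edge trimming, DFA of the pooled envelope, and
#' the windowed amplitude-vs-fluctuation correlation. Recordings with less
#' than `min_total_s` (default 2 min) of quiet wake are excluded outright.
#'
#' @param rec an [lfp_recording()].
#' @param channel channel name or index.
#' @param grid a [band_grid()] (or any data.frame with `lo`, `hi`, `label`).
#' @param track a [vigilance_track()] aligned to the recording.
#' @param state vigilance state to analyse (default `"quiet_wake"`).
#' @param min_total_s minimum summed state duration (default 120 s).
#' @inheritParams compute_fei
#' @return data.frame with one row per band: `band_label`, `lo`, `hi`,
#'   `fei`, `r`, `dfa_beta`, `n_windows`, `missing_reason`; or, when the
#'   recording is excluded, the same frame with zero rows and attribute
#'   `excluded_reason`.
#' @export
fei_spectrum <- function(rec, channel, grid = band_grid(), track,
                         state = "quiet_wake", min_total_s = 120,
                         beta_threshold = 0.6, min_windows = 40) {
  cc <- concatenate_state(rec, track, state, min_total_s)
  empty <- data.frame(band_label = character(0), lo = numeric(0),
                      hi = numeric(0), fei = numeric(0), r = numeric(0),
                      dfa_beta = numeric(0), n_windows = integer(0),
                      missing_reason = character(0))
  if (!cc$included) {
    attr(empty, "excluded_reason") <- cc$reason
    return(empty)
  }
  ci <- match(channel, rec$channels$name)
  if (is.na(ci)) ci <- as.integer(channel)
  # one shared forward FFT per segment across the whole band grid
  env_by_band <- rep(list(list()), nrow(grid))
  for (seg in cc$segments) {
    an <- band_analytic(seg[, ci], rec$fs, grid)
    for (b in seq_len(nrow(grid))) {
      if (!is.null(an[[b]])) {
        env_by_band[[b]][[length(env_by_band[[b]]) + 1L]] <- Mod(an[[b]])
      }
    }
  }
  rows <- lapply(seq_len(nrow(grid)), function(b) {
    lo <- grid$lo[b]; hi <- grid$hi[b]
    if (hi >= rec$fs / 2) return(NULL)   # band above Nyquist: skip
    envs <- env_by_band[[b]]
    if (!length(envs)) {
      return(data.frame(band_label = grid$label[b], lo = lo, hi = hi,
                        fei = NA_real_, r = NA_real_, dfa_beta = NA_real_,
                        n_windows = 0L, missing_reason = "too_short"))
    }
    beta <- tryCatch(dfa(envs, rec$fs)$beta, error = function(e) NA_real_)
    fr <- compute_fei(fei_windows(envs, rec$fs),
                      dfa_beta = beta, beta_threshold = beta_threshold,
                      min_windows = min_windows)
    data.frame(band_label = grid$label[b], lo = lo, hi = hi,
               fei = fr$fei, r = fr$r, dfa_beta = fr$dfa_beta,
               n_windows = fr$n_windows, missing_reason = fr$missing_reason)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}
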