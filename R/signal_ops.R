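#' Zero-phase FIR band-pass filter
#'
#' Filters a voltage trace with a linear-phase Hamming-window FIR band-pass
#' (designed by [signal::fir1()]) applied as a centred convolution, so the
#' output is zero-phase: phase relationships needed downstream (Hilbert phase
#' for phase-amplitude coupling) are preserved. The filter order covers at
#' least `n_cycles` cycles of the band's low edge and keeps the transition
#' width below a quarter of the bandwidth (see [fir_bandpass_taps()]), which
#' keeps narrow low bands stable and selective. Edges are handled by odd
#' reflection padding; output length equals input length.
#'
#' @param x numeric vector, the signal (uV).
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `hi` must be below Nyquist.
#' @param n_cycles low-edge cycles the filter must span (default 3).
#' @param taps optional precomputed FIR coefficients (odd length, symmetric);
#'   overrides `n_cycles`.
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, lo, hi, n_cycles = 3, taps = NULL) {
  check_band(lo, hi, fs)
  if (is.null(taps)) taps <- fir_bandpass_taps(fs, lo, hi, n_cycles)
  m <- (length(taps) - 1L) %/% 2L
  n <- length(x)
  if (n <= 2L * m) {
    stop("segment too short for band ", lo, "-", hi,
         " Hz filter (need > ", 2L * m, " samples, got ", n, ")")
  }
  # odd reflection about the end points suppresses edge transients
  left  <- 2 * x[1] - x[(m + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - m)]
  xp <- c(left, x, right)
  y <- fft_conv(xp, taps)
  y[(2L * m + 1L):(2L * m + n)]
}

#' FIR band-pass coefficients
#'
#' Designs the symmetric odd-length Hamming-window FIR used by [bandpass()].
#' The order covers at least `n_cycles` cycles of the band's low edge and is
#' additionally long enough to keep the Hamming transition width below a
#' quarter of the bandwidth, so narrow bands stay selective (the realized
#' noise bandwidth then matches an ideal rectangular mask within ~10%).
#' With `sharp = FALSE` only the cycle rule applies, leaving a wide
#' transition: that looser design is what amplitude extraction for
#' phase-amplitude coupling needs, since a band sharper than the phase
#' frequency would strip the modulation sidebands (centre +/- f_phase) it is
#' supposed to measure. Precompute once when filtering many segments in the
#' same band.
#'
#' @inheritParams bandpass
#' @param sharp enforce the transition-width bound (default TRUE).
#' @return numeric vector of filter coefficients (odd length).
#' @export
fir_bandpass_taps <- function(fs, lo, hi, n_cycles = 3, sharp = TRUE) {
  check_band(lo, hi, fs)
  ord <- ceiling(n_cycles * fs / lo)
  if (sharp) ord <- max(ord, ceiling(13.2 * fs / (hi - lo)))
  if (ord %% 2L == 1L) ord <- ord + 1L   # even order -> odd symmetric taps
  as.numeric(signal::fir1(ord, c(lo, hi) * 2 / fs, type = "pass"))
}

# Linear convolution via FFT; returns the full convolution of x and h.
fft_conv <- function(x, h) {
  L <- length(x) + length(h) - 1L
  n <- stats::nextn(L, 2)
  X <- stats::fft(c(x, numeric(n - length(x))))
  H <- stats::fft(c(h, numeric(n - length(h))))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n
  y[seq_len(L)]
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation of the analytic signal `x + i*H(x)`; its modulus is the
#' amplitude envelope and its argument the instantaneous phase.
#'
#' @param x numeric vector (should already be band-limited).
#' @return complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  if (any(!is.finite(x))) stop("analytic_signal: input must be finite")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a band-limited signal
#'
#' Pointwise modulus of the analytic signal. The caller is responsible for
#' trimming transform edge artifacts (see [edge_trim_samples()]).
#'
#' @param x numeric vector, a band-pass filtered trace.
#' @return nonnegative numeric vector, same length as `x`.
#' @export
amplitude_envelope <- function(x) Mod(analytic_signal(x))

#' Instantaneous phase of a band-limited signal
#'
#' @param x numeric vector, a band-pass filtered trace.
#' @return phase in radians in `[-pi, pi)`, same length as `x`.
#' @export
instantaneous_phase <- function(x) Arg(analytic_signal(x))

#' Edge samples to trim after filtering/Hilbert transform
#'
#' Two cycles of the band's low edge are trimmed from each side of every
#' filtered interval before windowed analysis, removing filter and Hilbert
#' edge artifacts.
#'
#' @param lo band low edge in Hz.
#' @param fs sampling rate in Hz.
#' @return integer number of samples to drop from each end.
#' @export
edge_trim_samples <- function(lo, fs) as.integer(ceiling(2 / lo * fs))

# Cache of FIR coefficient FFTs keyed by (band, fs, transform length).
.band_fft_cache <- new.env(parent = emptyenv())

# Analytic band signals for one contiguous segment across several bands,
# sharing a single forward FFT. The segment is odd-reflection padded, each
# band's zero-phase FIR is applied as a frequency-domain product, and the
# analytic (negative-frequency suppressing) mask is applied in the same
# padded domain before the inverse transform, so filtering and Hilbert
# transform cost one inverse FFT per band. Returns a list with one complex
# vector per band (trimmed by `trim_k` samples per side), or NULL entries
# for bands the segment is too short for.
band_analytic <- function(x, fs, bands, trim = TRUE, sharp = TRUE) {
  n <- length(x)
  taps_list <- lapply(seq_len(nrow(bands)), function(b) {
    if (bands$hi[b] >= fs / 2) return(NULL)
    fir_bandpass_taps(fs, bands$lo[b], bands$hi[b], sharp = sharp)
  })
  ms <- vapply(taps_list, function(tp) {
    if (is.null(tp)) NA_integer_ else (length(tp) - 1L) %/% 2L
  }, 0L)
  usable <- !is.na(ms) & (2L * ms < n)
  if (!any(usable)) return(rep(list(NULL), nrow(bands)))
  m_pad <- min(max(ms[usable]), n - 1L)
  left  <- 2 * x[1] - x[(m_pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - m_pad)]
  xp <- c(left, x, right)
  P <- stats::nextn(length(xp) + 2L * max(ms[usable]) + 1L, 2)
  X <- stats::fft(c(xp, numeric(P - length(xp))))
  # analytic mask for even P
  h <- numeric(P); h[1L] <- 1; h[P / 2L + 1L] <- 1; h[2L:(P / 2L)] <- 2
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    if (!usable[b] || ms[b] > m_pad) next
    tp <- taps_list[[b]]
    key <- paste(bands$lo[b], bands$hi[b], fs, P, length(tp), sep = "_")
    H <- .band_fft_cache[[key]]
    if (is.null(H)) {
      H <- stats::fft(c(tp, numeric(P - length(tp))))
      assign(key, H, envir = .band_fft_cache)
    }
    ya <- stats::fft(X * H * h, inverse = TRUE) / P
    k <- if (trim) edge_trim_samples(bands$lo[b], fs) else 0L
    if (n <= 2L * k + 2L) next
    idx <- (m_pad + ms[b] + k + 1L):(m_pad + ms[b] + n - k)
    out[[b]] <- ya[idx]
  }
  out
}

# Filter + envelope (+ optional phase) for one contiguous segment, with edge
# trimming. Returns NULL if the segment is too short to survive filtering
# and trimming.
band_envelope_segment <- function(x, fs, lo, hi, taps = NULL, trim = TRUE,
                                  want_phase = FALSE) {
  a <- band_analytic(x, fs, data.frame(lo = lo, hi = hi), trim = trim)[[1]]
  if (is.null(a)) return(NULL)
  out <- list(envelope = Mod(a), filtered = Re(a))
  if (want_phase) out$phase <- Arg(a)
  out
}
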