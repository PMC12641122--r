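#' Signal profile (cumulative sum of the demeaned envelope)
#'
#' First step of detrended fluctuation analysis: the amplitude envelope is
#' mean-subtracted and cumulatively summed. By construction the last profile
#' value is ~0 (telescoping of the demeaned series).
#'
#' @param envelope numeric vector (amplitude envelope).
#' @return numeric vector of the same length.
#' @export
signal_profile <- function(envelope) {
  if (length(envelope) < 2L) stop("signal_profile: need at least 2 samples")
  cumsum(envelope - mean(envelope))
}

#' Default log-spaced DFA window sizes
#'
#' 20 logarithmically spaced window sizes spanning the fit range (default
#' 0.4-30 s), capped at a quarter of the available samples and deduplicated
#' after rounding to whole samples.
#'
#' @param fs sampling rate in Hz.
#' @param n_samples total profile length in samples.
#' @param fit_range_s numeric length-2, fit range in seconds.
#' @param n_sizes number of sizes (default 20).
#' @return numeric vector of window sizes in seconds.
#' @export
dfa_window_sizes <- function(fs, n_samples, fit_range_s = c(0.4, 30),
                             n_sizes = 20) {
  hi <- min(fit_range_s[2], n_samples / 4 / fs)
  lo <- max(fit_range_s[1], 4 / fs)
  if (hi <= lo) stop("dfa_window_sizes: signal too short for the fit range")
  sizes <- exp(seq(log(lo), log(hi), length.out = n_sizes))
  unique(round(sizes * fs)) / fs
}

# Cumulative sums reused by window_rms across window sizes.
precompute_profile <- function(p) {
  list(p = p, A = cumsum(p), B = cumsum(p * seq_along(p)),
       C = cumsum(p * p))
}

# Residual RMS of linearly detrended windows for one window size, pooled
# across profile segments. Closed-form least squares on t = 1..L; window
# sums come from cumulative sums, so the cost is O(n) per segment. Each
# window's profile is re-anchored at its own start (subtracting the value
# just before the window), which leaves the detrended residual unchanged
# but keeps the cumulative sums well conditioned.
window_rms <- function(profiles, L, step) {
  tbar <- (L + 1) / 2
  Stt <- L * (L^2 - 1) / 12
  out <- numeric(0)
  for (pre in profiles) {
    if (is.numeric(pre)) pre <- precompute_profile(pre)
    p <- pre$p; A <- pre$A; B <- pre$B; C <- pre$C
    n <- length(p)
    if (n < L) next
    starts <- seq(1L, n - L + 1L, by = step)
    e <- starts + L - 1L
    prev <- starts - 1L
    first <- prev == 0L
    prev[first] <- 1L
    a0 <- A[prev]; a0[first] <- 0
    b0 <- B[prev]; b0[first] <- 0
    c0 <- C[prev]; c0[first] <- 0
    Sx <- A[e] - a0
    Stx <- (B[e] - b0) - (starts - 1) * Sx   # sum of t*x with t = 1..L
    Sxx <- C[e] - c0
    # re-anchor each window at its starting profile value
    cc <- p[prev]; cc[first] <- 0
    Sxx <- Sxx - 2 * cc * Sx + cc^2 * L
    Stx <- Stx - cc * L * (L + 1) / 2
    Sx <- Sx - cc * L
    slope <- (Stx - tbar * Sx) / Stt
    sxx_c <- Sxx - Sx^2 / L
    rss <- sxx_c - slope^2 * Stt
    rss[rss < 0] <- 0          # guard tiny negative rounding
    # near-perfect linear windows lose the residual to cancellation in the
    # cumulative sums; recompute those few exactly
    suspect <- which(rss < 1e-8 * pmax(sxx_c, .Machine$double.xmin))
    if (length(suspect)) {
      t1 <- seq_len(L)
      for (w in suspect) {
        xw <- p[starts[w]:(starts[w] + L - 1L)]
        b <- stats::cov(t1, xw) / stats::var(t1)
        res <- xw - mean(xw) - b * (t1 - tbar)
        rss[w] <- sum(res^2)
      }
    }
    out <- c(out, sqrt(rss / L))
  }
  out
}

#' Mean fluctuation per window size
#'
#' For each window size the profile is split into (50%-overlapping by
#' default) windows, each window is linearly detrended (DFA-1), the RMS of
#' the residual is taken per window, and the RMS values are averaged. When
#' the profile comes in several segments (vigilance-state intervals),
#' windows are laid within segments and pooled, never across seams.
#'
#' @param profile numeric vector or list of numeric vectors (segments).
#' @param fs sampling rate in Hz.
#' @param window_sizes_s window sizes in seconds.
#' @param overlap_frac window overlap fraction (default 0.5).
#' @return data.frame with columns `size_s` and `F`; sizes larger than every
#'   segment are dropped.
#' @export
fluctuation_function <- function(profile, fs, window_sizes_s,
                                 overlap_frac = 0.5) {
  profiles <- if (is.list(profile)) profile else list(profile)
  sizes <- sort(unique(round(window_sizes_s * fs)))
  sizes <- sizes[sizes >= 4]
  profiles <- lapply(profiles, precompute_profile)
  res <- lapply(sizes, function(L) {
    step <- max(1L, round(L * (1 - overlap_frac)))
    r <- window_rms(profiles, L, step)
    if (!length(r)) return(NULL)
    data.frame(size_s = L / fs, F = mean(r))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(size_s = numeric(0), F = numeric(0)) else out
}

#' DFA exponent from the fluctuation function
#'
#' Least-squares slope of `log10 F` on `log10 size` restricted to the fit
#' range (default 0.4-30 s, the range used throughout the pipeline).
#'
#' @param sizes_s window sizes in seconds.
#' @param F mean fluctuation per size.
#' @param fit_range_s numeric length-2 fit range in seconds.
#' @param n_samples profile length bookkeeping (optional).
#' @return object of class `dfa_result`: list with `beta`, `window_sizes_s`,
#'   `F`, `fit_range_s`, `fit_r2`, `n_samples`.
#' @export
dfa_exponent <- function(sizes_s, F, fit_range_s = c(0.4, 30),
                         n_samples = NA_integer_) {
  keep <- sizes_s >= fit_range_s[1] - 1e-9 & sizes_s <= fit_range_s[2] + 1e-9 &
    F > 0
  if (sum(keep) < 4L) {
    stop("dfa_exponent: fewer than 4 window sizes inside the fit range")
  }
  lx <- log10(sizes_s[keep]); ly <- log10(F[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  beta <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(beta = beta, window_sizes_s = sizes_s, F = F,
                 fit_range_s = fit_range_s, fit_r2 = r2,
                 n_samples = n_samples),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> beta = %.3f (fit %g-%g s, R2 = %.3f, %d sizes)\n",
              x$beta, x$fit_range_s[1], x$fit_range_s[2], x$fit_r2,
              length(x$window_sizes_s)))
  invisible(x)
}

#' DFA of an amplitude envelope
#'
#' Convenience wrapper: signal profile per segment (demeaned by the pooled
#' mean so the profile is comparable across segments), fluctuation function
#' with 50% overlapping windows, and log-log fit over `fit_range_s`.
#'
#' @param envelope numeric vector or list of numeric vectors (per-interval
#'   envelope segments).
#' @param fs sampling rate in Hz.
#' @param fit_range_s fit range in seconds (default 0.4-30).
#' @param overlap_frac DFA window overlap (default 0.5).
#' @param n_sizes number of window sizes (default 20).
#' @return a [dfa_exponent()] result.
#' @export
dfa <- function(envelope, fs, fit_range_s = c(0.4, 30), overlap_frac = 0.5,
                n_sizes = 20) {
  segs <- if (is.list(envelope)) envelope else list(envelope)
  n_total <- sum(lengths(segs))
  mu <- sum(vapply(segs, sum, 0)) / n_total
  profiles <- lapply(segs, function(s) cumsum(s - mu))
  sizes <- dfa_window_sizes(fs, n_total, fit_range_s, n_sizes)
  ff <- fluctuation_function(profiles, fs, sizes, overlap_frac)
  dfa_exponent(ff$size_s, ff$F, fit_range_s, n_samples = n_total)
}
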