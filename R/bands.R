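#' Construct the spectral band grid used throughout the pipeline
#'
#' Builds one low delta band plus `n_log_bands` geometrically (log) spaced
#' bands covering `f_lo`--`f_hi`. With the defaults this yields the 16-band
#' partition of the 1--150 Hz spectrum used for band-resolved fE/I analysis:
#' one band from 1 to 4 Hz and 15 log-spaced bands between 4 and 150 Hz.
#'
#' The geometric edges are `e_k = f_lo * (f_hi/f_lo)^(k/n_log_bands)` for
#' `k = 0..n_log_bands`. Adjacent band edges coincide exactly, so the grid is
#' an exact partition of `[f_lo, f_hi]`. Filtering always uses the raw edges;
#' the `label` column rounds edges to the nearest 0.5 Hz for display only
#' (e.g. raw edges 35.19--44.77 Hz display as "35-45 Hz").
#'
#' @param f_delta_lo,f_delta_hi low band edges in Hz (default 1 and 4).
#' @param f_lo,f_hi range covered by the log-spaced bands in Hz
#'   (default 4 and 150); `f_lo` must equal `f_delta_hi`.
#' @param n_log_bands number of log-spaced bands (default 15).
#' @return A data.frame of class `band_grid` with columns `lo`, `hi`
#'   (raw edges, Hz) and `label` (display name), one row per band,
#'   `1 + n_log_bands` rows in total.
#' @examples
#' g <- band_grid()
#' nrow(g)        # 16
#' g$label[[11]]  # "35-45 Hz" (raw edges 35.19, 44.77)
#' @export
band_grid <- function(f_delta_lo = 1, f_delta_hi = 4,
                      f_lo = 4, f_hi = 150, n_log_bands = 15) {
  if (!(f_delta_lo < f_delta_hi && f_delta_hi == f_lo && f_lo < f_hi)) {
    stop("band_grid: need f_delta_lo < f_delta_hi = f_lo < f_hi")
  }
  if (n_log_bands < 1) stop("band_grid: n_log_bands must be >= 1")
  k <- 0:n_log_bands
  edges <- f_lo * (f_hi / f_lo)^(k / n_log_bands)
  lo <- c(f_delta_lo, edges[-length(edges)])
  hi <- c(f_delta_hi, edges[-1])
  g <- data.frame(lo = lo, hi = hi,
                  label = band_label(lo, hi),
                  stringsAsFactors = FALSE)
  class(g) <- c("band_grid", "data.frame")
  g
}

#' Display label for a frequency band
#'
#' Rounds raw band edges to the nearest 0.5 Hz and formats them as
#' `"lo-hi Hz"`. Labels are cosmetic; computation uses raw edges.
#'
#' @param lo,hi band edges in Hz (vectorized).
#' @return character vector of labels.
#' @export
band_label <- function(lo, hi) {
  fmt <- function(x) {
    r <- round(x * 2) / 2
    ifelse(r == round(r), format(round(r), trim = TRUE),
           format(r, nsmall = 1, trim = TRUE))
  }
  paste0(fmt(lo), "-", fmt(hi), " Hz")
}

# Validate a (lo, hi) band against a sampling rate.
check_band <- function(lo, hi, fs) {
  if (!(lo > 0 && lo < hi)) stop("invalid band: need 0 < lo < hi")
  if (hi >= fs / 2) stop("band upper edge ", hi, " Hz is at or above Nyquist (fs = ", fs, " Hz)")
  invisible(TRUE)
}
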