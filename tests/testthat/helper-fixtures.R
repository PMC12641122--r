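# Small shared fixtures; everything is generated in code.

five_channels <- function() {
  data.frame(
    name = c("PFC1", "PTC1", "PTC2", "HC1", "HC2"),
    region = c("PFC", "PTC", "PTC", "HC", "HC"),
    hc_layer = c("none", "none", "none", "pyramidal", "pyramidal"),
    hemisphere = c("left", "left", "right", "left", "right"),
    stringsAsFactors = FALSE)
}

# white + pink background, one column per channel
noise_background <- function(n, channels, sd_white = 4, sd_pink = 6,
                             seed = 1) {
  out <- sapply(seq_len(nrow(channels)), function(j) {
    sd_pink * lfpei:::pink_noise(n, seed = seed * 100 + j) +
      lfpei:::with_seed(seed * 100 + 50 + j, stats::rnorm(n, sd = sd_white))
  })
  colnames(out) <- channels$name
  out
}

# naive MI oracle: two-pass binning, no vectorized shortcuts
mi_oracle <- function(phase, amplitude, n_bins = 18) {
  w <- 2 * pi / n_bins
  sums <- numeric(n_bins); cnt <- integer(n_bins)
  for (i in seq_along(phase)) {
    j <- floor((phase[i] + pi) / w) + 1
    if (j > n_bins) j <- n_bins
    sums[j] <- sums[j] + amplitude[i]
    cnt[j] <- cnt[j] + 1
  }
  m <- sums / cnt
  P <- m / sum(m)
  kl <- log(n_bins)
  for (j in seq_len(n_bins)) if (P[j] > 0) kl <- kl + P[j] * log(P[j])
  kl / log(n_bins)
}
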