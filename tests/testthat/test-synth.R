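test_that("fGn generator: white-noise case, determinism, analytic covariance", {
  x <- gen_fgn(0.5, 10000, seed = 2)
  expect_lt(abs(acf(x, plot = FALSE)$acf[2]), 3 / sqrt(10000))
  expect_identical(gen_fgn(0.5, 10000, seed = 2), x)
  expect_error(gen_fgn(1.2, 100), "H must be")
  # sample autocovariance matches the analytic fGn autocovariance at lags
  # 0..5 within 3 standard errors (SE estimated across seeds, since long
  # memory inflates it beyond the iid rate)
  G <- vapply(1:10, function(s) {
    acf(gen_fgn(0.8, 2^15, seed = s), lag.max = 5, type = "covariance",
        plot = FALSE, demean = FALSE)$acf[, 1, 1]
  }, numeric(6))
  g_true <- fgn_autocovariance(0:5, 0.8)
  dev <- abs(rowMeans(G) - g_true)
  se <- apply(G, 1, sd) / sqrt(10)
  expect_true(all(dev < 3 * se))
})

test_that("DFA of raw fGn recovers the Hurst exponent", {
  b <- mean(vapply(1:3, function(s) dfa(gen_fgn(0.8, 2^17, seed = s), 1000)$beta, 0))
  expect_lt(abs(b - 0.8), 0.05)
})

test_that("LRTC oscillation: envelope exponent recovery and white-noise limit", {
  fs <- 500
  rec_beta <- function(H, noise_sd, amplitude = 12, n_seeds = 5) {
    mean(vapply(seq_len(n_seeds), function(s) {
      o <- gen_lrtc_oscillation(150, fs, c(35, 45), envelope_H = H,
                                amplitude = amplitude, noise_sd = noise_sd,
                                seed = s)
      be <- lfpei:::band_envelope_segment(o$signal, fs, 35, 45)
      dfa(be$envelope, fs)$beta
    }, 0))
  }
  expect_lt(abs(rec_beta(0.6, 0) - 0.6), 0.07)
  # SNR -> 0: the exponent collapses from the generated 0.8 toward the
  # uncorrelated band-limited-envelope limit (slightly above 1/2 at this
  # fit range; see the ideal-mask oracle in the acceptance suite)
  b0 <- rec_beta(0.8, 30, amplitude = 0.05)
  expect_lt(b0, 0.65)
  expect_gt(b0, 0.45)
  # determinism
  o1 <- gen_lrtc_oscillation(10, fs, seed = 9)
  o2 <- gen_lrtc_oscillation(10, fs, seed = 9)
  expect_identical(o1$signal, o2$signal)
})

test_that("PAC signal construction matches its closed form", {
  p <- gen_pac_signal(6, 60, 0.4, 2, 1000)
  tt <- (0:1999) / 1000
  a <- 1 - 0.4 + 0.4 * (1 + cos(2 * pi * 6 * tt)) / 2
  expect_equal(p$modulator, a)
  expect_equal(p$signal, sin(2 * pi * 6 * tt) + a * sin(2 * pi * 60 * tt))
  expect_equal(range(gen_pac_signal(6, 60, 1, 1, 500)$modulator),
               c(0, 1), tolerance = 1e-6)
  expect_error(gen_pac_signal(60, 6, 0.5, 1, 500), "f_phase < f_amp")
  expect_error(gen_pac_signal(6, 60, 1.5, 1, 500), "chi")
})

test_that("event injection produces an exact ground-truth catalog", {
  fs <- 500
  ch <- five_channels()
  data <- noise_background(600 * fs, ch, seed = 11)
  tms <- seq(10, 580, length.out = 12)
  ev <- data.frame(time_s = tms, type = "isolated", channel = "HC1",
                   amplitude_sd = 9, width_ms = 40)
  inj <- inject_events(data, fs, ch, ev)
  expect_equal(nrow(inj$truth), 12L)
  expect_equal(nrow(inj$truth) / 600, 0.02)          # bookkeeping rate
  # injected samples actually lie where the catalog says (negative peak)
  xf <- bandpass(inj$data[, "HC1"] - data[, "HC1"], fs, 5, 200)
  for (t0 in inj$truth$time_s) {
    i <- round(t0 * fs) + 1
    expect_lt(xf[i], 0)
    expect_gt(abs(xf[i]), 0.5 * max(abs(xf)))
  }
  # SWD template satisfies the duration arithmetic: 8 cycles at 7 Hz
  expect_gte(8 / 7, 1)
  evs <- data.frame(time_s = 100, type = "swd", channel = "PFC1",
                    amplitude_sd = 3, rate_hz = 7, n_cycles = 8)
  injs <- inject_events(data, fs, ch, evs)
  d <- injs$data[, "PFC1"] - data[, "PFC1"]
  expect_equal(sum(d != 0) / fs, 8 / 7, tolerance = 0.02)
  # out-of-bounds template errors
  evb <- data.frame(time_s = 599.9, type = "isolated", channel = "HC1",
                    amplitude_sd = 9, width_ms = 40)
  expect_error(inject_events(data, fs, ch, evb), "bounds")
})

test_that("cohort bookkeeping, determinism and nested structure", {
  coh <- gen_cohort(n_per_genotype = 1, months = 5, weeks_per_month = 4,
                    duration_s = 30, fs = 200, seed = 3,
                    effects = cohort_effects(5))
  # 4 weekly recordings per month per mouse
  expect_equal(nrow(coh$manifest), 4 * 2)   # two genotypes
  expect_equal(unname(table(coh$manifest$subject_id)), c(4L, 4L),
               ignore_attr = TRUE)
  coh2 <- gen_cohort(n_per_genotype = 1, months = 5, weeks_per_month = 4,
                     duration_s = 30, fs = 200, seed = 3,
                     effects = cohort_effects(5))
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)
  expect_identical(coh$manifest, coh2$manifest)
  # channel metadata invariants
  expect_true(all(xor(coh$channels$region == "HC",
                      coh$channels$hc_layer == "none")))
})
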