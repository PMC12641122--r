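test_that("NEO algebraic identities", {
  fs <- 1000
  tt <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 25 * tt)
  psi <- neo(x)
  core <- psi[100:900]
  expect_lt(max(core) / min(core), 1.05)     # tone -> flat NEO
  # impulse of height h
  imp <- numeric(101); imp[51] <- 3
  expect_equal(neo(imp)[51], 9)
  # linear ramp -> 1 everywhere
  ramp <- as.numeric(1:50)
  expect_true(all(neo(ramp)[2:49] == 1))
  # lagged operator on a tone: A^2 sin^2(2 pi f k / fs)
  psik <- neo(x, lag = 10)
  expect_equal(mean(psik[100:900]), sin(2 * pi * 25 * 10 / fs)^2,
               tolerance = 0.01)
  expect_error(neo(1:2), "samples")
})

test_that("neo_detect: zero signal, threshold monotonicity, scale invariance", {
  fs <- 500
  expect_equal(nrow(neo_detect(numeric(10 * fs), fs)), 0L)
  ch <- five_channels()
  data <- noise_background(120 * fs, ch, seed = 21)
  ev <- data.frame(time_s = seq(10, 110, by = 10), type = "isolated",
                   channel = "HC1", amplitude_sd = 8, width_ms = 40)
  x <- inject_events(data, fs, ch, ev)$data[, "HC1"]
  n8 <- nrow(neo_detect(x, fs, k_thresh = 8))
  n16 <- nrow(neo_detect(x, fs, k_thresh = 16))
  expect_lte(n16, n8)
  # thresholds are relative: rescaling leaves detections unchanged
  d1 <- neo_detect(x, fs)
  d2 <- neo_detect(1000 * x, fs)
  expect_equal(d1$time_s, d2$time_s)
  expect_equal(d1$amplitude_sd, d2$amplitude_sd, tolerance = 1e-9)
})

test_that("injected isolated spikes are recovered with high recall/precision", {
  fs <- 500
  ch <- five_channels()
  data <- noise_background(600 * fs, ch, seed = 2)
  tms <- seq(10, 590, by = 29)
  ev <- data.frame(time_s = tms, type = "isolated", channel = "HC1",
                   amplitude_sd = 8, width_ms = 40)
  inj <- inject_events(data, fs, ch, ev)
  catal <- detect_events(lfp_recording(inj$data, fs, ch))
  det <- catal$events[catal$events$type == "isolated_hc", ]
  tp <- sum(vapply(inj$truth$time_s,
                   function(t) any(abs(det$time_s - t) < 0.05), TRUE))
  expect_gte(tp / nrow(inj$truth), 0.9)
  expect_gte(tp / max(1, nrow(det)), 0.9)
})

test_that("SWD rules accept and reject exactly as printed", {
  fs <- 500
  ch <- five_channels()
  data <- noise_background(300 * fs, ch, seed = 3)
  base <- data.frame(time_s = 150, type = "swd", channel = "PFC1",
                     amplitude_sd = 3, rate_hz = 7, n_cycles = 8)
  ep <- detect_swd(inject_events(data, fs, ch, base)$data[, "PFC1"], fs)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$n_cycles, 8L)
  expect_gte(ep$rate_hz, 6)
  expect_gte(ep$end_s - ep$start_s, 1)
  expect_gt(ep$peak_to_peak_ratio, 2)
  # < 3 cycles rejected
  ep2 <- detect_swd(inject_events(data, fs, ch, transform(base, n_cycles = 2))$data[, "PFC1"], fs)
  expect_equal(nrow(ep2), 0L)
  # 5 Hz train rejected (< 6 Hz)
  ep3 <- detect_swd(inject_events(data, fs, ch, transform(base, rate_hz = 5))$data[, "PFC1"], fs)
  expect_equal(nrow(ep3), 0L)
  # two trains < 1 s apart merge into one episode
  two <- rbind(base, transform(base, time_s = 150 + 8 / 7 + 0.5))
  ep4 <- detect_swd(inject_events(data, fs, ch, two)$data[, "PFC1"], fs)
  expect_equal(nrow(ep4), 1L)
  expect_equal(ep4$n_cycles, 16L)
  # background alone yields no episodes
  expect_equal(nrow(detect_swd(data[, "PFC1"], fs)), 0L)
})

test_that("giant spikes require simultaneity, amplitude and the AHP", {
  fs <- 500
  ch <- five_channels()
  data <- noise_background(200 * fs, ch, seed = 4)
  ev <- data.frame(time_s = c(60, 140), type = "giant", channel = "HC1",
                   amplitude_sd = 12)
  inj <- inject_events(data, fs, ch, ev)
  rec <- lfp_recording(inj$data, fs, ch)
  g <- detect_events(rec)$events
  g <- g[g$type == "giant", ]
  expect_equal(nrow(g), 2L)
  expect_true(all(g$amplitude_sd > 10))
  # constructed candidate sets: missing on one channel -> not giant
  cand <- lapply(ch$name, function(nm) data.frame(
    time_s = 50, polarity = "negative", width_ms = 30, amplitude = -60,
    amplitude_sd = 12, type = "candidate"))
  names(cand) <- ch$name
  cand[["PTC2"]] <- cand[["PTC2"]][0, ]
  miss <- classify_giant(cand, rec)
  expect_equal(nrow(miss), 0L)
  # all channels but amplitude below 10 SD on HC -> not giant
  cand2 <- lapply(ch$name, function(nm) data.frame(
    time_s = 50, polarity = "negative", width_ms = 30, amplitude = -30,
    amplitude_sd = 6, type = "candidate"))
  names(cand2) <- ch$name
  expect_equal(nrow(classify_giant(cand2, rec)), 0L)
  # 12 SD but no positive tail -> not giant
  flat <- lfp_recording(matrix(-1, 200 * fs, 5), fs, ch)
  cand3 <- lapply(ch$name, function(nm) data.frame(
    time_s = 50, polarity = "negative", width_ms = 30, amplitude = -60,
    amplitude_sd = 12, type = "candidate"))
  names(cand3) <- ch$name
  expect_equal(nrow(classify_giant(cand3, flat)), 0L)
})

test_that("isolated classification follows width, polarity and pairing rules", {
  ch <- five_channels()
  mk <- function(...) {
    d <- data.frame(...)
    d$type <- "candidate"
    d
  }
  cand <- list(
    HC1 = mk(time_s = c(10, 20, 30), polarity = c("negative", "negative", "negative"),
             width_ms = c(60, 120, 60), amplitude = -40, amplitude_sd = 8),
    HC2 = mk(time_s = 10.05, polarity = "negative", width_ms = 50,
             amplitude = -35, amplitude_sd = 7))
  iso <- classify_isolated(cand, ch)
  # t=10 paired contralaterally (within 100 ms) -> neither isolated;
  # t=20 too wide; t=30 lone 60 ms negative spike -> isolated
  expect_equal(iso$time_s, 30)
  expect_equal(iso$type, "isolated_hc")
  # positive polarity excluded
  cand2 <- list(HC1 = mk(time_s = 15, polarity = "positive", width_ms = 40,
                         amplitude = 40, amplitude_sd = 8))
  expect_equal(nrow(classify_isolated(cand2, ch)), 0L)
  # no contralateral channel: rule passes vacuously, with a caveat
  ch1 <- ch[ch$name %in% c("PFC1", "HC1"), ]
  iso3 <- classify_isolated(cand[
    "HC1"], ch1)
  expect_equal(nrow(iso3), 2L)   # width rule still applies
  expect_true("HC1" %in% attr(iso3, "pairing_caveat"))
})

test_that("rates and ISI histograms satisfy their conservation laws", {
  catal <- structure(list(
    events = data.frame(time_s = c(1, 2, 3), channel = "HC1",
                        polarity = "negative", width_ms = 40,
                        amplitude_sd = 8, type = "isolated_hc"),
    episodes = data.frame()[0, ], recording_duration_s = 600),
    class = "event_catalog")
  expect_equal(event_rate(catal, "isolated_hc"), 0.005)
  expect_equal(event_rate(catal, "giant"), 0)
  # additivity under concatenation: pooled rate is count-weighted
  r1 <- 12 / 600; r2 <- 3 / 300
  expect_equal((12 + 3) / (600 + 300), (r1 * 600 + r2 * 300) / 900)
  # ISI histogram
  h <- isi_histogram(c(0, 1, 2, 3), n_bins = 10, range_s = c(0.1, 10))
  expect_equal(sum(h$counts), 3L)
  expect_equal(length(unique(which(h$counts > 0))), 1L)
  set.seed(6)
  for (s in 1:10) {
    t0 <- cumsum(rexp(40, rate = 0.05))
    h2 <- isi_histogram(t0)
    expect_equal(sum(h2$counts), 39L)
  }
  # Poisson spikes: mean interval ~ 1/rate over seeds
  mean_isi <- mean(vapply(1:10, function(s) {
    set.seed(s)
    mean(isi_histogram(cumsum(rexp(60, 0.05)))$intervals_s)
  }, 0))
  expect_lt(abs(mean_isi - 20) / 20, 0.2)
  expect_equal(length(isi_histogram(c(1))$counts), 0L)
})

test_that("candidate types partition: every event carries exactly one label", {
  fs <- 500
  ch <- five_channels()
  data <- noise_background(200 * fs, ch, seed = 7)
  ev <- rbind(
    data.frame(time_s = c(30, 90), type = "isolated", channel = "HC1",
               amplitude_sd = 9, width_ms = 40),
    data.frame(time_s = 150, type = "isolated", channel = "PTC1",
               amplitude_sd = 9, width_ms = 40))
  catal <- detect_events(lfp_recording(inject_events(data, fs, ch, ev)$data, fs, ch))
  expect_true(all(catal$events$type %in%
                    c("isolated_hc", "isolated_ctx", "giant", "swd_member")))
  expect_false(any(duplicated(catal$events[, c("time_s", "channel")])))
  expect_true(all(diff(catal$events$time_s) >= 0))   # sorted
})
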