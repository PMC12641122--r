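test_that("MI is 0 for uniform coupling and exactly 1 for single-bin mass", {
  set.seed(1)
  ph <- runif(60000, -pi, pi)
  amp <- abs(rnorm(60000)) + 1          # independent of phase
  expect_lt(modulation_index(ph, amp), 1e-3)
  # all amplitude mass in one bin
  ph2 <- runif(18000, -pi, pi)
  amp2 <- as.numeric(ph2 >= -pi & ph2 < -pi + 2 * pi / 18)
  expect_identical(modulation_index(ph2, amp2), 1)
})

test_that("MI matches a naive two-pass binning oracle", {
  p <- gen_pac_signal(6, 60, 0.7, 20, 500, seed = 2)
  expect_equal(modulation_index(p$phase, p$modulator),
               mi_oracle(p$phase, p$modulator), tolerance = 1e-12)
})

test_that("MI invariances: amplitude scale and bin-aligned phase rotation", {
  p <- gen_pac_signal(6, 60, 0.5, 30, 500, seed = 3)
  m0 <- modulation_index(p$phase, p$modulator)
  expect_equal(modulation_index(p$phase, 250 * p$modulator), m0,
               tolerance = 1e-12)
  rot <- function(ph, d) ((ph + pi + d) %% (2 * pi)) - pi
  expect_equal(modulation_index(rot(p$phase, 2 * pi / 18), p$modulator), m0,
               tolerance = 1e-12)
  # arbitrary rotation changes MI only slightly on long fixtures
  expect_lt(abs(modulation_index(rot(p$phase, 0.123), p$modulator) - m0), 1e-2)
})

test_that("an empty phase bin raises an insufficient-data error", {
  ph <- runif(1000, 0, pi / 2)   # covers a quarter of the cycle
  expect_error(modulation_index(ph, abs(rnorm(1000))), "empty phase bin")
  expect_error(modulation_index(1:3, 1:2), "lengths differ")
})

test_that("filtered-path MI agrees with the modulator oracle and rises with chi", {
  fs <- 1000
  g <- list(phase = data.frame(center = 6, lo = 5, hi = 7),
            amp = data.frame(center = 60, lo = 50, hi = 70))
  p <- gen_pac_signal(6, 60, 0.8, 60, fs, seed = 7)
  cm <- comodulogram(p$signal, fs, g)
  expect_lt(abs(cm$mi[1, 1] - mi_oracle(p$phase, p$modulator)), 1e-2)
  mis <- vapply(c(0, 0.3, 0.6, 0.9), function(chi) {
    pp <- gen_pac_signal(6, 60, chi, 60, fs, noise_sd = 0.5, seed = 3)
    comodulogram(pp$signal, fs, g)$mi[1, 1]
  }, 0)
  expect_true(all(diff(mis) > 0))
  expect_lt(mis[1], 0.01)                  # chi = 0: uncoupled
  expect_true(all(mis >= 0 & mis <= 1))
})

test_that("grids follow the printed centre/bandwidth conventions", {
  g <- pac_grids("cortical", fs = 1000)
  expect_equal(g$phase$center, 2:14)
  expect_equal(g$phase$hi - g$phase$lo, rep(2, 13))
  expect_equal(g$amp$center, 40:200)
  expect_equal(g$amp$hi - g$amp$lo, rep(2, 161))
  gh <- pac_grids("hippocampal", fs = 1000)
  expect_equal(gh$amp$center, seq(40, 300, 2))
  expect_equal(gh$amp$hi - gh$amp$lo, rep(4, 131))
  expect_warning(gt <- pac_grids("hippocampal", fs = 500), "Nyquist")
  expect_true(all(gt$amp$hi < 250))
})

test_that("band averages reduce correctly and localize coupling", {
  mi <- matrix(0.37, nrow = 4, ncol = 6)
  com <- structure(list(phase_centers = c(4, 6, 8, 10),
                        amp_centers = c(40, 60, 80, 100, 120, 160),
                        mi = mi, minutes_used = 5),
                   class = "comodulogram")
  expect_equal(pac_band_average(com, c(4, 10), c(40, 90)), 0.37)
  s <- pac_summary(com, "cortical")
  expect_equal(s$theta_low_gamma, 0.37)
  expect_null(s$theta_total_gamma)        # cortical omits total gamma
  sh <- pac_summary(com, "hippocampal")
  expect_equal(sh$theta_total_gamma, 0.37)
  expect_error(pac_band_average(com, c(20, 30), c(40, 90)), "empty range")
  # coupling injected at (6, 60) localizes to theta x low gamma
  fs <- 500
  p <- gen_pac_signal(6, 60, 0.8, 60, fs, noise_sd = 0.3, seed = 4)
  g <- list(phase = data.frame(center = c(6, 8), lo = c(5, 7), hi = c(7, 9)),
            amp = data.frame(center = c(60, 120), lo = c(55, 115),
                             hi = c(65, 125)))
  cm <- comodulogram(p$signal, fs, g)
  tl <- pac_band_average(cm, c(4, 10), c(40, 90))
  th <- pac_band_average(cm, c(4, 10), c(90, 160))
  expect_gt(tl, th)
})

test_that("monthly_pac truncates to the target and flags shortfall", {
  fs <- 250
  ch <- five_channels()
  mk_week <- function(seed) {
    set.seed(seed)
    n <- 200 * fs
    x <- matrix(rnorm(n * 5), ncol = 5)
    p <- gen_pac_signal(6, 60, 0.6, 200, fs, amp_fast = 4, seed = seed)
    x[, 4] <- x[, 4] + 3 * p$signal
    list(rec = lfp_recording(x, fs, ch),
         tr = vigilance_track(rep("active_wake", 40)))
  }
  wks <- lapply(1:4, mk_week)
  g <- list(phase = data.frame(center = 6, lo = 5, hi = 7),
            amp = data.frame(center = 60, lo = 55, hi = 65))
  mp <- monthly_pac(lapply(wks, `[[`, "rec"), lapply(wks, `[[`, "tr"),
                    "HC1", g, target_minutes = 10)
  expect_equal(mp$minutes_used, 10, tolerance = 0.05)
  expect_false(mp$shortfall)
  mp1 <- monthly_pac(list(wks[[1]]$rec), list(wks[[1]]$tr), "HC1", g,
                     target_minutes = 10)
  expect_lt(mp1$minutes_used, 10)
  expect_true(mp1$shortfall)
  # no active wake at all
  tr_s <- vigilance_track(rep("sleep", 40))
  expect_null(monthly_pac(list(wks[[1]]$rec), list(tr_s), "HC1", g))
})
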