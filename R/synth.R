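# Synthetic LFP with analytically known ground truth: envelope Hurst
# exponent, coupling depth, injected epileptiform events, vigilance
# structure, and a nested longitudinal cohort. All generators are pure
# functions of (parameters, seed).

# Evaluate code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Analytic autocovariance of fractional Gaussian noise
#'
#' `gamma(k) = 0.5 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))` for unit
#' variance.
#'
#' @param k integer lag(s).
#' @param H Hurst exponent in (0, 1).
#' @return autocovariance value(s).
#' @export
fgn_autocovariance <- function(k, H) {
  k <- abs(k)
  0.5 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

#' Exact fractional Gaussian noise via circulant embedding
#'
#' Davies-Harte construction: the fGn autocovariance is embedded in a
#' circulant matrix whose eigenvalues (FFT of the first row) must be
#' nonnegative; complex Gaussian variates shaped by the eigenvalue square
#' roots then yield a series with *exactly* the fGn covariance. `H = 0.5`
#' gives white noise; `H > 0.5` long-range positive correlation.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n number of samples.
#' @param seed integer seed (generation is reproducible).
#' @return numeric vector of length `n`, zero mean, unit variance.
#' @export
gen_fgn <- function(H, n, seed = 1) {
  if (H <= 0 || H >= 1) stop("gen_fgn: H must be in (0, 1)")
  m <- 2L * stats::nextn(n, 2)
  g <- fgn_autocovariance(0:(m / 2), H)
  row1 <- c(g, rev(g[2:(m / 2)]))
  ev <- Re(stats::fft(row1))
  if (min(ev) < -1e-8 * max(ev)) {
    stop("gen_fgn: circulant embedding not positive definite for H = ", H,
         ", n = ", n)
  }
  ev[ev < 0] <- 0
  with_seed(seed, {
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    # Re of the transform of independent complex normals shaped by
    # sqrt(ev/m) has exactly the circulant covariance (hence exact fGn
    # covariance on the first n samples)
    w <- stats::fft(sqrt(ev / m) * z)
    Re(w)[seq_len(n)]
  })
}

#' Band-limited oscillation with long-range temporally correlated envelope
#'
#' A sinusoidal carrier at the band centre is multiplied by a positive
#' envelope built by exponentiating scaled fGn (geometric envelope;
#' exponentiation preserves the long-range correlation structure that
#' clipping would destroy), then white measurement noise is added. The DFA
#' exponent of the recovered analytic envelope tracks `envelope_H`.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 1000).
#' @param carrier_band numeric length-2, carrier band in Hz (default
#'   35-45, the low-gamma band); the carrier sits at the geometric centre.
#' @param envelope_H target Hurst exponent of the envelope in (0, 1).
#' @param env_log_sd log-scale SD of the geometric envelope (default 0.3).
#' @param amplitude mean envelope amplitude in uV (default 20).
#' @param env_offset additive slow amplitude offset (uV) driven by a
#'   low-frequency modulator; nonzero values break the amplitude/fluctuation
#'   symmetry and push fE/I above 1 (excitation-dominated regime). Default
#'   0 (balanced).
#' @param noise_sd white noise SD in uV (default 0).
#' @param seed integer seed.
#' @return list with `signal`, `envelope` (ground-truth envelope), `fs`,
#'   `true_H`.
#' @export
gen_lrtc_oscillation <- function(duration_s, fs = 1000,
                                 carrier_band = c(35, 45), envelope_H = 0.8,
                                 env_log_sd = 0.3, amplitude = 20,
                                 env_offset = 0, noise_sd = 0, seed = 1) {
  n <- round(duration_s * fs)
  g <- gen_fgn(envelope_H, n, seed = seed)
  env <- exp(env_log_sd * g)
  env <- env / mean(env) * amplitude
  if (env_offset != 0) {
    # slow (0.05 Hz) raised-cosine modulator adds amplitude without adding
    # fluctuation -> high-amplitude windows have lower normalized fluctuation
    tt <- (seq_len(n) - 1) / fs
    slow <- 0.5 * (1 + cos(2 * pi * 0.05 * tt + with_seed(seed + 7, stats::runif(1, 0, 2 * pi))))
    env <- env + env_offset * amplitude * slow
  }
  f0 <- sqrt(prod(carrier_band))
  tt <- (seq_len(n) - 1) / fs
  x <- env * sin(2 * pi * f0 * tt)
  if (noise_sd > 0) x <- x + with_seed(seed + 1, stats::rnorm(n, sd = noise_sd))
  list(signal = x, envelope = env, fs = fs, true_H = envelope_H)
}

#' Phase-amplitude coupled test signal
#'
#' `x(t) = sin(2 pi f_phase t) + a(t) sin(2 pi f_amp t) + noise` with
#' modulator `a(t) = 1 - chi + chi * (1 + cos(2 pi f_phase t)) / 2`:
#' `chi = 0` gives a constant fast-oscillation amplitude (no coupling),
#' `chi = 1` full-depth modulation (amplitude reaching zero at the phase
#' trough).
#'
#' @param f_phase slow (phase) frequency in Hz.
#' @param f_amp fast (amplitude) frequency in Hz.
#' @param chi modulation depth in `[0, 1]`.
#' @param duration_s length in seconds.
#' @param fs sampling rate in Hz (default 1000).
#' @param amp_fast fast-oscillation base amplitude (default 1).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed integer seed.
#' @return list with `signal`, `modulator` (the true `a(t)`), `phase`
#'   (the true slow phase), `fs`, `true_chi`.
#' @export
gen_pac_signal <- function(f_phase, f_amp, chi, duration_s, fs = 1000,
                           amp_fast = 1, noise_sd = 0, seed = 1) {
  if (chi < 0 || chi > 1) stop("gen_pac_signal: chi must be in [0, 1]")
  if (!(f_phase < f_amp && f_amp < fs / 2)) {
    stop("gen_pac_signal: need f_phase < f_amp < fs/2")
  }
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  a <- 1 - chi + chi * (1 + cos(2 * pi * f_phase * tt)) / 2
  x <- sin(2 * pi * f_phase * tt) + amp_fast * a * sin(2 * pi * f_amp * tt)
  if (noise_sd > 0) x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  ph <- ((2 * pi * f_phase * tt + pi) %% (2 * pi)) - pi
  list(signal = x, modulator = a, phase = ph, fs = fs, true_chi = chi)
}

# --- event templates ---------------------------------------------------------

# Biphasic spike: dominant sharp negative peak (full width at half maximum
# about width_ms) followed by a smaller positive rebound.
spike_template <- function(fs, width_ms = 40, amplitude = 1,
                           polarity = "negative") {
  sigma <- width_ms / 1000 / 2.355
  tt <- seq(-3 * sigma, 6 * sigma, by = 1 / fs)
  w <- -exp(-tt^2 / (2 * sigma^2)) +
    0.35 * exp(-(tt - 2.2 * sigma)^2 / (2 * (1.8 * sigma)^2))
  w <- w / max(abs(w)) * amplitude
  if (polarity == "negative") w else -w
}

# 1/f ("pink") noise via FFT spectral shaping of white noise; unit SD.
pink_noise <- function(n, seed = 1) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)              # symmetric frequency index
    X <- X / sqrt(f)
    y <- Re(stats::fft(X, inverse = TRUE)) / n
    (y - mean(y)) / stats::sd(y)
  })
}

# One spike-wave cycle: sharp negative spike followed by a slow positive wave.
swd_cycle_template <- function(fs, rate_hz, amplitude = 1) {
  period <- 1 / rate_hz
  n <- round(period * fs)
  tt <- seq_len(n) / fs
  spike_sd <- period / 14
  sp <- -exp(-((tt - period * 0.15)^2) / (2 * spike_sd^2))
  wave <- 0.45 * sin(pi * pmax(0, (tt - period * 0.3)) / (period * 0.7))
  amplitude * (sp + wave)
}

# Giant spike: sharp transient plus a sustained positive AHP tail.
giant_template <- function(fs, amplitude = 1, ahp_ms = 300,
                           ahp_frac = 0.5) {
  sp <- spike_template(fs, width_ms = 30, amplitude = amplitude,
                       polarity = "negative")
  n_ahp <- round(ahp_ms / 1000 * fs)
  tail <- ahp_frac * amplitude * sin(pi * seq_len(n_ahp) / n_ahp)^0.5
  c(sp, tail)
}

#' Inject epileptiform events into multichannel traces
#'
#' Adds parameterized event waveforms at requested times and returns the
#' exact ground-truth catalog. Amplitudes are specified in SD units of the
#' pre-injection 5-200 Hz filtered background of the target channel.
#'
#' Supported types: `"isolated"` (biphasic negative transient < 100 ms on
#' one channel), `"swd"` (a train of `n_cycles >= 3` spike-wave cycles at
#' `rate_hz >= 6` on a PFC channel), `"giant"` (simultaneous transient on
#' all channels, largest on one HC channel, followed by a > 200 ms positive
#' deflection on every channel).
#'
#' @param data samples-x-channels numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channels channel metadata (see [lfp_recording()]).
#' @param events data.frame with columns `time_s`, `type`, `channel`,
#'   `amplitude_sd`, and optionally `width_ms` (isolated), `rate_hz`,
#'   `n_cycles` (swd). For isolated and giant events `amplitude_sd` is in
#'   robust-SD units of the 5-200 Hz background; for SWD trains it is the
#'   target peak-to-peak ratio versus the 1-80 Hz background.
#' @return list with `data` (modified matrix) and `truth` (the injected
#'   event catalog with exact times/channels/amplitudes).
#' @export
inject_events <- function(data, fs, channels, events) {
  data <- as.matrix(data)
  n <- nrow(data)
  # background SD per channel on the pre-injection filtered trace,
  # computed only for channels that receive events
  need <- if (any(events$type == "giant")) channels$name else
    intersect(channels$name, unique(events$channel))
  bg_sd <- stats::setNames(rep(NA_real_, ncol(data)), channels$name)
  for (ch in need) {
    j <- match(ch, channels$name)
    xf <- bandpass(data[, j], fs, 5, min(200, 0.45 * fs))
    s <- 1.4826 * stats::mad(xf, constant = 1)
    bg_sd[j] <- if (s <= 0) stats::sd(xf) else s
  }
  bg_p2p <- function(x, fs) {
    xf <- bandpass(x, fs, 1, min(80, 0.45 * fs))
    wlen <- round(fs)
    nw <- floor(length(xf) / wlen)
    stats::median(vapply(seq_len(nw), function(w) {
      diff(range(xf[((w - 1L) * wlen + 1L):(w * wlen)]))
    }, 0))
  }
  # peak attenuation of a template through the 5-200 Hz detection band;
  # amplitudes are calibrated on the filtered template so the injected
  # event genuinely reaches its nominal SD in the band the detector sees
  filtered_gain <- function(w) {
    lo <- 5; hi <- min(200, 0.45 * fs)
    taps <- fir_bandpass_taps(fs, lo, hi)
    pad <- numeric(length(taps))
    max(abs(bandpass(c(pad, w, pad), fs, lo, hi, taps = taps)))
  }
  add_at <- function(j, i0, w) {
    i1 <- i0 + length(w) - 1L
    if (i0 < 1L || i1 > n) stop("inject_events: template exceeds recording bounds")
    data[i0:i1, j] <<- data[i0:i1, j] + w
  }
  truth <- list()
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    i0 <- round(ev$time_s * fs) + 1L
    if (ev$type == "isolated") {
      j <- match(ev$channel, channels$name)
      wms <- if (!is.null(events$width_ms) && is.finite(ev$width_ms)) ev$width_ms else 40
      w1 <- spike_template(fs, wms, 1)
      w <- w1 * ev$amplitude_sd * bg_sd[j] / filtered_gain(w1)
      add_at(j, i0, w)
      truth[[e]] <- data.frame(time_s = ev$time_s + (which.min(w) - 1) / fs,
                               channel = ev$channel, type = "isolated",
                               amplitude_sd = ev$amplitude_sd)
    } else if (ev$type == "swd") {
      # for SWD, amplitude_sd is the target peak-to-peak ratio versus the
      # 1-80 Hz background (median 1-s-window peak-to-peak)
      j <- match(ev$channel, channels$name)
      cyc1 <- swd_cycle_template(fs, ev$rate_hz, 1)
      scale <- ev$amplitude_sd * bg_p2p(data[, j], fs) / diff(range(cyc1))
      w <- rep(cyc1 * scale, ev$n_cycles)
      add_at(j, i0, w)
      truth[[e]] <- data.frame(time_s = ev$time_s, channel = ev$channel,
                               type = "swd", amplitude_sd = ev$amplitude_sd)
    } else if (ev$type == "giant") {
      hc_j <- match(ev$channel, channels$name)   # channel carrying > 10 SD
      g1 <- giant_template(fs, 1)
      gain <- filtered_gain(g1)
      for (j in seq_len(ncol(data))) {
        a_sd <- if (j == hc_j) ev$amplitude_sd else max(8, ev$amplitude_sd / 2)
        w <- g1 * a_sd * bg_sd[j] / gain
        add_at(j, i0, w)
      }
      truth[[e]] <- data.frame(time_s = ev$time_s, channel = ev$channel,
                               type = "giant", amplitude_sd = ev$amplitude_sd)
    } else stop("inject_events: unknown type ", ev$type)
  }
  list(data = data,
       truth = do.call(rbind, truth))
}

# --- cohort ------------------------------------------------------------------

#' Default genotype-by-age effect table for synthetic cohorts
#'
#' One row per (genotype, age_month): shifts applied to the low-gamma
#' envelope Hurst exponent (`H_shift`), an excitation-dominance amplitude
#' offset (`ei_shift`, drives fE/I above 1), the theta-gamma coupling depth
#' (`chi_shift`), and the isolated-spike rate in Hz (`spike_rate`). The
#' default emulates an amyloidosis-like phenotype: from month 6 the affected
#' genotype gains excitation-dominated low-gamma activity, loses coupling
#' depth, and spikes more.
#'
#' @param months integer vector of months.
#' @param genotypes character vector (first = control, second = affected).
#' @param onset_month month at which the affected genotype's shifts start
#'   (default 6).
#' @param ei_shift,chi_deficit,spike_rate_affected affected-genotype effect
#'   sizes from onset.
#' @param spike_rate_base baseline isolated-spike rate (Hz).
#' @return data.frame of effects.
#' @export
cohort_effects <- function(months = c(5, 6), genotypes = c("WT", "APP"),
                           onset_month = 6, ei_shift = 0.6,
                           chi_deficit = -0.3, spike_rate_affected = 0.08,
                           spike_rate_base = 0.02) {
  eff <- expand.grid(genotype = genotypes, age_month = months,
                     stringsAsFactors = FALSE)
  aff <- eff$genotype == genotypes[2] & eff$age_month >= onset_month
  eff$H_shift <- 0
  eff$ei_shift <- ifelse(aff, ei_shift, 0)
  eff$chi_shift <- ifelse(aff, chi_deficit, 0)
  eff$spike_rate <- ifelse(aff, spike_rate_affected, spike_rate_base)
  eff
}

# One synthetic weekly recording: blocked vigilance states; quiet wake
# carries the LRTC low-gamma oscillation, active wake the theta-gamma PAC
# signal, sleep a strong delta oscillation; isolated spikes are injected at
# the prescribed rate. Returns recording + annotation + velocity + truth.
synth_weekly_recording <- function(duration_s, fs, channels, H, chi,
                                   ei_shift, spike_rate, seed,
                                   chi_latent_sd = 0) {
  epoch_s <- 5
  n_ep <- floor(duration_s / epoch_s)
  # blocked states: quiet wake first 50%, active wake 35%, sleep rest
  n_q <- floor(0.5 * n_ep); n_a <- floor(0.35 * n_ep)
  states <- c(rep("quiet_wake", n_q), rep("active_wake", n_a),
              rep("sleep", n_ep - n_q - n_a))
  track <- vigilance_track(states, epoch_s)
  velocity <- with_seed(seed + 11, ifelse(states == "active_wake",
                                          stats::runif(n_ep, 2, 6),
                                          stats::runif(n_ep, 0, 0.5)))
  n <- n_ep * epoch_s * fs
  tt <- (seq_len(n) - 1) / fs
  nch <- nrow(channels)
  data <- matrix(0, n, nch, dimnames = list(NULL, channels$name))
  st <- rep(states, each = epoch_s * fs)
  qw <- st == "quiet_wake"; aw <- st == "active_wake"; sl <- st == "sleep"
  for (j in seq_len(nch)) {
    sj <- seed + 97L * j
    x <- with_seed(sj, stats::rnorm(n, sd = 5))             # broadband noise
    # quiet wake: LRTC low-gamma oscillation (generated per state block)
    osc <- gen_lrtc_oscillation(sum(qw) / fs, fs, c(35, 45), envelope_H = H,
                                amplitude = 12, env_offset = ei_shift,
                                seed = sj + 1)
    x[qw] <- x[qw] + osc$signal
    # active wake: theta + PAC-modulated low gamma
    chi_j <- min(1, max(0, chi))
    pac <- gen_pac_signal(6, 60, chi_j, sum(aw) / fs, fs, amp_fast = 6,
                          seed = sj + 2)
    # modest scale keeps oscillatory bursts well below spike amplitudes
    # (the modulation index is amplitude-scale invariant)
    x[aw] <- x[aw] + 4 * pac$signal
    # sleep: strong delta
    x[sl] <- x[sl] + 15 * sin(2 * pi * 2.5 * tt[sl] + j)
    data[, j] <- x
  }
  # isolated spikes on the first HC channel at the prescribed rate. The
  # fE/I and PAC substrates are cleaned data (epileptiform transients
  # excluded), so spikes are placed in the sleep block: detection is
  # vigilance-agnostic and rates are normalized to the whole recording.
  truth <- NULL
  hc_ch <- channels$name[channels$region == "HC"]
  sleep_t <- range(which(sl)) / fs
  if (spike_rate > 0 && length(hc_ch) && diff(sleep_t) > 5) {
    n_spk <- with_seed(seed + 23, stats::rpois(1, spike_rate * duration_s))
    if (n_spk > 0) {
      t_spk <- with_seed(seed + 29, sort(stats::runif(
        n_spk, sleep_t[1] + 1, sleep_t[2] - 1)))
      # enforce non-overlap
      t_spk <- t_spk[c(TRUE, diff(t_spk) > 0.3)]
      ev <- data.frame(time_s = t_spk, type = "isolated",
                       channel = hc_ch[1], amplitude_sd = 10, width_ms = 40)
      inj <- inject_events(data, fs, channels, ev)
      data <- inj$data
      truth <- inj$truth
    }
  }
  rec <- lfp_recording(data, fs, channels)
  list(recording = rec, track = track, velocity = velocity,
       truth = truth)
}

#' Generate a nested longitudinal synthetic cohort
#'
#' For each pseudo-mouse of each genotype, four weekly recordings per month
#' are generated with blocked quiet-wake / active-wake / sleep structure,
#' channel-nested random offsets, and genotype-by-age shifts applied to the
#' low-gamma envelope criticality, the excitation-dominance offset, the
#' theta-gamma coupling depth and the isolated-spike rate. Fully
#' reproducible under `seed` (per-mouse/per-week streams are derived by
#' fixed offsets from the master seed).
#'
#' @param n_per_genotype mice per genotype.
#' @param months integer vector of age months.
#' @param effects effect table from [cohort_effects()].
#' @param weeks_per_month weekly recordings per month (default 4, the study
#'   design; smaller values scale simulation studies down).
#' @param duration_s weekly recording length in seconds (default 600).
#' @param fs sampling rate in Hz (default 1000).
#' @param base_H baseline envelope Hurst exponent (default 0.8).
#' @param base_chi baseline coupling depth (default 0.55).
#' @param mouse_sd,channel_sd between-mouse and between-channel SDs of the
#'   coupling/criticality offsets.
#' @param channels_per_region named counts, e.g. `c(PFC = 1, PTC = 2, HC = 2)`.
#' @param seed master seed.
#' @return object of class `lfp_cohort`: list with `manifest` (one row per
#'   recording), `recordings`, `tracks`, `velocities` (named lists keyed by
#'   manifest `rec_id`), `spike_truth`, `effects`, `channels`.
#' @export
gen_cohort <- function(n_per_genotype = 3, months = c(5, 6),
                       effects = cohort_effects(months),
                       weeks_per_month = 4,
                       duration_s = 600, fs = 1000, base_H = 0.8,
                       base_chi = 0.55, mouse_sd = 0.03, channel_sd = 0.02,
                       channels_per_region = c(PFC = 1, PTC = 2, HC = 2),
                       seed = 1) {
  genotypes <- unique(effects$genotype)
  channels <- make_channels(channels_per_region)
  manifest <- NULL
  recordings <- list(); tracks <- list(); velocities <- list()
  spike_truth <- list()
  mouse_idx <- 0L
  for (g in genotypes) {
    for (m in seq_len(n_per_genotype)) {
      mouse_idx <- mouse_idx + 1L
      sid <- sprintf("%s_%02d", g, m)
      m_off <- with_seed(seed + 1000L * mouse_idx, stats::rnorm(1, sd = mouse_sd))
      for (mo in months) {
        eff <- effects[effects$genotype == g & effects$age_month == mo, ]
        if (!nrow(eff)) stop("gen_cohort: no effects for ", g, " month ", mo)
        for (wk in seq_len(weeks_per_month)) {
          week <- (mo - months[1]) * weeks_per_month + wk
          wseed <- seed + 1000L * mouse_idx + 50L * match(mo, months) + wk
          sw <- synth_weekly_recording(
            duration_s, fs, channels,
            H = base_H + eff$H_shift + m_off,
            chi = base_chi + eff$chi_shift + m_off,
            ei_shift = eff$ei_shift,
            spike_rate = eff$spike_rate, seed = wseed)
          rid <- sprintf("%s_m%02d_w%d", sid, mo, wk)
          sw$recording$subject_id <- sid
          sw$recording$age_week <- week
          sw$recording$age_month <- mo
          recordings[[rid]] <- sw$recording
          tracks[[rid]] <- sw$track
          velocities[[rid]] <- sw$velocity
          if (!is.null(sw$truth)) {
            sw$truth$rec_id <- rid
            spike_truth[[rid]] <- sw$truth
          }
          manifest <- rbind(manifest, data.frame(
            rec_id = rid, subject_id = sid, genotype = g, age_week = week,
            age_month = mo, stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(manifest = manifest, recordings = recordings,
                 tracks = tracks, velocities = velocities,
                 spike_truth = if (length(spike_truth)) do.call(rbind, spike_truth) else NULL,
                 effects = effects, channels = channels),
            class = "lfp_cohort")
}

#' @export
print.lfp_cohort <- function(x, ...) {
  cat(sprintf("<lfp_cohort> %d recordings, %d mice, months %s\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              paste(unique(x$manifest$age_month), collapse = ", ")))
  invisible(x)
}

# Channel metadata for a synthetic animal.
make_channels <- function(channels_per_region = c(PFC = 1, PTC = 2, HC = 2)) {
  rows <- list()
  hemis <- c("left", "right")
  layers <- c("pyramidal", "pyramidal", "supra_pyramidal", "infra_pyramidal")
  for (reg in names(channels_per_region)) {
    k <- channels_per_region[[reg]]
    for (i in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s%d", reg, i), region = reg,
        hc_layer = if (reg == "HC") layers[(i - 1L) %% 4L + 1L] else "none",
        hemisphere = hemis[(i - 1L) %% 2L + 1L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk
#'
#' Emits the delimited recording files, vigilance annotations, velocity
#' traces and a manifest in the formats the readers consume.
#'
#' @param cohort an `lfp_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"delim"` (default) or `"edf"` for the recordings.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("delim", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (rid in names(cohort$recordings)) {
    rec <- cohort$recordings[[rid]]
    ext <- if (format == "edf") "edf" else "tsv"
    f <- file.path(dir, paste0(rid, ".", ext))
    if (format == "edf") write_edf(rec, f) else write_recording_delim(rec, f)
    write_vigilance_annotation(cohort$tracks[[rid]],
                               file.path(dir, paste0(rid, "_states.tsv")))
    write_velocity(cohort$velocities[[rid]],
                   file.path(dir, paste0(rid, "_velocity.tsv")))
    mrow <- cohort$manifest[cohort$manifest$rec_id == rid, ]
    rows <- rbind(rows, merge(
      data.frame(subject_id = mrow$subject_id, genotype = mrow$genotype,
                 age_week = mrow$age_week, age_month = mrow$age_month,
                 file = basename(f)),
      data.frame(channel = cohort$channels$name,
                 region = cohort$channels$region,
                 hc_layer = cohort$channels$hc_layer,
                 hemisphere = cohort$channels$hemisphere)))
  }
  mf <- file.path(dir, "manifest.tsv")
  write_cohort_manifest(rows, mf)
  invisible(mf)
}
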