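# lfpei

Analysis of longitudinal multichannel local field potential (LFP)
recordings from freely behaving rodents, built around four biomarkers of
network excitation–inhibition balance and their statistical linkage:

* **fE/I — the functional excitation–inhibition ratio.** The LFP is
  band-pass filtered (16 bands spanning 1–150 Hz: one delta band and 15
  log-spaced bands over 4–150 Hz), the amplitude envelope A(t) is
  extracted, and its signal profile is divided into 5-s windows with 80%
  overlap. With w<sub>A</sub> the mean envelope per window and nF the RMS
  of the amplitude-normalized, linearly detrended profile per window,

  **fE/I = 1 − r(w<sub>A</sub>, nF)**  (Pearson),

  so fE/I ≈ 1 indicates balanced excitation/inhibition, > 1 excitation
  dominance, < 1 inhibition dominance. The ratio is computed on quiet-wake
  data (≥ 2 min required) and gated by long-range temporal correlations:
  when the envelope's DFA exponent β < 0.6 the result is a typed missing
  value, never a silent NaN.
* **DFA — detrended fluctuation analysis** of the amplitude envelope:
  β is the log–log slope of the mean detrended fluctuation F(t) versus
  window size, fitted over 0.4–30 s. β ≈ 0.5 means an uncorrelated
  envelope; β > 0.6 long-range temporal correlations.
* **θ–γ PAC — phase–amplitude coupling** via the Kullback–Leibler
  modulation index: θ phase is binned into 18 bins of 20°, the mean γ
  amplitude per bin is normalized to a distribution P, and
  MI = (log 18 + Σ P log P)/log 18 ∈ [0, 1]. Comodulograms cover phase
  2–14 Hz and amplitude 40–200 Hz (cortical) / 40–300 Hz (hippocampal);
  monthly values concatenate a month's active-wake data up to 10 min.
* **Epileptiform events** detected irrespective of vigilance state:
  NEO-proposed spike candidates; spike-wave discharges (≥ 3 cycles,
  ≥ 6 Hz, ≥ 1 s, peak-to-peak > 2× background, episodes < 1 s apart
  merged); giant spikes (simultaneous on all channels, > 10 SD on ≥ 1
  hippocampal channel, > 200 ms positive after-hyperpolarization
  everywhere); isolated hippocampal/cortical spikes (< 100 ms,
  negative-going, no contralateral partner within ± 100 ms). Rates are
  events/s; inter-spike intervals get log-binned histograms.

The statistics layer aggregates weekly values to electrode-months and
mouse-months, runs monthly genotype contrasts (Levene-gated Student/Welch
t-tests, Benjamini–Hochberg across months), and estimates repeated
measures correlations (ANCOVA with subject intercepts and a common slope;
r<sub>rm</sub> = sign(b)·√(SS<sub>x</sub>/(SS<sub>x</sub>+SS<sub>res</sub>)),
dof = N − k − 1) linking fE/I, PAC and spiking — separately per brain
region and genotype, across all 16 fE/I bands.

Because such recordings are rarely shareable, the package ships a
synthetic-LFP generator with exact ground truth — fractional Gaussian
noise envelopes with prescribed Hurst exponent (Davies–Harte circulant
embedding), closed-form θ–γ coupling of prescribed depth, parameterized
event templates, vigilance structure, and nested genotype-by-age cohorts —
so the whole pipeline is testable end to end.

## Worked example

```r
library(lfpei)

# a 200-s low-gamma oscillation whose envelope has Hurst exponent 0.85
o   <- gen_lrtc_oscillation(duration_s = 200, fs = 1000,
                            carrier_band = c(35, 45), envelope_H = 0.85,
                            seed = 42)
env <- amplitude_envelope(bandpass(o$signal, 1000, 35, 45))[2001:198000]

(d <- dfa(env, fs = 1000))
#> <dfa_result> beta = 0.865 (fit 0.4-30 s, R2 = 0.999, 20 sizes)

compute_fei(fei_windows(env, fs = 1000), dfa_beta = d$beta)
#> <fei_result> fE/I = 1.022 (r = -0.022, beta = 0.865, 192 windows)
```

The envelope's fluctuation exponent (0.865) recovers the generator's 0.85
and clears the 0.6 gate; the near-zero amplitude–fluctuation correlation
yields fE/I ≈ 1 — the balanced regime expected for a symmetric
multiplicative envelope.

```r
p  <- gen_pac_signal(f_phase = 6, f_amp = 60, chi = 0.8, duration_s = 60,
                     fs = 1000, seed = 7)
g  <- list(phase = data.frame(center = 6,  lo = 5,  hi = 7),
           amp   = data.frame(center = 60, lo = 50, hi = 70))
comodulogram(p$signal, 1000, g)
#> <comodulogram> 1 phase x 1 amplitude bands, 1.0 min used; max MI = 0.0336
```

An 80%-deep 6-Hz modulation of a 60-Hz rhythm yields MI = 0.034 through
the full filter–Hilbert path, within 0.01 of the value computed directly
from the known modulator.

For cohorts: `gen_cohort()` builds a nested synthetic study,
`run_all()` produces fE/I spectra, monthly PAC, event catalogs, genotype
contrasts and the three repeated-measures-correlation sweeps in one call.
See the methods vignette (`vignettes/lfpei-methods.Rmd`) for the model
details and every numerical choice.

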