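---
title: "Methods: functional E/I, temporal correlations, theta-gamma coupling and epileptiform events in rodent LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional E/I, temporal correlations, theta-gamma coupling and epileptiform events in rodent LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpei)
```

# Scope

`lfpei` analyses longitudinal multichannel local field potential (LFP)
recordings from freely behaving rodents, with four measurement stages and a
statistics layer:

1. the **functional excitation-inhibition ratio (fE/I)** per channel, week
   and frequency band, gated by detrended fluctuation analysis (DFA);
2. **theta-gamma phase-amplitude coupling (PAC)** per channel and month via
   the Kullback-Leibler modulation index (MI);
3. rule-based **epileptiform event detection** (isolated hippocampal and
   cortical spikes, spike-wave discharges, giant spikes) with rates and
   log-binned inter-spike-interval histograms;
4. **vigilance-state scoring** into active wake / quiet wake / sleep per
   5-s epoch, which routes data to the right analysis (quiet wake for fE/I,
   active wake for PAC, all states for events);
5. longitudinal aggregation, genotype contrasts and repeated measures
   correlations linking the three biomarkers.

A synthetic-LFP generator with exact ground truth (envelope Hurst exponent,
coupling depth, injected events, nested cohort structure) makes every stage
testable without animal data.

# The fE/I ratio

Oscillation amplitude in a narrow band carries two kinds of information:
its level, and the temporal structure of its fluctuations. In a network
where excitation dominates, bursts of high amplitude are self-reinforcing
and *relatively* less variable once normalized; where inhibition dominates,
high-amplitude excursions are actively quenched. The fE/I algorithm turns
this into a statistic:

* filter the LFP into a band (e.g. low gamma, raw edges 35.2-44.8 Hz,
  displayed "35-45 Hz") with a zero-phase FIR and extract the amplitude
  envelope via the Hilbert transform;
* build the signal profile (cumulative sum of the demeaned envelope) and
  slide 5-s windows with 80% overlap across it;
* per window, record the mean envelope amplitude `w_amp`, divide the
  profile segment by `w_amp`, detrend it linearly, and take the residual
  RMS as the normalized fluctuation `nF`;
* `fE/I = 1 - cor(w_amp, nF)` (Pearson). Values near 1 indicate balance,
  above 1 excitation dominance, below 1 inhibition dominance.

The statistic is only meaningful when the envelope shows long-range
temporal correlations, so it is gated: if the DFA exponent of the same
envelope is below 0.6, the result is a *typed* missing value (`low_dfa`).
Other typed reasons are `too_short` (fewer than 40 windows, about what the
2-minute minimum yields at 1-s steps) and `degenerate` (zero variance in
either window series). Missingness is never a silent `NaN`, so aggregation
can report per-reason counts.

Analysis is restricted to quiet wake. Contiguous quiet-wake intervals are
concatenated only if they total at least 2 minutes; otherwise the recording
is excluded outright for that week. Filtering and envelope extraction
happen *per interval before* concatenation, and analysis windows are laid
out within intervals, so no window ever straddles a splice.

## The spectral grid

Sixteen bands cover 1-150 Hz: one delta band (1-4 Hz) and fifteen
geometrically spaced bands `e_k = 4 * (150/4)^(k/15)`. Adjacent edges
coincide exactly; display labels round raw edges to the nearest 0.5 Hz
(e.g. raw 35.19-44.77 Hz is "35-45 Hz"), but computation always uses raw
edges. One printed-label convention cannot reproduce every label variant
seen in practice; the raw geometric edges are authoritative here and the
labels cosmetic.

# DFA of the amplitude envelope

The envelope's signal profile is split into 20 log-spaced window sizes
spanning the fit range 0.4-30 s (capped at a quarter of the data), with
50% overlap; each window is linearly detrended (DFA-1) and the RMS of the
residual averaged per size. The DFA exponent is the least-squares slope of
`log10 F` versus `log10 size` restricted to the fit range. An exponent
near 0.5 indicates an uncorrelated envelope; above 0.6 is taken as
long-range temporal correlation, the regime where fE/I is interpretable.

DFA runs on the concatenated quiet-wake envelope with seam-respecting
windows (windows are laid within intervals and pooled), and the profile is
demeaned by the pooled mean so segments are comparable.

Note a structural property visible in the band-resolved output: very
narrow low bands (the 1-4 Hz band especially) have envelope coherence
times comparable to the smallest fit windows, which inflates the fitted
exponent at the short-window end. This is a property of band-limited
envelopes, not an artifact of this implementation; it is one reason the
fE/I literature interprets band profiles jointly rather than a single band
in isolation.

# Theta-gamma PAC

For a phase band (theta) and an amplitude band (gamma), the Hilbert phase
of the former is binned into 18 bins of 20 degrees and the mean amplitude
of the latter is computed per bin. Normalizing the bin means to a
distribution `P` and measuring its Kullback-Leibler distance from uniform
(natural log; `0*log 0 := 0`) gives `MI = (log 18 + sum P log P)/log 18`,
bounded in [0, 1]: 0 for amplitude independent of phase, 1 for all
amplitude mass in one bin.

Comodulogram grids follow the centre-frequency convention: phase centres
2-14 Hz in 1-Hz steps with 2-Hz bandwidth; amplitude centres 40-200 Hz
(1-Hz steps, 2-Hz bandwidth) for cortical channels and 40-300 Hz (2-Hz
steps, 4-Hz bandwidth) for hippocampal channels. Amplitude bands above
Nyquist are truncated with a warning rather than erroring. Summaries
average MI over theta (4-10 Hz) against low gamma (40-90 Hz), high gamma
(90-160 Hz), and - hippocampal channels only - total gamma (40-300 Hz).

Monthly PAC concatenates a month's weekly active-wake intervals in
chronological order and truncates to 10 minutes (first-in-month when more
are available); months with less than 10 minutes are flagged as shortfall
but kept.

# Epileptiform event detection

Detection runs on the whole recording irrespective of vigilance state and
is amplitude-scale invariant (all thresholds are relative).

**Candidates.** Each channel is filtered to 5-200 Hz and passed through
the nonlinear energy operator. For LFP interictal spikes (tens of
milliseconds wide) the canonical lag-1 operator responds as
`A^2 sin^2(2*pi*f/fs)`, which at a 1 kHz rate is nearly blind to a 12-Hz
transient, so the detector uses the lagged (multiresolution) form
`psi_k[n] = x[n]^2 - x[n-k]x[n+k]` with a 10-ms lag, Bartlett-smoothed
over 8 ms and thresholded at 8 times its mean. Because the NEO energy of
such slow transients still overlaps the colored-noise background,
candidates below 5 robust SDs (1.4826 * MAD of the filtered trace,
excluding candidate windows) are discarded - consistent with the
amplitude-referenced definitions of every downstream event class. Runs
closer than 30 ms merge into one candidate; polarity and width (duration
above half the peak magnitude) are measured on the filtered trace.

**Spike-wave discharges** (prefrontal channels): cycle peaks are sharp
negative local minima of the 1-80 Hz trace (at least 3 robust SDs deep,
at least 60 ms apart); peaks whose successive intervals sustain >= 6 Hz
are grouped, and a group is an episode iff it has >= 3 cycles, lasts
>= 1 s (counting one full period beyond the first-to-last peak span, so 8
cycles at 7 Hz last 8/7 s) and its peak-to-peak amplitude exceeds 2x
background (median 1-s-window peak-to-peak of the surrounding trace,
excluding events). Episodes separated by < 1 s merge.

**Giant spikes**: a candidate time is giant iff a candidate exists on
*every* channel within +-10 ms, the amplitude exceeds 10 robust SDs on at
least one hippocampal channel, and the raw-trace mean over the following
200 ms is positive on all channels (the after-hyperpolarization).

**Isolated spikes**: remaining hippocampal candidates that are brief
(< 100 ms), negative-going, and have no contralateral-hippocampal
candidate within +-100 ms; the same rule on parietal channels gives
isolated cortical spikes. With no contralateral channel the pairing rule
passes vacuously and the result carries a caveat flag.

Rates are event counts normalized by recording duration (Hz).
Inter-spike-interval histograms use 24 logarithmically spaced bins over
0.05-200 s by default (log binning stabilizes the sparse long-interval
tail); out-of-range intervals clamp into the end bins so counts always sum
to `n - 1`.

# Vigilance scoring

Per 5-s epoch: velocity above 1 cm/s is active wake; otherwise a
delta/theta power ratio (mean squared envelope of the 1-4 Hz band over the
4-10 Hz band) at or above 1.5 is sleep, below it quiet wake. The two
thresholds are declared stand-ins - the scoring procedure this simplifies
is calibrated per laboratory - and synthetic cohorts carry ground-truth
state labels, so no downstream test depends on them.

# Longitudinal statistics

**Aggregation** is two-stage: weekly values average to electrode-months,
electrode-months to mouse-months; typed-missing values are excluded from
means and the electrode-month intermediate is retained for channel-level
matching.

**Genotype contrasts** per month use Levene's test (classic form: ANOVA on
absolute deviations from the group mean, alpha 0.05) to choose between the
unpaired Student's t-test (equal variance) and Welch's t-test, with
Benjamini-Hochberg correction across the months at q = 0.05.

**Repeated measures correlation** estimates the common within-subject
association between two repeatedly measured variables by ANCOVA: `y` on
subject indicators plus a common slope on `x`;
`r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_res))` with
`dof = N - n_subjects - 1`; the confidence interval uses the Fisher z
transform with standard error `1/sqrt(dof - 1)`. Subjects with fewer than
two pairs or zero x-variance carry no slope information and are dropped
(recorded in the result). The three linkage analyses match (1) monthly
electrode-level fE/I with monthly PAC per (subject, channel, month);
(2) weekly channel-averaged fE/I with weekly spike rates, excluding
zero-rate weeks; (3) monthly mean PAC with monthly mean spike rates,
excluding zero-rate months. Every analysis runs separately per brain
region (the three hippocampal CA1 layers and the parietal cortex are never
pooled) and per genotype. Band sweeps report one coefficient per fE/I
band at a fixed primary threshold alpha = 0.01, with 0.01-0.05 flagged as
marginal and no formal correction across the 16 bands - a deliberate,
documented convention rather than a formal multiplicity control.

A `bmlm_export()` writer emits one analysis-ready tidy table per metric
(`value, genotype, age_month, mouse, channel`) for any multilevel fitter;
fitting Bayesian multilevel models is intentionally out of scope.

# Numerical choices

* **Filters** are odd-length Hamming-window FIRs applied as centred
  convolutions (zero phase). The order covers at least 3 cycles of the
  band's low edge *and* keeps the transition width below a quarter of the
  bandwidth, so the realized noise bandwidth matches an ideal rectangular
  mask within ~10%. The one deliberate exception: comodulogram *amplitude*
  bands use only the loose 3-cycle rule, because an amplitude filter
  sharper than the phase frequency strips the modulation sidebands
  (centre +- f_phase) that PAC is supposed to measure - the classic PAC
  practice.
* **Filtering + Hilbert** are fused in the frequency domain: each segment
  is odd-reflection padded and transformed once; every band multiplies by
  its cached FIR transfer function and the analytic mask before one
  inverse transform. Envelope values agree with the sequential
  filter-then-transform construction to ~0.1% in the trimmed interior.
* **Edge trimming**: two cycles of the band's low edge are dropped from
  each side of every filtered interval before any windowed analysis.
* **DFA inner loop** uses closed-form linear detrending from cumulative
  sums (O(n) per window size), re-anchoring each window at its start for
  conditioning; windows whose residual nearly cancels are recomputed
  exactly. Agreement with an explicit per-window regression is ~1e-13.
* **fGn generation** uses exact circulant embedding (Davies-Harte):
  eigenvalues of the embedded covariance shape independent complex
  normals, so the sample autocovariance is exact in expectation at all
  lags. Non-positive-definite embeddings raise an error.
* **Phase bins** are half-open, starting at -180 degrees; natural log in
  the KL distance (MI is log-base invariant; declared for bit-exactness).
* **Ties/degeneracies**: zero-variance window series yield typed missing
  values; empty phase bins raise an informative error; flat EDF channels
  get a unit physical range to keep calibration finite.

# The synthetic generator

`gen_lrtc_oscillation()` multiplies a sinusoidal carrier at the band's
geometric centre with a geometric (exponentiated, scaled) fGn envelope -
exponentiation keeps the envelope positive without the clipping that would
destroy its long-range correlations. An optional slow additive amplitude
offset (`env_offset`) breaks the amplitude/fluctuation symmetry and pushes
fE/I above 1, emulating excitation dominance; the default is the balanced
regime. `gen_pac_signal()` uses the closed-form modulator
`a(t) = 1 - chi + chi(1 + cos(2 pi f_phase t))/2`, so the expected MI is
computable directly from `a(t)` and the slow phase. Event injection uses
parameterized waveforms (biphasic spikes with a dominant negative lobe;
spike-wave cycles as sharp negative spike plus slow positive wave; giant
spikes with a sustained positive tail on all channels), calibrated in
robust-SD units of the pre-injection 5-200 Hz background - except SWD
trains, whose amplitude parameter is the target peak-to-peak ratio versus
the 1-80 Hz background, matching the rule that detects them.

`gen_cohort()` nests everything longitudinally: per genotype and mouse,
weekly recordings per month with blocked quiet-wake (50%), active-wake
(35%) and sleep (15%) states, mouse-level random offsets on criticality
and coupling, and genotype-by-age shifts (`cohort_effects()`) on the
low-gamma envelope criticality, the excitation offset, the coupling depth
and the spike rate. The default affected-genotype phenotype - excitation
offset 0.6 (raising low-gamma fE/I by about 0.2, the scale of reported
genotype differences), coupling deficit -0.3 and a four-fold spike-rate
increase from month 6 - emulates an amyloidosis-like progression. Spikes
are placed in the sleep block because the fE/I and PAC substrates are
*cleaned* data (epileptiform transients excluded upstream in real
pipelines, and inputs here are assumed pre-cleaned); detection is
vigilance-agnostic, so rates are unaffected. The default sampling rate is
1000 Hz (configurable); one master seed drives fixed per-mouse/per-week
substreams, so cohorts are fully reproducible.

What the generator does *not* emulate: biophysical network dynamics,
1/f-mixed state transitions, movement or technical artifacts, electrode
drift, volume conduction between channels (channels are independent), or
genuine coupling between the planted biomarkers beyond the programmed
effect structure. Passing tests therefore demonstrate that the pipeline
recovers known statistical structure at realistic scales - not that it is
robust to every failure mode of real recordings.

# Problem sizes used by the test suite

The validation suite exercises the study design at desk scale: weekly
recordings of 250-300 s at 400-500 Hz (50% quiet wake, satisfying the
2-minute rule), cohorts of 3 mice per genotype over 2 months with 3
weekly recordings per month, parameter-recovery runs of 200 s at 1 kHz,
and event benchmarks on 600-s traces. Replicated end-to-end checks use
5 planted-effect and 3 null cohorts; metric-level power checks use
400 replicates. These sizes are the package's validation design; the
functions themselves impose no such limits.

# Known limitations

* The fE/I DFA gate uses each band's own envelope exponent; a broadband
  gate would be a one-line change but is not the default.
* Narrow low bands inherit an upward DFA bias at short window sizes (see
  above); compare bands jointly.
* The vigilance scorer is a two-threshold stand-in; use recorded
  annotations when available.
* The NEO amplitude criterion and the SWD cycle-peak picker are calibrated
  for LFP-scale transients; action-potential-scale data would need a
  shorter lag and smoothing window.
* EDF support covers plain continuous EDF with one sampling rate across
  signals (the common case for LFP arrays), not EDF+ annotations or
  discontinuous records.
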