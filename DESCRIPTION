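Package: lfpei
Title: Functional Excitation-Inhibition Ratio, Temporal Correlations and
    Theta-Gamma Coupling Analysis for Rodent LFP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for longitudinal multichannel local field
    potential (LFP) recordings from freely behaving rodents. Implements the
    functional excitation-inhibition (fE/I) ratio computed from windowed
    oscillation amplitude and amplitude-normalized detrended fluctuations,
    gated by detrended fluctuation analysis (DFA) of the amplitude envelope;
    theta-gamma phase-amplitude coupling via the Kullback-Leibler modulation
    index with comodulograms and band-averaged summaries; rule-based detection
    of epileptiform events (nonlinear-energy-operator spike candidates,
    spike-wave discharges, giant spikes, isolated hippocampal and cortical
    spikes) with rates and log-binned inter-spike-interval histograms;
    vigilance-state scoring from delta/theta power ratio and locomotion
    velocity; longitudinal weekly-to-monthly aggregation, genotype contrasts
    (Levene-gated Student/Welch t-tests with FDR correction) and repeated
    measures correlations linking fE/I, coupling and spiking. A synthetic-LFP
    generator with controllable envelope Hurst exponent, coupling depth,
    injected events and nested cohort structure provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
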