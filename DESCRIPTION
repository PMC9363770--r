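Package: freqtag
Title: Frequency-Tagged EEG Analysis by Inter-Trial Phase Coherency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of frequency-tagged steady-state visual evoked potential
    (SSVEP) experiments from single-channel EEG trials. Implements per-trial
    phase extraction at 0.2 Hz resolution, inter-trial phase coherency with a
    bootstrapped white-noise null threshold (95th percentile of 10,000
    matched-size surrogate datasets), detection of stimulus harmonics,
    trial-level pooling across participants, Morlet-wavelet event-related
    spectral perturbation (ERSP) and inter-trial coherence (ITC) maps with
    bootstrap significance masking, and Monte-Carlo trial-budget planning
    (required trial counts for a target detection probability at a given
    signal-to-noise ratio, and the inverse). A synthetic single-channel EEG
    generator emulating a square-wave depth-alternation stereogram experiment
    (harmonic response, 1/f plus white noise, mains interference,
    non-phase-locked band-power perturbations, artifacts) provides a
    ground-truth testbed for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
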