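---
title: "Phase-coherency analysis of frequency-tagged EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coherency analysis of frequency-tagged EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqtag)
```

## The statistic and its assumptions

A frequency-tagging experiment drives the visual system with a stimulus that
is strictly periodic — here a disparity plane alternating as a 50% duty-cycle
square wave at f₀ = 2.1 Hz — and looks for that periodicity in the EEG. The
package's core statistic is the inter-trial phase coherency: for each trial,
the FFT of the 5 s window starting at stimulus onset gives one complex
number per 0.2 Hz bin; the amplitude is discarded and only the unit phasor
is kept. The coherency at a bin is the resultant length of the n trial
phasors,

$$R(f) = \Big|\tfrac{1}{n}\sum_{j=1}^{n} e^{i\varphi_j(f)}\Big| \in [0,1].$$

Two assumptions make this work: the stimulus frequency and phase are
identical in every trial (the trials are cut at photodiode-grade onsets, so
the depth alternation is in the same phase across trials), and the
propagation delay through the visual system is near-constant across trials.
Under those assumptions a driven component keeps the same phase in every
trial and R approaches 1, while any signal not locked to the stimulus has
uniformly distributed phase and R concentrates near zero as n grows.

Because phases of noise are uniform *by principle*, the null distribution of
R does not depend on the noise spectrum. The detection threshold is built by
a bootstrap: `null_threshold()` generates B = 10,000 surrogate datasets of n
white-noise trials, computes R for each, and takes the 95th percentile per
frequency. The default fast path draws i.i.d. uniform phases directly; the
equivalence with full white-noise time series is *tested* (not assumed) in
the suite. For the resultant length the null tail is Rayleigh,
P(R > r) ≈ exp(−n r²), so the 95th percentile is ≈ √(ln 20 / n):
0.150 at n = 134 and 0.075 at n = 534 — which is why pooling trials across
participants pays off: the pooled coherency value drops a little (different
propagation delays), but the threshold drops as 1/√n.

A `ci_fraction` estimator (one minus the width of the empirical 95%
confidence interval of the phase angles as a fraction of the full circle) is
provided as a secondary estimator. The resultant length is the default: it
is the standard ITC estimator and its null reproduces the bootstrap
thresholds through the Rayleigh closed form, which serves as the analytic
oracle in the tests.

### Harmonics and the analysis grid

A 50% duty-cycle square wave contains only odd harmonics with strictly
decreasing amplitudes (`square_wave_harmonic_amplitude()`); energy at the
*even* harmonics of the alternation frequency in the EEG therefore indicates
a nonlinear (rectified) neural transformation rather than stimulus
leak-through. Detection is evaluated at the first six harmonics of 2.1 Hz.
The 5 s window fixes the grid at 0.2 Hz, so the even harmonics (4.2, 8.4,
12.6 Hz) fall exactly on bins while the odd ones (2.1, 6.3, 10.5 Hz) fall
half a bin off. `detect_harmonics()` evaluates at the nearest bin and
reports the offset. For a phase-locked component the off-bin penalty is an
amplitude loss only (the leaked phase is identical across trials), so
nearest-bin evaluation costs sensitivity, not validity;
`extract_phases(pad_factor = 2)` places bins exactly on all harmonics when
that matters. The per-harmonic p-values are exceedance ranks in the retained
null sample and are deliberately not corrected for the family of six tests,
mirroring standard practice for this rule; reports should state the family
size.

## The synthetic generator

The generator is the package's ground truth. It does not model dot patterns
or rectification mechanisms; it parameterises the response directly at the
observation level — per-harmonic amplitudes and onset-locked phases — so a
test can place energy exactly where a hypothesis puts it. A trial is

* a pre-period of 1–1.5 s (uniform) of noise only, then 5–6 s (uniform) of
  stimulus, at 1 kHz;
* a phase-locked response: Σₖ aₖ cos(2π k f₀ (t − latency) + φₖ + j), with a
  per-trial phase offset j ~ N(0, σ²) common to all harmonics and a fixed
  per-participant latency that shifts harmonic k by 2π k f₀ · latency — this
  is what makes trial-level pooling across participants cheap at low
  harmonics and expensive at high ones;
* noise: white Gaussian (default sd 5 µV) + 1/f^γ (γ = 1, RMS 15 µV,
  flattened below 0.5 Hz) + 50 Hz mains (5 µV, random phase per trial);
* optional band-power perturbations from onset onward, implemented by
  scaling the Fourier components of the post-onset noise inside the band —
  the band power changes by exactly the requested dB while the component
  phases stay random per trial, so the perturbation is powerful in ERSP and
  invisible to coherency.

Condition presets mirror the two stimulus classes the analysis
distinguishes: a correlated-like response on the even harmonics (amplitude
ratios 1 : 0.5 : 0.25 at k = 2, 4, 6) at broadband time-domain SNR 0.5, and
an anticorrelated-like response on the first harmonic alone at SNR 0.1. The
phase-jitter default of 1.5 rad was set once so that the driven-harmonic
coherency of the synthetic pooled data lands at the ~0.3 scale real
recordings show; with jitter 0 the no-noise coherency is exactly 1, which
the tests use as an exact oracle. The broadband SNR target is enforced
per trial: the noise of each trial is rescaled so that response power over
noise power in the 5 s analysis window equals the target exactly.

What the generator does *not* emulate: onset ERPs, non-stationary or
heavy-tailed noise, electrode drift, intermodulation "birdie" peaks, or any
spatial structure (it is single-channel by design). Tests passing on this
generator therefore certify the statistics and the pipeline plumbing, not
robustness to every pathology of real recordings.

## Preprocessing

Filtering is zero-phase (forward–backward) Butterworth: high-pass order 2 at
0.1 Hz, low-pass order 8 at 70 Hz, band-stop order 2 at 48–52 Hz. Zero-phase
application is mandated because the analysis lives in phase space: a causal
filter would add frequency-dependent phase offsets — harmless for coherency
magnitude, not for any cross-condition phase comparison. The low-pass order
was chosen so the realized response is ≥ 20 dB down at 80 Hz
(`measure_filter_response()` reports the realized curve, which is recorded
with the data rather than trusted from the design). Artifact rejection is a
single-channel stand-in for the multi-channel rules used with full caps: an
absolute 200 µV peak-to-peak ceiling and a robust (median/MAD) z > 5 ceiling
on trial variance. It preserves the function — excluding contaminated
trials — in a form that is testable against the generator's blink and
noisy-trial injections.

## Time–frequency maps

ERSP maps are Morlet-wavelet power averaged over trials and expressed per
cell as 10·log₁₀(P(t,f)/B(f)) against the mean pre-onset baseline at the
same frequency; ITC maps are resultant lengths of per-trial wavelet phases.
The kernel default is n_cycles = 2f — a constant 0.5 Hz spectral sd and
~0.32 s temporal sd. This choice is driven by the 1 s guaranteed baseline: a
wider kernel (e.g. 3f, sd 0.48 s) leaves less than one independent baseline
sample per trial and leaks post-onset power into the baseline, while a much
narrower one blurs the 8–12 Hz band into its neighbours. Cells closer than
0.45 s (≈ 2 energy-sds) to the onset are excluded from the baseline mean for
the same reason.

Band summaries average cells whose kernel center lies strictly *inside* the
band: a cell centered exactly on a band edge measures half of its power
outside the band, and including the 8 and 12 Hz cells would bias a +1 dB
alpha injection down to ~0.8 dB. With interior cells the injection is
recovered at 1.00 ± 0.09 dB (sd over seeds) at the 540-trial scale. The
summary averages all cells in the band-window by default; restricting to
significant cells (`use_mask = TRUE`) is available but not the default,
because conditioning an effect-size estimate on its own significance inflates
it.

The significance mask is a per-cell, uncorrected bootstrap in the spirit of
the common EEG tooling: each null draw resamples trials with replacement
*and* a random baseline latency per trial, giving the distribution of a
baseline cell mean under both sources of sampling variation. Resampling
latencies alone is not enough: 1/f noise power is long-range correlated in
time, so within-trial latency choice underestimates the across-trial
variance and inflated the false-positive rate to ~30% in development; with
trial resampling the rate is nominal. ITC cells are masked against the
(1 − α) quantile of the resultant length of n uniform phases.

One caveat the maps make visible: with a broadband-SNR-0.5 even-harmonic
response, the alpha band summary picks up leakage from the 8.4 Hz harmonic
(the 9 Hz cell sits 1.2 spectral sds away). Band effects should be read off
perturbation-style datasets or bands away from the driven harmonics.

## Trial planning: what "SNR" has to mean

`required_trials(s)` is the smallest n whose Monte-Carlo detection
probability at the driven harmonic reaches 80% (bracketing plus bisection
over replicate experiments run through the generator and the coherency
detector); `estimate_snr_from_trials(n)` is its inverse by bisection on the
log-SNR axis. The planning SNR is defined **within the analysis bandwidth**
of the driven harmonic (the 1/T = 0.2 Hz matched band), not as a broadband
power ratio. The reason is arithmetic, not taste: a 5 s window at 1 kHz has
a coherent processing gain of N/2 = 2500 at a bin, so *any* broadband
response-to-noise ratio of 0.5 would make the driven bin overwhelming and
detection trivial at 2–3 trials, independent of the noise spectrum; trial
counts in the tens to hundreds, an invertible n(s) relationship, and the
superiority of phase pooling over amplitude evaluation all live in the
weak-per-bin-signal regime. With the matched-band definition the per-trial
bin SNR equals s exactly, and the simulated counts land at the right scale
(~15–25 trials at s = 0.5, ~50–80 at s = 0.1 for 80% power; amplitude-based
evaluation needs a few times more at 0.5 and an order of magnitude more at
0.1). Because the calibration is in-band, the result is invariant to the
broadband noise shape, and the planning default uses white noise only.

The "spectral evaluation" comparator is the across-trial mean Fourier
magnitude at the driven bin, normalised by flanking bins, against its own
white-noise null (simulated directly from Rayleigh magnitudes — the same
fast-path logic as the phase null). Phase pooling integrates coherently
(required n ∝ 1/s), magnitude averaging incoherently (n ∝ 1/s²), which is
the whole argument for doing this analysis in phase space; the package
tests the ordering, not any particular ratio. Detection probability is a
noisy function of n, so both searches use common random numbers across
candidate values and an early-stopping rule on the replicate batches; the
80% power target is a convention of this package (the method literature
rarely states one) and the searches expose it as a parameter.

## Numerical choices and degenerate inputs

* Phases live in (−π, π] (`Arg()`); coherency of n < 2 trials is an error,
  as is an all-rejected trial set (the statistic is undefined).
* Surrogate counts: B = 10,000 for reported thresholds (Monte-Carlo error of
  the 95th percentile ≈ 0.001 at n = 534); tests use B = 2,000–3,000 with
  tolerances set to ~3 Monte-Carlo standard errors.
* The trial matrix is trimmed to the shortest pre/post extent so sets are
  rectangular; duration randomisation beyond the 5 s analysis window
  therefore only affects the baseline available to the ERSP.
* Wavelet transforms reflect-pad trials; empirically the stationary-noise
  ERSP profile shows no edge bias at the grid extremes.
* Every stochastic operation takes an explicit seed; dataset generation
  derives per-trial-set seeds deterministically from the master seed, and
  `run_pipeline()` writes a manifest with the configuration hash and MD5 of
  every output, so a run is reproducible byte for byte.
* Problem sizes in the shipped tests (hundreds of trials, B in the low
  thousands, ≤ 100 planning replicates) were chosen as the smallest sizes at
  which each assertion's Monte-Carlo error is comfortably inside its
  tolerance.

## Known limitations

* The `ci_fraction` estimator is a plain empirical-quantile construction;
  its exact correspondence to published confidence-interval coherency
  formulations is approximate, and thresholds quoted in this package are for
  the resultant length.
* Printed trial-count brackets from the experimental literature (e.g. 60–80
  trials at s = 0.5) are treated as calibration corridors: the simulated
  counts land at the same order but depend on the jitter and power-target
  conventions above, which field reports rarely pin down.
* p-values are per-harmonic and uncorrected (family size 6, stated in the
  detection output); "only harmonic k detected" statements are statements
  about confident detections, since a 5% per-bin rule exceeds its threshold
  at null bins at the nominal rate by construction.
* EDF ingest is not provided; the on-disk interchange format is the TSV
  matrix + JSON sidecar of `write_trialset()`.
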