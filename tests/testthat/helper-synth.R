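# Shared fixtures, built in code.

# Fixed-duration schedule: exactly 1 s pre, 5 s stimulus, at 1 kHz.
quick_schedule <- function(f0 = 2.1, fs = 1000) {
  stimulus_schedule(f0 = f0, pre_range = c(1, 1), stim_range = c(5, 5), fs = fs)
}

# Silent noise model (for noise-free phase-lock limits).
no_noise <- function() noise_model(white_sd = 0, pink_sd = 0, mains_amp = 0)

# A deterministic phase-locked trial set: every trial is the same sum of
# cosines at the given frequencies, beginning at onset.
locked_set <- function(n = 10, freqs = 4.2, amps = 1, phases = 0,
                       fs = 1000, pre = 1, post = 5) {
  n_pre <- round(pre * fs); n_post <- round(post * fs)
  t <- (0:(n_post - 1)) / fs
  sig <- rowSums(vapply(seq_along(freqs), function(k) {
    rep(amps[min(k, length(amps))], n_post) *
      cos(2 * pi * freqs[k] * t + phases[min(k, length(phases))])
  }, numeric(n_post)))
  dat <- matrix(rep(c(numeric(n_pre), sig), each = n), n)
  trialset(dat, fs = fs, onset = n_pre + 1L)
}

# Noise-only trial set from the generator.
noise_set <- function(n, seed, noise = noise_model(), perturbations = list(),
                      f0 = 2.1) {
  simulate_trials(n, quick_schedule(f0 = f0), response_model(0),
                            noise, perturbations, seed = seed)
}
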