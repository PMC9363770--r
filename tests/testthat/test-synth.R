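test_that("square-wave disparity toggles between +/- amplitude at the alternation period", {
  sch <- stimulus_schedule(f0 = 2.1, disparity_amp = 0.05)
  w <- square_wave_disparity(sch, pre_duration = 1, stim_duration = 5)
  onset <- attr(w, "onset")
  expect_identical(onset, 1001L)
  expect_true(all(w[1:(onset - 1)] == 0))
  post <- w[onset:length(w)]
  expect_setequal(unique(post), c(0.05, -0.05))
  # period 1/2.1 s ~ 476.2 ms: first downward switch at duty * period
  first_neg <- which(post < 0)[1]
  expect_equal((first_neg - 1) / sch$fs, 0.5 / 2.1, tolerance = 6e-3)
  # a full period later the waveform is positive again
  expect_gt(post[first_neg + round(0.5 / 2.1 * sch$fs)], 0)

  # zero amplitude: identically zero
  w0 <- square_wave_disparity(stimulus_schedule(disparity_amp = 0))
  expect_true(all(w0 == 0))

  expect_error(stimulus_schedule(duty = 0), "duty")
  expect_error(stimulus_schedule(duty = 1.2), "duty")
  expect_error(stimulus_schedule(f0 = 2.1, fs = 6), "4 samples")
})

test_that("50% duty cycle square wave has only odd harmonics, strictly decreasing", {
  k <- 1:12
  a <- square_wave_harmonic_amplitude(k, duty = 0.5)
  expect_equal(a[k %% 2 == 0], rep(0, 6))
  odd <- a[k %% 2 == 1]
  expect_true(all(diff(odd) < 0))
  # cross-check against an FFT of the sampled waveform at parameters where
  # whole periods fit the window exactly (f0 = 2 Hz, 10 s)
  sch <- stimulus_schedule(f0 = 2, pre_range = c(1, 1), stim_range = c(10, 10))
  w <- square_wave_disparity(sch, 1, 10)
  post <- w[attr(w, "onset"):length(w)]
  X <- 2 * Mod(fft(post)) / length(post)
  bins <- k * 2 * 10 + 1  # harmonic bins on the 0.1 Hz grid
  expect_equal(X[bins[k %% 2 == 0]], rep(0, 6), tolerance = 1e-12)
  expect_equal(X[bins[k %% 2 == 1]],
               square_wave_harmonic_amplitude(k[k %% 2 == 1], amp = 0.05),
               tolerance = 2e-3)
})

test_that("trial generation is seed-deterministic and phase-locked in the noise-free limit", {
  t1 <- generate_trial(seed = 7)
  t2 <- generate_trial(seed = 7)
  expect_identical(t1$data, t2$data)
  expect_gte(t1$onset, t1$fs * 1.0)
  expect_gte(ncol(t1$data) - t1$onset + 1, 5 * t1$fs)

  # no jitter, no noise: coherency is exactly 1 at every driven harmonic
  resp <- response_model(c(0, 1, 0, 0.5, 0, 0.25), phase_jitter_sd = 0,
                         latency = 0.1)
  ts <- simulate_trials(20, quick_schedule(), resp, no_noise(),
                                  seed = 3)
  cs <- coherency(ts)
  for (f in c(4.2, 8.4, 12.6)) {
    i <- which.min(abs(cs$freqs - f))
    expect_equal(cs$values[i], 1, tolerance = 1e-9)
  }
})

test_that("realized broadband time-domain SNR matches the target", {
  sch <- quick_schedule()
  resp <- response_preset("correlated")
  sim <- simulate_trials(100, sch, resp,
                                   noise_model(target_time_snr = 0.5), seed = 2)
  pure <- simulate_trials(100, sch, resp, no_noise(), seed = 2)
  win <- sim$onset:(sim$onset + 5 * sim$fs - 1)
  ps <- rowMeans(pure$data[, win]^2)
  pn <- rowMeans((sim$data[, win] - pure$data[, win])^2)
  expect_equal(mean(ps / pn), 0.5, tolerance = 0.05 * 0.5)
})

test_that("non-phase-locked band perturbation leaves coherency at noise level", {
  ts <- noise_set(134, seed = 21,
                  perturbations = list(band_perturbation(c(8, 12), 1)))
  cs <- coherency(ts)
  thr <- rayleigh_threshold(134)
  band <- cs$freqs > 8 & cs$freqs < 12
  # exceedance of the 95th-percentile threshold stays near the nominal level
  expect_lt(mean(cs$values[band] > thr), 0.25)
  expect_true(all(cs$values[band] < 2 * thr))
})

test_that("phase-locked band perturbation raises band power by the requested dB", {
  ts0 <- noise_set(40, seed = 5)
  ts1 <- noise_set(40, seed = 5,
                   perturbations = list(band_perturbation(c(8, 12), 2,
                                                          phase_locked = TRUE)))
  win <- ts0$onset:ncol(ts0$data)
  p0 <- mean(freqtag:::band_power_rows(ts0$data[, win], ts0$fs, c(8, 12)))
  p1 <- mean(freqtag:::band_power_rows(ts1$data[, win], ts1$fs, c(8, 12)))
  expect_equal(10 * log10(p1 / p0), 2, tolerance = 0.25)
})

test_that("dataset generation keeps counts, labels and per-participant latencies", {
  ds <- generate_dataset(4, 10, latency_spread = 0.01, seed = 9)
  expect_length(ds, 8)
  expect_length(unique(attr(ds, "latencies")), 4)
  pooled <- pool_trials(Filter(function(s) s$trials$condition[1] == "correlated", ds))
  expect_identical(n_trials(pooled), 40L)
  expect_setequal(unique(pooled$trials$participant),
                  sprintf("P%02d", 1:4))
})

test_that("artifact injection is targeted and reversible by omission", {
  ts <- noise_set(20, seed = 4)
  same <- inject_artifact(ts, integer(0), "blink")
  expect_identical(same$data, ts$data)
  blinked <- inject_artifact(ts, 1:2, "blink", amplitude = 300, seed = 1)
  p2p <- apply(blinked$data[1:2, ], 1, function(r) diff(range(r)))
  expect_true(all(p2p > 200))
  expect_identical(blinked$data[3:20, ], ts$data[3:20, ])
  noisy <- inject_artifact(ts, 3, "noisy", factor = 4)
  expect_equal(var(noisy$data[3, ]), 4 * var(ts$data[3, ]), tolerance = 1e-9)
  expect_error(inject_artifact(ts, 1, "zap"))
})
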