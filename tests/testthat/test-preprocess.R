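test_that("the filter chain meets its magnitude and phase contracts", {
  resp <- measure_filter_response(filter_spec(), fs = 1000,
                                  freqs = c(4.2, 50, 80))
  g <- function(f) resp$gain_db[resp$freq == f]
  expect_lt(g(50), -20)                      # notch: >= 20 dB down at mains
  expect_lt(abs(g(4.2)), 20 * log10(1.05))   # pass band: gain within 5%
  expect_lt(abs(resp$phase_deg[resp$freq == 4.2]), 1)  # zero-phase
  expect_lt(g(80), -20)                      # stop band above 70 Hz
})

test_that("a pure 50 Hz tone is suppressed to under 10% RMS", {
  ts <- locked_set(3, freqs = 50)
  out <- apply_filters(ts)
  rms <- function(m) sqrt(mean(m^2))
  mid <- (ts$onset + 500):(ts$onset + 4500)  # avoid filter edge transients
  expect_lt(rms(out$data[, mid]) / rms(ts$data[, mid]), 0.10)
})

test_that("zero-phase filtering does not bias phase coherency", {
  resp <- response_model(c(0, 1, 0, 0.5), phase_jitter_sd = 0)
  ts <- simulate_trials(10, quick_schedule(), resp, no_noise(),
                                  seed = 1)
  before <- coherency(ts)
  after <- coherency(apply_filters(ts))
  i <- which.min(abs(before$freqs - 4.2))
  expect_equal(before$values[i], 1, tolerance = 1e-9)
  expect_equal(after$values[i], 1, tolerance = 1e-3)
})

test_that("segmentation aligns onsets and drops events without full context", {
  fs <- 1000
  cont <- sin(2 * pi * 4 * (0:(45 * fs)) / fs)  # 4 Hz: period divides spacing
  onsets <- seq(2 * fs, 38 * fs, by = 4 * fs)  # 10 events, all with context
  ts <- segment_trials(cont, fs, onsets, pre = 1, post = 3)
  expect_identical(n_trials(ts), 10L)
  expect_identical(ts$onset, 1001L)
  # all onset columns carry the same instantaneous value (alignment)
  expect_lt(max(ts$data[, ts$onset]) - min(ts$data[, ts$onset]), 1e-9)

  onsets_bad <- c(onsets, 45 * fs - 200)  # 0.2 s before the end
  expect_warning(ts2 <- segment_trials(cont, fs, onsets_bad, pre = 1, post = 3),
                 "dropped")
  expect_identical(n_trials(ts2), 10L)
})

test_that("trial rejection removes contaminated trials and only those", {
  ts <- noise_set(100, seed = 11)
  clean <- reject_trials(ts)
  expect_identical(n_trials(clean$trialset), 100L)
  expect_identical(sum(clean$report$rejected), 0L)

  bad_idx <- seq(5, 95, by = 10)  # 10 of 100
  dirty <- inject_artifact(ts, bad_idx, "blink", amplitude = 300, seed = 2)
  res <- reject_trials(dirty)
  expect_gte(sum(res$report$rejected[bad_idx]), 9)
  expect_identical(sum(res$report$rejected[-bad_idx]), 0L)
  expect_match(res$report$reason[res$report$rejected][1], "peak_to_peak")

  # infinite criteria are the identity
  res_inf <- reject_trials(dirty, rejection_criteria(Inf, Inf))
  expect_identical(res_inf$trialset$data, dirty$data)

  # everything rejected is an explicit error
  tiny <- subset_trials(dirty, bad_idx[1:3])
  expect_error(reject_trials(tiny, rejection_criteria(peak_to_peak_max = 1e-6,
                                                      variance_zmax = 1e-6)),
               "fewer than 2")
})
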