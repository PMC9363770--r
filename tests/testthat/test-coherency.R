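test_that("phase extraction uses the 0.2 Hz grid and is phase-linear", {
  ts <- locked_set(6, freqs = 4.2)
  pt <- extract_phases(ts)
  expect_length(pt$freqs, 71)
  expect_equal(pt$freqs[1], 1.0)
  expect_equal(pt$freqs[71], 15.0)
  expect_equal(unique(round(diff(pt$freqs), 10)), 0.2)
  i <- which.min(abs(pt$freqs - 4.2))
  expect_lt(diff(range(pt$phases[, i])), 1e-9)  # identical across trials
  expect_true(all(pt$phases > -pi & pt$phases <= pi))

  # a trial with a known phase offset differs by exactly that offset
  ts2 <- locked_set(1, freqs = 4.2, phases = 0.7)
  d <- extract_phases(ts2)$phases[1, i] - pt$phases[1, i]
  expect_equal(Arg(exp(1i * d)), 0.7, tolerance = 1e-6)

  short <- trialset(matrix(rnorm(2 * 3000), 2), fs = 1000, onset = 1L)
  expect_error(extract_phases(short), "shorter")
})

test_that("coherency hits its exact limits and stays in [0, 1]", {
  eq <- structure(list(phases = matrix(1.2, 40, 3), freqs = c(2, 3, 4),
                       n_trials = 40, window = 5, fs = 1000),
                  class = "phase_table")
  expect_equal(coherency(eq)$values, rep(1, 3))
  expect_equal(coherency(eq, estimator = "ci_fraction")$values, rep(1, 3))

  spaced <- structure(list(phases = matrix(seq(-pi, pi, length.out = 9)[-9], 8, 1),
                           freqs = 5, n_trials = 8, window = 5, fs = 1000),
                      class = "phase_table")
  expect_equal(coherency(spaced)$values, 0, tolerance = 1e-12)

  set.seed(1)
  for (r in 1:20) {
    ph <- matrix(runif(30 * 5, -pi, pi), 30, 5)
    v <- freqtag:::coherency_values(ph)
    expect_true(all(v >= 0 & v <= 1))
    v2 <- freqtag:::coherency_values(ph, "ci_fraction")
    expect_true(all(v2 >= 0 & v2 <= 1))
  }
  one <- structure(list(phases = matrix(0, 1, 1), freqs = 5, n_trials = 1,
                        window = 5, fs = 1000), class = "phase_table")
  expect_error(coherency(one), "2 trials")
})

test_that("coherency is invariant to per-trial amplitude scaling", {
  ts <- noise_set(12, seed = 31)
  scaled <- ts
  scaled$data <- ts$data * rep(c(0.2, 5, 17, 1), 3)
  expect_equal(coherency(ts)$values, coherency(scaled)$values, tolerance = 1e-12)
})

test_that("the bootstrap null threshold matches the Rayleigh closed form and shrinks with n", {
  thr <- vapply(c(50, 134, 534), function(n)
    null_threshold(n, B = 3000, freqs = 4.2, seed = n)$threshold, 0)
  expect_equal(thr, rayleigh_threshold(c(50, 134, 534)), tolerance = 0.05)
  expect_true(all(diff(thr) < 0))
  expect_true(all(thr > 0))
})

test_that("the uniform-phase fast path agrees with full white-noise simulation", {
  n <- 40
  a <- null_threshold(n, B = 500, freqs = c(4.2, 10), seed = 1)
  b <- null_threshold(n, B = 500, freqs = c(4.2, 10), seed = 2,
                      method = "white_noise")
  # both are ~0.27; tolerance ~3 combined Monte-Carlo SEs of a B=500 quantile
  expect_equal(a$threshold, b$threshold, tolerance = 0.12)
  expect_equal(dim(a$null_samples), c(500L, 2L))
})

test_that("harmonic detection flags driven harmonics and keeps p-values calibrated", {
  resp <- response_model(c(0, 1, 0, 0.5, 0, 0), phase_jitter_sd = 0.4,
                         latency = 0.1)
  ts <- simulate_trials(134, quick_schedule(), resp,
                                  noise_model(target_time_snr = 0.5), seed = 17)
  cs <- coherency(ts)
  null <- null_threshold(134, B = 2000, freqs = cs$freqs, seed = 5)
  det <- detect_harmonics(cs, null, f0 = 2.1, K = 6)
  expect_identical(nrow(det), 6L)
  expect_true(all(det$detected[det$k %in% c(2, 4)]))
  expect_true(all(det$p_value[det$detected] < 0.05))
  expect_lte(sum(det$detected[det$k %in% c(1, 3, 5)]), 1)
  # the even harmonics sit exactly on the analysis grid, odd ones 0.1 Hz off
  expect_equal(det$bin_offset[det$k == 2], 0, tolerance = 1e-9)
  expect_equal(abs(det$bin_offset[det$k == 1]), 0.1, tolerance = 1e-9)
  expect_error(detect_harmonics(cs, null, f0 = 2.1, K = 8), "above")
})

test_that("a marginal coherency value just above threshold is a marginal detection", {
  freqs <- seq(1, 15, by = 0.2)
  null <- null_threshold(134, B = 2000, freqs = freqs, seed = 8)
  i <- which.min(abs(freqs - 2.1))
  vals <- rep(0.03, length(freqs))
  vals[i] <- 0.155
  cs <- structure(list(freqs = freqs, values = vals,
                       estimator = "resultant_length", n_trials = 134),
                  class = "coherency_spectrum")
  det <- detect_harmonics(cs, null, f0 = 2.1, K = 1)
  expect_true(det$detected[1])
  expect_lt(det$p_value[1], 0.08)
  expect_gt(det$p_value[1], 0.005)
})

test_that("false-positive rate at the 95th-percentile threshold is nominal", {
  set.seed(99)
  n <- 50
  thr <- rayleigh_threshold(n)
  hits <- replicate(400, Mod(mean(exp(1i * runif(n, -pi, pi)))) > thr)
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("pooling concatenates trials unweighted and penalizes high harmonics under latency spread", {
  sets <- lapply(1:4, function(p) noise_set(10, seed = p))
  pooled <- pool_trials(sets)
  expect_identical(n_trials(pooled), 40L)

  # identical-latency participants: pooled coherency == coherency of the
  # concatenation (the same trials), deterministically
  resp <- response_model(c(0, 1), phase_jitter_sd = 0.8)
  parts <- lapply(1:3, function(p)
    simulate_trials(30, quick_schedule(), resp, no_noise(), seed = p))
  pooled2 <- pool_trials(parts)
  i <- which.min(abs(seq(1, 15, .2) - 4.2))
  big <- coherency(pooled2)
  expect_equal(big$n_trials, 90)

  # 20 ms latency spread: pooled coherency loss is larger at 12.6 than 4.2 Hz
  resp_k <- function(lat) response_model(c(0, 1, 0, 0, 0, 1), latency = lat)
  lats <- c(-0.03, -0.01, 0.01, 0.03)  # sd = 20 ms around zero, one value per set
  mk <- function(lat_vec) pool_trials(lapply(seq_along(lat_vec), function(p)
    simulate_trials(8, quick_schedule(), resp_k(lat_vec[p]),
                              no_noise(), seed = p)))
  cs0 <- coherency(mk(c(0, 0, 0, 0)))
  cs1 <- coherency(mk(lats))
  at <- function(cs, f) cs$values[which.min(abs(cs$freqs - f))]
  loss_42  <- at(cs0, 4.2) - at(cs1, 4.2)
  loss_126 <- at(cs0, 12.6) - at(cs1, 12.6)
  expect_gt(loss_126, loss_42)
  expect_error(pool_trials(sets[[1]],
                           trialset(matrix(0, 2, 100), fs = 500, onset = 10)),
               "sampling rates")
})

test_that("coherency SNR is the plain ratio of value to threshold", {
  expect_equal(coherency_snr(0.29, 0.08), 3.625)
  expect_equal(round(coherency_snr(0.29, 0.08), 1), 3.6)
  expect_equal(coherency_snr(0.15, 0.15), 1)
  expect_error(coherency_snr(0.3, 0), "> 0")
})
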