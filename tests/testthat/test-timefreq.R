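test_that("ERSP of stationary noise is flat at 0 dB", {
  ts <- noise_set(300, seed = 41)
  m <- ersp(ts)
  bs <- band_summary(m)
  expect_lt(max(abs(bs$mean_delta_db)), 0.2)  # ~3 SE at this trial count
})

test_that("ITC is ~1 at a noiseless locked harmonic and at chance without a stimulus", {
  resp <- response_model(c(0, 1), phase_jitter_sd = 0)
  ts <- simulate_trials(20, quick_schedule(), resp,
                                  noise_model(white_sd = 0.01, pink_sd = 0,
                                              mains_amp = 0), seed = 6)
  m <- itc_timecourse(ts, freqs = c(4, 10))
  post <- m$times > 1 & m$times < 4
  expect_gt(min(m$values[post, 1]), 0.98)
  expect_true(all(m$values >= 0 & m$values <= 1))

  # pure noise: ITC at chance level (E[R] ~ sqrt(pi / (4 n))) everywhere
  nz <- noise_set(20, seed = 7)
  mn <- itc_timecourse(nz, freqs = c(4, 10))
  expect_lt(mean(mn$values), 3 * sqrt(pi / (4 * 20)))
})

test_that("a non-phase-locked band perturbation is powerful in ERSP but silent in ITC", {
  ts <- noise_set(150, seed = 52,
                  perturbations = list(band_perturbation(c(8, 12), 1.5)))
  m <- significance_mask(ersp(ts, freqs = seq(2, 20, 2)), B_perm = 200, seed = 1)
  post <- m$times > 0.5 & m$times < 4.5
  alpha_cells <- m$mask[post, m$freqs == 10]
  expect_gt(mean(alpha_cells), 0.5)

  itc <- significance_mask(itc_timecourse(ts, freqs = c(10)), B_perm = 200,
                           seed = 2)
  expect_lt(mean(itc$mask[post, 1]), 0.5)  # majority of cells not significant
})

test_that("the significance mask has a nominal false-positive level on stationary noise", {
  ts <- noise_set(100, seed = 61)
  m <- significance_mask(ersp(ts, freqs = seq(4, 28, 4)), B_perm = 250, seed = 3)
  post <- m$times > 0.2
  expect_lt(mean(m$mask[post, ]), 0.2)
  expect_gt(mean(m$mask[post, ]), 0.001)
  all_m <- significance_mask(m, B_perm = 250, alpha = 1, seed = 4)
  expect_gt(mean(all_m$mask), 0.99)
})

test_that("injected band effects are recovered at moderate trial counts", {
  ts <- simulate_trials(200, quick_schedule(), response_model(0),
                                  noise_model(),
                                  list(band_perturbation(c(8, 12), 1),
                                       band_perturbation(c(13, 30), -1)),
                                  seed = 77)
  bs <- band_summary(ersp(ts))
  expect_equal(bs$mean_delta_db[bs$band == "alpha"], 1, tolerance = 0.35)
  expect_equal(bs$mean_delta_db[bs$band == "beta"], -1, tolerance = 0.35)
  expect_error(band_summary(ersp(ts), bands = list(hf = c(60, 80))), "outside")
})

test_that("fine frequency resolution preserves the driven-harmonic peak", {
  resp <- response_model(c(0, 1), phase_jitter_sd = 0.3)
  ts <- simulate_trials(60, quick_schedule(), resp,
                                  noise_model(target_time_snr = 0.5), seed = 13)
  rc <- resolution_comparison(ts, f0 = 2.1, harmonic = 2)
  expect_gte(rc$coherency[rc$resolution == 0.2],
             rc$coherency[rc$resolution == 1])
  expect_equal(rc$bin_offset[rc$resolution == 0.2], 0, tolerance = 1e-9)

  # a broadband (1/f) signal is insensitive to the resolution choice
  nz <- noise_set(40, seed = 14, noise = noise_model(white_sd = 1, pink_sd = 10,
                                                     mains_amp = 0))
  rn <- resolution_comparison(nz, f0 = 2.1, harmonic = 2)
  expect_lt(abs(log(rn$amplitude_density[1] / rn$amplitude_density[2])), log(2))
})

test_that("ITC at the driven harmonic orders with SNR like FFT coherency", {
  resp <- response_model(c(0, 1), phase_jitter_sd = 0)
  at_snr <- function(s) {
    ts <- simulate_trials(50, quick_schedule(), resp,
                                    noise_model(target_time_snr = s), seed = 23)
    m <- itc_timecourse(ts, freqs = 4)
    post <- m$times > 1 & m$times < 4
    c(itc = mean(m$values[post, 1]),
      coh = coherency(ts)$values[which.min(abs(seq(1, 15, .2) - 4.2))])
  }
  lo <- at_snr(0.05); hi <- at_snr(0.5)
  expect_gt(hi["itc"], lo["itc"])
  expect_gt(hi["coh"], lo["coh"])
})
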