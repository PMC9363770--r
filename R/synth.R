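#' Stimulus schedule for a square-wave depth-alternation experiment
#'
#' Describes the timing of one trial: a zero-disparity pre-period of random
#' length, followed by a disparity plane alternating between `+disparity_amp`
#' and `-disparity_amp` degrees as a square wave of frequency `f0` with duty
#' cycle `duty`, presented for a random stimulus duration.
#'
#' @param f0 alternation frequency in Hz.
#' @param duty fraction of each period spent at `+disparity_amp` (0 < duty < 1).
#'   A 50% duty cycle square wave contains only odd harmonics.
#' @param disparity_amp disparity amplitude in degrees.
#' @param pre_range range (s) the pre-period duration is drawn from, uniformly.
#' @param stim_range range (s) the stimulus duration is drawn from, uniformly.
#' @param fs sampling rate in samples/s.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(f0 = 2.1, duty = 0.5, disparity_amp = 0.05,
                              pre_range = c(1, 1.5), stim_range = c(5, 6),
                              fs = 1000) {
  stopifnot_scalar(f0, "f0", positive = TRUE)
  stopifnot_scalar(duty, "duty")
  if (duty <= 0 || duty >= 1) stop("`duty` must lie strictly between 0 and 1")
  stopifnot_scalar(disparity_amp, "disparity_amp")
  if (disparity_amp < 0) stop("`disparity_amp` must be >= 0")
  stopifnot(length(pre_range) == 2L, length(stim_range) == 2L)
  if (pre_range[1] < 1) stop("pre-period must be at least 1 s (baseline requirement)")
  if (diff(pre_range) < 0 || diff(stim_range) < 0) stop("duration ranges must be non-decreasing")
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs < 4 * f0) stop("`fs` must resolve the alternation period (>= 4 samples/period)")
  structure(list(f0 = f0, duty = duty, disparity_amp = disparity_amp,
                 pre_range = pre_range, stim_range = stim_range, fs = fs),
            class = "stimulus_schedule")
}

#' Disparity waveform of the stimulus
#'
#' Samples the square-wave disparity modulation: zero before onset, then
#' `+disparity_amp` for the first `duty` fraction of each period and
#' `-disparity_amp` for the rest, at the schedule's sampling rate.
#'
#' @param schedule a [stimulus_schedule()].
#' @param pre_duration pre-period length in s (default: lower end of range).
#' @param stim_duration stimulus length in s (default: lower end of range).
#' @return Numeric vector of disparity in degrees per sample, with attribute
#'   `onset` giving the 1-based sample index of stimulus onset.
#' @export
square_wave_disparity <- function(schedule,
                                  pre_duration = schedule$pre_range[1],
                                  stim_duration = schedule$stim_range[1]) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  fs <- schedule$fs
  if (fs < 4 * schedule$f0)
    stop("sampling rate resolves fewer than 4 samples per alternation period")
  n_pre <- round(pre_duration * fs)
  n_stim <- round(stim_duration * fs)
  t <- (0:(n_stim - 1)) / fs
  phase <- (t * schedule$f0) %% 1
  wave <- ifelse(phase < schedule$duty, schedule$disparity_amp, -schedule$disparity_amp)
  out <- c(numeric(n_pre), wave)
  attr(out, "onset") <- as.integer(n_pre + 1L)
  out
}

#' Analytic harmonic amplitude of the square-wave stimulus
#'
#' Fourier-series amplitude of the k-th harmonic of a square wave toggling
#' between `+amp` and `-amp` with the given duty cycle:
#' `4 * amp * |sin(pi * k * duty)| / (pi * k)`. For a 50% duty cycle all even
#' harmonics vanish and odd-harmonic amplitudes decrease strictly
#' monotonically with k.
#'
#' @param k harmonic index (vectorised).
#' @param duty duty cycle in (0, 1).
#' @param amp square-wave amplitude.
#' @return Amplitude of the k-th harmonic (same units as `amp`).
#' @export
square_wave_harmonic_amplitude <- function(k, duty = 0.5, amp = 1) {
  if (any(k < 1)) stop("harmonic index must be >= 1")
  4 * amp * abs(sin(pi * k * duty)) / (pi * k)
}

#' Phase-locked neural response model
#'
#' The steady-state response is modelled directly as a sum of sinusoids at
#' harmonics of the stimulus frequency, each with its own amplitude and
#' onset-locked phase. A per-trial random phase offset (common to all
#' harmonics) models residual trial-to-trial variability of the response
#' phase; a fixed latency models the propagation delay of a participant and
#' shifts the phase of harmonic k by `2*pi*k*f0*latency`.
#'
#' @param harmonic_amps amplitudes in microvolts for harmonics k = 1..K.
#' @param harmonic_phases onset-locked phases in radians (default all 0).
#' @param phase_jitter_sd sd (radians) of the per-trial phase offset.
#' @param latency propagation delay in seconds.
#' @return An object of class `response_model`.
#' @export
response_model <- function(harmonic_amps, harmonic_phases = NULL,
                           phase_jitter_sd = 0, latency = 0) {
  stopifnot(is.numeric(harmonic_amps), all(harmonic_amps >= 0))
  K <- length(harmonic_amps)
  if (is.null(harmonic_phases)) harmonic_phases <- numeric(K)
  stopifnot(length(harmonic_phases) == K)
  stopifnot_scalar(phase_jitter_sd, "phase_jitter_sd")
  if (phase_jitter_sd < 0) stop("`phase_jitter_sd` must be >= 0")
  stopifnot_scalar(latency, "latency")
  structure(list(harmonic_amps = harmonic_amps,
                 harmonic_phases = harmonic_phases,
                 phase_jitter_sd = phase_jitter_sd, latency = latency),
            class = "response_model")
}

#' Condition presets for the stereogram experiment
#'
#' The two study conditions as response models. The correlated-like condition
#' carries energy on the even harmonics of the alternation frequency
#' (dominant second), the anticorrelated-like condition on the first harmonic
#' only. The per-trial phase jitter default of 1.5 rad puts the driven-harmonic
#' coherency at the ~0.3 scale observed in real recordings.
#'
#' @param condition `"correlated"` or `"anticorrelated"`.
#' @param phase_jitter_sd per-trial phase jitter in radians.
#' @param latency propagation delay in seconds.
#' @return A [response_model()].
#' @export
response_preset <- function(condition = c("correlated", "anticorrelated"),
                            phase_jitter_sd = 1.5, latency = 0.1) {
  condition <- match.arg(condition)
  amps <- switch(condition,
    correlated     = c(0, 1, 0, 0.5, 0, 0.25),
    anticorrelated = c(1, 0, 0, 0, 0, 0))
  response_model(amps, phase_jitter_sd = phase_jitter_sd, latency = latency)
}

#' Broadband noise model
#'
#' Additive noise as white Gaussian noise plus a `1/f^gamma` component plus a
#' mains-frequency sinusoid with random phase per trial. When
#' `target_time_snr` is set, the noise of each trial is rescaled so that the
#' ratio of response power to noise power over the 5 s post-onset analysis
#' window equals the target exactly. With `snr_band` set, both powers are
#' measured within that frequency band instead of broadband (used by the
#' trial-planning module, where the signal-to-noise ratio is defined within
#' the analysis bandwidth of the driven harmonic).
#'
#' @param white_sd sd of the white component, microvolts.
#' @param pink_sd RMS of the `1/f^gamma` component, microvolts.
#' @param pink_exponent spectral slope gamma of the pink component.
#' @param mains_freq mains interference frequency, Hz.
#' @param mains_amp mains sinusoid amplitude, microvolts.
#' @param target_time_snr optional power ratio (response/noise) to calibrate to.
#' @param snr_band optional `c(f_lo, f_hi)` band (Hz) in which the calibration
#'   powers are measured; `NULL` means broadband (the full sampled band).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 5, pink_sd = 15, pink_exponent = 1,
                        mains_freq = 50, mains_amp = 5,
                        target_time_snr = NULL, snr_band = NULL) {
  stopifnot(white_sd >= 0, pink_sd >= 0, mains_amp >= 0, mains_freq > 0)
  if (!is.null(target_time_snr)) stopifnot_scalar(target_time_snr, "target_time_snr", positive = TRUE)
  if (!is.null(snr_band)) stopifnot(length(snr_band) == 2L, snr_band[1] < snr_band[2])
  structure(list(white_sd = white_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent, mains_freq = mains_freq,
                 mains_amp = mains_amp, target_time_snr = target_time_snr,
                 snr_band = snr_band),
            class = "noise_model")
}

#' Non-phase-locked band-power perturbation
#'
#' A stimulus-evoked change of band power applied from stimulus onset onward.
#' The default (non-phase-locked) implementation rescales the Fourier
#' components of the post-onset noise inside the band so that band power
#' changes by exactly `delta_db` dB relative to the pre-period; the component
#' phases remain random per trial, so the perturbation carries no inter-trial
#' phase coherency. With `phase_locked = TRUE` a fixed-phase sinusoid at the
#' band center with the equivalent power change is added instead.
#'
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param delta_db change of band power after onset, dB (negative = decrease).
#' @param phase_locked logical; see above.
#' @return An object of class `band_perturbation`.
#' @export
band_perturbation <- function(band, delta_db, phase_locked = FALSE) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  stopifnot_scalar(delta_db, "delta_db")
  structure(list(band = band, delta_db = delta_db, phase_locked = phase_locked),
            class = "band_perturbation")
}

#' Simulate a set of trials under one condition
#'
#' Vectorised forward model: draws per-trial durations from the schedule,
#' aligns all trials at stimulus onset (trimmed to the shortest pre/post
#' extent so the set is rectangular), and assembles phase-locked response,
#' noise and band perturbations. [generate_trial()] and [generate_dataset()]
#' are thin wrappers around this.
#'
#' @param n number of trials.
#' @inheritParams generate_trial
#' @param participant,condition labels stored per trial.
#' @return A `trialset`.
#' @export
simulate_trials <- function(n, schedule, response, noise,
                            perturbations = list(), seed = NULL,
                            participant = NA_character_,
                            condition = NA_character_) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(response, "response_model"),
            inherits(noise, "noise_model"))
  fs <- schedule$fs
  K <- length(response$harmonic_amps)
  if (K * schedule$f0 >= fs / 2)
    stop("highest modelled harmonic exceeds the Nyquist frequency")
  if (fs < 4 * K * schedule$f0)
    stop("`fs` must be at least 4x the highest analysed harmonic")
  if (inherits(perturbations, "band_perturbation")) perturbations <- list(perturbations)

  with_seed(seed, {
    pre  <- runif(n, schedule$pre_range[1], schedule$pre_range[2])
    stim <- runif(n, schedule$stim_range[1], schedule$stim_range[2])
    n_pre  <- round(min(pre) * fs)
    n_post <- round(min(stim) * fs)
    S <- n_pre + n_post
    onset <- n_pre + 1L
    t_post <- (0:(n_post - 1)) / fs

    # phase-locked response: sum_k a_k cos(2 pi k f0 (t - latency) + phi_k + j_i)
    # decomposed as cos(j_i) C(t) - sin(j_i) D(t) with the per-trial jitter j_i
    Cvec <- numeric(n_post); Dvec <- numeric(n_post)
    for (k in seq_len(K)) {
      a <- response$harmonic_amps[k]
      if (a == 0) next
      th <- 2 * pi * k * schedule$f0 * (t_post - response$latency) +
        response$harmonic_phases[k]
      Cvec <- Cvec + a * cos(th)
      Dvec <- Dvec + a * sin(th)
    }
    jit <- if (response$phase_jitter_sd > 0) rnorm(n, 0, response$phase_jitter_sd) else numeric(n)
    resp <- matrix(0, n, S)
    resp[, onset:S] <- outer(cos(jit), Cvec) - outer(sin(jit), Dvec)

    # noise: white + 1/f^gamma + mains (random phase per trial)
    nz <- matrix(rnorm(n * S, sd = noise$white_sd), n, S)
    if (noise$pink_sd > 0) {
      W <- matrix(rnorm(n * S), S, n)
      fgrid <- (seq_len(S) - 1) * fs / S
      fgrid[fgrid > fs / 2] <- fs - fgrid[fgrid > fs / 2]  # mirror
      H <- 1 / pmax(fgrid, 0.5)^(noise$pink_exponent / 2)
      H[1] <- 0
      pk <- Re(mvfft(mvfft(W) * H, inverse = TRUE)) / S
      pk <- pk * (noise$pink_sd / sqrt(mean(H^2)))
      nz <- nz + t(pk)
    }
    if (noise$mains_amp > 0) {
      ph <- runif(n, -pi, pi)
      tt <- (seq_len(S) - onset) / fs
      nz <- nz + noise$mains_amp * cos(outer(ph, 2 * pi * noise$mains_freq * tt, `+`))
    }

    # SNR calibration over the 5 s post-onset analysis window.
    # Broadband: per-trial exact scaling (the broadband noise power has
    # thousands of degrees of freedom, so conditioning on it is harmless).
    # Band-referenced: a single ensemble scale factor, because a narrow band
    # holds only a few Fourier bins and per-trial conditioning would destroy
    # the natural (Rayleigh) variability of the in-band noise.
    if (!is.null(noise$target_time_snr)) {
      win <- onset:min(S, onset + 5 * fs - 1)
      if (is.null(noise$snr_band)) {
        p_resp <- rowMeans(resp[, win, drop = FALSE]^2)
        p_nz <- rowMeans(nz[, win, drop = FALSE]^2)
        if (any(p_resp == 0))
          stop("cannot calibrate SNR: the response has zero power in the window")
        nz <- nz * sqrt(p_resp / (noise$target_time_snr * p_nz))
      } else {
        p_resp <- mean(band_power_rows(resp[, win, drop = FALSE], fs, noise$snr_band))
        p_nz <- mean(band_power_rows(nz[, win, drop = FALSE], fs, noise$snr_band))
        if (p_resp == 0)
          stop("cannot calibrate SNR: the response has zero power in the calibration band")
        nz <- nz * sqrt(p_resp / (noise$target_time_snr * p_nz))
      }
    }

    # stimulus-locked band perturbations on the post-onset noise
    for (p in perturbations) {
      stopifnot(inherits(p, "band_perturbation"))
      seg <- nz[, onset:S, drop = FALSE]
      if (p$phase_locked) {
        fc <- mean(p$band)
        pb <- band_power_rows(seg, fs, p$band)
        a <- sqrt(2 * pmax(10^(p$delta_db / 10) - 1, 0) * pb)
        nz[, onset:S] <- seg + a * matrix(cos(2 * pi * fc * t_post), n, n_post, byrow = TRUE)
      } else {
        nz[, onset:S] <- scale_band_rows(seg, fs, p$band, 10^(p$delta_db / 20))
      }
    }

    dat <- resp + nz
    out <- trialset(dat, fs = fs, onset = onset,
                    participant = participant, condition = condition,
                    params = list(schedule = unclass(schedule),
                                  response = unclass(response),
                                  noise = unclass(noise),
                                  perturbations = lapply(perturbations, unclass),
                                  seed = seed,
                                  pre_durations = pre, stim_durations = stim))
    out
  })
}

# Power of each row restricted to a frequency band, via the FFT.
band_power_rows <- function(m, fs, band) {
  S <- ncol(m)
  X <- mvfft(t(m))
  f <- (seq_len(S) - 1) * fs / S
  f[f > fs / 2] <- fs - f[f > fs / 2]
  keep <- f >= band[1] & f <= band[2]
  colSums(Mod(X[keep, , drop = FALSE])^2) / S^2
}

# Multiply the Fourier components of each row inside `band` by `gain`.
scale_band_rows <- function(m, fs, band, gain) {
  S <- ncol(m)
  X <- mvfft(t(m))
  f <- (seq_len(S) - 1) * fs / S
  f[f > fs / 2] <- fs - f[f > fs / 2]
  keep <- f >= band[1] & f <= band[2]
  X[keep, ] <- X[keep, ] * gain
  t(Re(mvfft(X, inverse = TRUE))) / S
}

#' Generate one synthetic trial
#'
#' Assembles a single trial from the forward model: square-wave-driven
#' harmonic response starting at stimulus onset, broadband noise spanning the
#' whole trial, and optional stimulus-locked band perturbations after onset.
#' Identical seeds yield identical trials.
#'
#' @param schedule a [stimulus_schedule()].
#' @param response a [response_model()].
#' @param noise a [noise_model()].
#' @param perturbations list of [band_perturbation()] objects.
#' @param seed integer seed (required for reproducibility).
#' @return A `trialset` containing one trial.
#' @export
generate_trial <- function(schedule = stimulus_schedule(),
                           response = response_preset("correlated"),
                           noise = noise_model(), perturbations = list(),
                           seed = NULL) {
  simulate_trials(1L, schedule, response, noise, perturbations, seed = seed)
}

#' Generate a multi-participant synthetic dataset
#'
#' Produces one trial set per participant and condition. Participant latencies
#' are drawn once per participant around a 100 ms base delay with the given
#' spread; all trials of a participant share that latency, so pooling across
#' participants at the trial level incurs the realistic phase penalty at high
#' harmonics.
#'
#' @param n_participants number of participants.
#' @param trials_per_condition trials per participant and condition.
#' @param latency_spread sd (s) of the across-participant latency differences.
#' @param seed master seed; per-set seeds are derived deterministically.
#' @param conditions named list of condition definitions, each a list with a
#'   `response` ([response_model()]) and a `target_time_snr`. The default is
#'   the two study conditions: correlated-like (even harmonics, broadband
#'   time-domain SNR 0.5) and anticorrelated-like (first harmonic, SNR 0.1).
#' @param schedule a [stimulus_schedule()].
#' @param noise a [noise_model()] (its `target_time_snr` is overridden per
#'   condition).
#' @return Named list of `trialset` objects (`participant.condition`), with
#'   attribute `latencies`.
#' @export
generate_dataset <- function(n_participants = 4, trials_per_condition = 134,
                             latency_spread = 0.01, seed = NULL,
                             conditions = list(
                               correlated = list(response = response_preset("correlated"),
                                                 target_time_snr = 0.5),
                               anticorrelated = list(response = response_preset("anticorrelated"),
                                                     target_time_snr = 0.1)),
                             schedule = stimulus_schedule(),
                             noise = noise_model()) {
  stopifnot(n_participants >= 1)
  lat <- with_seed(sub_seed(seed, 1L) %||% NULL,
                   0.1 + rnorm(n_participants, 0, latency_spread))
  out <- list()
  k <- 2L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    for (cn in names(conditions)) {
      cd <- conditions[[cn]]
      resp <- cd$response
      resp$latency <- lat[p]
      nz <- noise
      nz$target_time_snr <- cd$target_time_snr
      out[[paste(pid, cn, sep = ".")]] <-
        simulate_trials(trials_per_condition, schedule, resp, nz,
                        seed = sub_seed(seed, k),
                        participant = pid, condition = cn)
      k <- k + 1L
    }
  }
  attr(out, "latencies") <- lat
  out
}

#' Inject artifacts into trials
#'
#' Adds a blink-like transient (a low-frequency, high-amplitude Gaussian bump
#' at a random latency) or inflates the variance of whole trials
#' (noisy-trial). The `good` flags are left untouched: identifying and
#' excluding contaminated trials is the preprocessing stage's job.
#'
#' @param x a `trialset`.
#' @param trials integer indices of trials to contaminate.
#' @param kind `"blink"` or `"noisy"`.
#' @param amplitude blink peak amplitude in microvolts.
#' @param factor variance inflation factor for `kind = "noisy"`.
#' @param seed integer seed for the random blink latencies.
#' @return The modified `trialset`.
#' @export
inject_artifact <- function(x, trials, kind = c("blink", "noisy"),
                            amplitude = 300, factor = 4, seed = NULL) {
  stopifnot(inherits(x, "trialset"))
  kind <- match.arg(kind)
  if (length(trials) == 0L) return(x)
  stopifnot(all(trials >= 1), all(trials <= nrow(x$data)))
  S <- ncol(x$data)
  fs <- x$fs
  with_seed(seed, {
    if (kind == "blink") {
      width <- 0.15 * fs
      centers <- runif(length(trials), 0.2 * S, 0.8 * S)
      for (i in seq_along(trials)) {
        bump <- amplitude * exp(-((seq_len(S) - centers[i])^2) / (2 * width^2))
        x$data[trials[i], ] <- x$data[trials[i], ] + bump
      }
    } else {
      x$data[trials, ] <- x$data[trials, , drop = FALSE] * sqrt(factor)
    }
    x
  })
}
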