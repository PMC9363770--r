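# Trial-budget planning by brute-force simulation over the generator and
# coherency stack.
#
# `time_snr` here is the response-to-noise power ratio within the analysis
# bandwidth of the driven harmonic (a 1/window = 0.2 Hz matched band), which
# for a matched band equals the per-trial SNR of the analysis bin. A
# broadband power ratio would be inflated by the full noise bandwidth and
# would not determine detectability; see the methods vignette.

planning_models <- function(time_snr, f0, harmonic, window, fs) {
  f <- harmonic * f0
  amps <- numeric(harmonic); amps[harmonic] <- 1
  list(
    schedule = stimulus_schedule(f0 = f0, pre_range = c(1, 1),
                                 stim_range = c(window, window), fs = fs),
    response = response_model(amps, phase_jitter_sd = 0, latency = 0),
    noise = noise_model(white_sd = 10, pink_sd = 0, mains_amp = 0,
                        target_time_snr = time_snr,
                        snr_band = c(f - 1 / (2 * window), f + 1 / (2 * window))),
    freq = f
  )
}

# Null 95th percentile of the spectral detection statistic
# (mean trial magnitude at the driven bin / mean magnitude over nref
# reference bins) for n white-noise trials. Magnitudes of white-noise FFT
# bins are i.i.d. Rayleigh, so the null is drawn directly.
spectral_null_threshold <- function(n, nref, B = 2000, alpha = 0.05) {
  stat <- vapply(seq_len(B), function(b) {
    mean(sqrt(rexp(n))) / mean(sqrt(rexp(n * nref)))
  }, 0)
  quantile(stat, 1 - alpha, names = FALSE)
}

#' Detection probability of the driven harmonic by simulation
#'
#' Simulates replicate experiments of `n_trials` phase-locked trials at the
#' given SNR through the generator and the coherency (or spectral) detector,
#' and reports the fraction of replicates in which the driven harmonic is
#' detected at level `alpha`.
#'
#' The coherency detector compares the resultant length at the driven bin
#' with the white-noise null percentile; the spectral detector compares the
#' across-trial mean Fourier magnitude at the driven bin (normalised by
#' flanking bins) with its white-noise null.
#'
#' @param n_trials trials per simulated experiment.
#' @param time_snr signal-to-noise power ratio within the analysis bandwidth
#'   at the driven harmonic.
#' @param method `"coherency"` or `"spectral"`.
#' @param replicates maximum Monte-Carlo replicates.
#' @param alpha detection significance level.
#' @param f0 stimulus fundamental, Hz.
#' @param harmonic driven harmonic index.
#' @param seed integer seed.
#' @param window analysis window, s.
#' @param fs sampling rate, Hz.
#' @param early_stop_target optional power value: replicate batches stop as
#'   soon as the estimate is more than 2 standard errors from it.
#' @param B_null surrogate count for the detector's null threshold.
#' @return list with `power`, `n_detected`, `replicates_used`, `threshold`.
#' @export
detection_power <- function(n_trials, time_snr,
                            method = c("coherency", "spectral"),
                            replicates = 100, alpha = 0.05, f0 = 2.1,
                            harmonic = 2, seed = NULL, window = 5, fs = 1000,
                            early_stop_target = NULL, B_null = 2000) {
  method <- match.arg(method)
  stopifnot(n_trials >= 2, time_snr > 0)
  m <- planning_models(time_snr, f0, harmonic, window, fs)
  nref_offsets <- c(-(7:3), 3:7)  # flanking bins, in grid steps of 1/window
  thr <- with_seed(sub_seed(seed, 0L), {
    if (method == "coherency") {
      null_threshold(n_trials, B = B_null, freqs = m$freq,
                     percentile = 100 * (1 - alpha))$threshold
    } else {
      spectral_null_threshold(n_trials, length(nref_offsets), B = B_null, alpha)
    }
  })
  det <- logical(0)
  batch <- 25L
  r <- 0L
  while (r < replicates) {
    nb <- min(batch, replicates - r)
    for (b in seq_len(nb)) {
      r <- r + 1L
      ts <- simulate_trials(n_trials, m$schedule, m$response, m$noise,
                            seed = sub_seed(seed, r))
      sp <- trial_spectrum(ts, window = window,
                           fmin = m$freq - 2, fmax = m$freq + 2)
      i <- which.min(abs(sp$freqs - m$freq))
      det[r] <- if (method == "coherency") {
        z <- sp$coef[, i]
        Mod(mean(z / pmax(Mod(z), .Machine$double.eps))) > thr
      } else {
        df <- 1 / window
        ref <- vapply(nref_offsets,
                      function(o) which.min(abs(sp$freqs - (m$freq + o * df))), 0L)
        (mean(Mod(sp$coef[, i])) / mean(Mod(sp$coef[, ref]))) > thr
      }
    }
    if (!is.null(early_stop_target) && r >= 2 * batch) {
      p <- mean(det); se <- sqrt(p * (1 - p) / r) + 1e-9
      if (abs(p - early_stop_target) > 2 * se) break
    }
  }
  list(power = mean(det), n_detected = sum(det), replicates_used = r,
       threshold = thr)
}

#' Required trial count for detecting the driven harmonic
#'
#' Smallest number of trials for which the Monte-Carlo detection probability
#' of the driven harmonic reaches `target_power`, found by bracketing
#' (doubling) and bisection over replicate simulated experiments. Common
#' random numbers are used across candidate trial counts.
#'
#' @inheritParams detection_power
#' @param target_power required detection probability.
#' @param n_max largest trial count considered; if the power target is not
#'   reached by `n_max` the estimate is reported as unreachable
#'   (`n_required = NA`).
#' @return An object of class `plan_estimate`: list with `time_snr`, `alpha`,
#'   `target_power`, `method`, `n_required`, `reached`, `replicates`, `trace`
#'   (data.frame of evaluated counts and powers).
#' @export
required_trials <- function(time_snr, alpha = 0.05, target_power = 0.8,
                            method = c("coherency", "spectral"),
                            replicates = 100, n_max = 1000, seed = NULL,
                            f0 = 2.1, harmonic = 2, window = 5, fs = 1000) {
  method <- match.arg(method)
  cache <- new.env(parent = emptyenv())
  powf <- function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- detection_power(n, time_snr, method, replicates, alpha, f0, harmonic,
                         seed = seed, window = window, fs = fs,
                         early_stop_target = target_power)$power
    cache[[key]] <- p
    p
  }
  trace <- function() {
    ns <- sort(as.integer(ls(cache)))
    data.frame(n = ns, power = vapply(as.character(ns), function(k) cache[[k]], 0))
  }
  lo <- 1L; hi <- 2L
  while (powf(hi) < target_power) {
    lo <- hi
    hi <- min(2L * hi, as.integer(n_max))
    if (lo >= n_max) {
      warning(sprintf("target power %.2f not reached within n_max = %d trials",
                      target_power, n_max))
      return(structure(list(time_snr = time_snr, alpha = alpha,
                            target_power = target_power, method = method,
                            n_required = NA_integer_, reached = FALSE,
                            replicates = replicates, trace = trace()),
                       class = "plan_estimate"))
    }
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (powf(mid) >= target_power) hi <- mid else lo <- mid
  }
  structure(list(time_snr = time_snr, alpha = alpha,
                 target_power = target_power, method = method,
                 n_required = hi, reached = TRUE, replicates = replicates,
                 trace = trace()),
            class = "plan_estimate")
}

#' @export
print.plan_estimate <- function(x, ...) {
  cat(sprintf("<plan_estimate> method = %s, SNR = %g, alpha = %g, power = %g\n",
              x$method, x$time_snr, x$alpha, x$target_power))
  if (isTRUE(x$reached)) {
    cat(sprintf("  required trials: %d (%d Monte-Carlo replicates)\n",
                x$n_required, x$replicates))
  } else {
    cat("  target power NOT reached within the trial budget\n")
  }
  invisible(x)
}

#' Estimate the SNR implied by a minimal detectable trial count
#'
#' Inverse of [required_trials()]: the smallest SNR at which `n_detect`
#' trials reach the target detection probability, found by bisection on the
#' log-SNR axis with common random numbers. Self-consistency
#' (`estimate_snr_from_trials(required_trials(s)) ~ s`) holds up to the
#' Monte-Carlo resolution of both searches.
#'
#' @inheritParams required_trials
#' @param n_detect minimal trial count at which detection was achieved.
#' @param snr_range search interval for the SNR.
#' @param iterations bisection steps.
#' @return list with `time_snr` (the estimate), `bracket`, `n_detect`,
#'   `method`.
#' @export
estimate_snr_from_trials <- function(n_detect, alpha = 0.05,
                                     target_power = 0.8,
                                     method = c("coherency", "spectral"),
                                     replicates = 100, seed = NULL,
                                     snr_range = c(0.005, 4), iterations = 12,
                                     f0 = 2.1, harmonic = 2, window = 5,
                                     fs = 1000) {
  method <- match.arg(method)
  stopifnot(n_detect >= 2)
  powf <- function(s) detection_power(n_detect, s, method, replicates, alpha,
                                      f0, harmonic, seed = seed,
                                      window = window, fs = fs,
                                      early_stop_target = target_power)$power
  lo <- snr_range[1]; hi <- snr_range[2]
  if (powf(lo) >= target_power) {
    warning("even the lowest SNR in `snr_range` is detectable with n_detect trials")
    return(list(time_snr = lo, bracket = c(NA, lo), n_detect = n_detect,
                method = method))
  }
  if (powf(hi) < target_power) {
    warning("the highest SNR in `snr_range` is not detectable with n_detect trials")
    return(list(time_snr = hi, bracket = c(hi, NA), n_detect = n_detect,
                method = method))
  }
  for (it in seq_len(iterations)) {
    mid <- sqrt(lo * hi)
    if (powf(mid) >= target_power) hi <- mid else lo <- mid
  }
  list(time_snr = sqrt(lo * hi), bracket = c(lo, hi), n_detect = n_detect,
       method = method)
}
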