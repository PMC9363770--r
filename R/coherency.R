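#' Per-trial Fourier spectrum of the analysis window
#'
#' FFT of the window starting at stimulus onset (default 5 s, giving a 0.2 Hz
#' frequency resolution at any sampling rate). Used internally by
#' [extract_phases()]; exported because the trial-planning module also needs
#' the complex bins.
#'
#' @param x a `trialset` with at least `window` seconds after onset.
#' @param window analysis window length, s.
#' @param fmin,fmax frequency range of bins to keep, Hz.
#' @param pad_factor integer zero-padding factor; 1 keeps the native
#'   `1/window` grid, larger values interpolate the grid (e.g. 2 places bins
#'   exactly on multiples of 0.1 Hz, covering all harmonics of 2.1 Hz).
#' @return list with `coef` (complex matrix, trials x frequencies) and `freqs`.
#' @export
trial_spectrum <- function(x, window = 5, fmin = 1, fmax = 15, pad_factor = 1) {
  stopifnot(inherits(x, "trialset"))
  N <- round(window * x$fs)
  if (ncol(x$data) - x$onset + 1 < N)
    stop(sprintf("trials are shorter than the %g s analysis window", window))
  seg <- x$data[, x$onset:(x$onset + N - 1), drop = FALSE]
  Nfft <- N * as.integer(pad_factor)
  M <- t(seg)
  if (Nfft > N) M <- rbind(M, matrix(0, Nfft - N, ncol(M)))
  X <- mvfft(M)
  binf <- (seq_len(Nfft) - 1) * x$fs / Nfft
  keep <- which(binf >= fmin - 1e-9 & binf <= fmax + 1e-9)
  list(coef = t(X[keep, , drop = FALSE]), freqs = binf[keep])
}

#' Extract per-trial phases on the analysis grid
#'
#' Takes the FFT of the window from stimulus onset and keeps only the phase
#' angle of each Fourier component, discarding the amplitude. With the default
#' 5 s window the grid runs from `fmin` to `fmax` in steps of 0.2 Hz
#' (71 bins for 1-15 Hz).
#'
#' @inheritParams trial_spectrum
#' @return An object of class `phase_table`: list with `phases` (radians in
#'   (-pi, pi], trials x frequencies), `freqs`, `n_trials`, `window`.
#' @export
extract_phases <- function(x, window = 5, fmin = 1, fmax = 15, pad_factor = 1) {
  sp <- trial_spectrum(x, window, fmin, fmax, pad_factor)
  structure(list(phases = Arg(sp$coef), freqs = sp$freqs,
                 n_trials = nrow(sp$coef), window = window, fs = x$fs),
            class = "phase_table")
}

#' Inter-trial phase coherency
#'
#' A coherency of 0 means the phase at a frequency is effectively random
#' across trials; 1 means it is always in the exact same phase. The default
#' estimator is the resultant length (magnitude of the mean unit phasor of
#' the trial phases), whose white-noise null 95th percentile follows the
#' Rayleigh closed form `sqrt(ln 20 / n)`. The alternative `ci_fraction`
#' estimator expresses one minus the width of the empirical `(1-alpha)`
#' confidence interval of the phase angles as a fraction of the full circle;
#' it is a documented approximation of the confidence-interval formulation.
#'
#' @param x a `phase_table` (from [extract_phases()]) or a `trialset`, in
#'   which case phases are extracted with default settings first.
#' @param estimator `"resultant_length"` or `"ci_fraction"`.
#' @param alpha confidence level parameter of the `ci_fraction` estimator.
#' @param ... passed to [extract_phases()] for the `trialset` method.
#' @return An object of class `coherency_spectrum`: list with `freqs`,
#'   `values` (each in [0, 1]), `estimator`, `n_trials`.
#' @export
coherency <- function(x, estimator = c("resultant_length", "ci_fraction"),
                      alpha = 0.05, ...) {
  if (inherits(x, "trialset")) x <- extract_phases(x, ...)
  stopifnot(inherits(x, "phase_table"))
  estimator <- match.arg(estimator)
  if (x$n_trials < 2L) stop("coherency needs at least 2 trials")
  vals <- coherency_values(x$phases, estimator, alpha)
  structure(list(freqs = x$freqs, values = vals, estimator = estimator,
                 n_trials = x$n_trials),
            class = "coherency_spectrum")
}

# Column-wise coherency of a phase matrix (trials x frequencies).
coherency_values <- function(phases, estimator = "resultant_length",
                             alpha = 0.05) {
  if (estimator == "resultant_length") {
    Mod(colMeans(exp(1i * phases)))
  } else {
    apply(phases, 2L, function(ph) {
      mu <- Arg(mean(exp(1i * ph)))
      dev <- abs(Arg(exp(1i * (ph - mu))))
      width <- 2 * quantile(dev, 1 - alpha, names = FALSE, type = 1)
      max(0, 1 - width / (2 * pi))
    })
  }
}

#' @export
print.coherency_spectrum <- function(x, ...) {
  cat(sprintf("<coherency_spectrum> %d bins (%.1f-%.1f Hz), %d trials, estimator = %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_trials, x$estimator))
  cat(sprintf("  max coherency %.3f at %.1f Hz\n",
              max(x$values), x$freqs[which.max(x$values)]))
  invisible(x)
}

#' Closed-form white-noise coherency threshold (Rayleigh limit)
#'
#' For n uniform phases the resultant length R satisfies
#' `P(R > r) = exp(-n r^2)` asymptotically, so the `p`-th percentile of the
#' null is `sqrt(-log(1 - p/100) / n)`; at the 95th percentile,
#' `sqrt(ln 20 / n)`. Serves as the analytic oracle for [null_threshold()].
#'
#' @param n_trials number of trials.
#' @param percentile percentile of the null distribution (default 95).
#' @return The threshold coherency value.
#' @export
rayleigh_threshold <- function(n_trials, percentile = 95) {
  stopifnot(all(n_trials >= 2), percentile > 0, percentile < 100)
  sqrt(-log(1 - percentile / 100) / n_trials)
}

#' Bootstrapped white-noise null threshold for coherency
#'
#' Generates `B` surrogate datasets containing only noise, each with the same
#' number of trials as the data, computes their coherency, and takes the given
#' percentile per frequency. Because in phase space noise is uniformly
#' distributed by principle, the default fast path draws i.i.d. uniform phases
#' directly per bin; `method = "white_noise"` simulates full white-noise time
#' series through [extract_phases()] instead (slower; the two paths agree and
#' this is verified in the test suite, not assumed).
#'
#' @param n_trials number of trials the threshold must match.
#' @param B number of surrogate datasets (default 10,000).
#' @param percentile percentile of the null distribution (default 95).
#' @param freqs frequencies (Hz) to label/simulate (default the 1-15 Hz grid).
#' @param seed integer seed.
#' @param method `"uniform_phase"` (fast path) or `"white_noise"`.
#' @param estimator coherency estimator, as in [coherency()].
#' @param fs,window sampling rate and window for the `white_noise` method.
#' @return An object of class `null_threshold`: list with `freqs`,
#'   `threshold` (per frequency), `null_samples` (B x n_freqs), `B`,
#'   `percentile`, `n_trials`, `method`.
#' @export
null_threshold <- function(n_trials, B = 10000, percentile = 95,
                           freqs = seq(1, 15, by = 0.2), seed = NULL,
                           method = c("uniform_phase", "white_noise"),
                           estimator = "resultant_length",
                           fs = 1000, window = 5) {
  stopifnot(n_trials >= 2, B >= 100)
  method <- match.arg(method)
  nf <- length(freqs)
  with_seed(seed, {
    if (method == "uniform_phase") {
      null <- matrix(0, B, nf)
      for (j in seq_len(nf)) {
        ph <- matrix(runif(n_trials * B, -pi, pi), n_trials, B)
        null[, j] <- if (estimator == "resultant_length") {
          Mod(colMeans(exp(1i * ph)))
        } else {
          coherency_values(ph, estimator)
        }
      }
    } else {
      null <- t(vapply(seq_len(B), function(b) {
        ts <- trialset(matrix(rnorm(n_trials * round(window * fs)),
                              n_trials), fs = fs, onset = 1L)
        pt <- extract_phases(ts, window = window,
                             fmin = min(freqs), fmax = max(freqs))
        idx <- vapply(freqs, function(f) which.min(abs(pt$freqs - f)), 0L)
        coherency_values(pt$phases, estimator)[idx]
      }, numeric(nf)))
      if (nf == 1L) null <- matrix(null, ncol = 1L)
    }
    thr <- apply(null, 2L, quantile, probs = percentile / 100, names = FALSE)
    structure(list(freqs = freqs, threshold = thr, null_samples = null,
                   B = B, percentile = percentile, n_trials = n_trials,
                   method = method, estimator = estimator, seed = seed),
              class = "null_threshold")
  })
}

#' Detect stimulus harmonics against the noise threshold
#'
#' Compares the coherency at the first `K` harmonics of the stimulus
#' frequency with the per-frequency null threshold. A harmonic is detected
#' when its coherency exceeds the threshold; with the default 10,000-dataset
#' 95th-percentile threshold this corresponds to p < 0.05. The exact p-value
#' is the exceedance rank within the retained null sample. Harmonics that do
#' not fall exactly on the analysis grid (e.g. 2.1 Hz on a 0.2 Hz grid) are
#' evaluated at the nearest bin and the offset is reported; use
#' `pad_factor = 2` in [extract_phases()] to place bins exactly on all
#' harmonics of 2.1 Hz.
#'
#' @param cs a `coherency_spectrum`.
#' @param null a `null_threshold` with matching `n_trials`.
#' @param f0 stimulus fundamental frequency, Hz.
#' @param K number of harmonics to test.
#' @return An object of class `harmonic_detection`: data.frame with one row
#'   per harmonic (`k`, `freq`, `bin_freq`, `bin_offset`, `coherency`,
#'   `threshold`, `detected`, `p_value`).
#' @export
detect_harmonics <- function(cs, null, f0 = 2.1, K = 6) {
  stopifnot(inherits(cs, "coherency_spectrum"), inherits(null, "null_threshold"))
  if (null$n_trials != cs$n_trials)
    warning("null threshold was computed for a different trial count")
  hf <- (1:K) * f0
  if (any(hf > max(cs$freqs) + 1e-9))
    stop("a requested harmonic lies above the maximum analysis frequency")
  df <- if (length(cs$freqs) > 1) min(diff(cs$freqs)) else 0.2
  rows <- lapply(seq_len(K), function(k) {
    f <- hf[k]
    i <- which.min(abs(cs$freqs - f))
    j <- which.min(abs(null$freqs - cs$freqs[i]))
    if (abs(null$freqs[j] - cs$freqs[i]) > df / 2 + 1e-9)
      stop("null threshold grid does not cover the analysis bin at ",
           cs$freqs[i], " Hz")
    obs <- cs$values[i]
    data.frame(k = k, freq = f, bin_freq = cs$freqs[i],
               bin_offset = cs$freqs[i] - f,
               coherency = obs, threshold = null$threshold[j],
               detected = obs > null$threshold[j],
               p_value = (1 + sum(null$null_samples[, j] >= obs)) / (null$B + 1))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("harmonic_detection", "data.frame")
  attr(out, "f0") <- f0
  attr(out, "n_trials") <- cs$n_trials
  out
}

#' Coherency signal-to-noise ratio
#'
#' The ratio of an observed coherency value to the noise threshold at the
#' same frequency and trial count. Pooling trials across participants lowers
#' the threshold (as `1/sqrt(n)`), which can raise this ratio even when the
#' pooled coherency value itself drops.
#'
#' @param coherency_value observed coherency (vectorised).
#' @param threshold_value noise threshold (> 0).
#' @return The dimensionless ratio.
#' @export
coherency_snr <- function(coherency_value, threshold_value) {
  if (any(threshold_value <= 0)) stop("threshold must be > 0")
  coherency_value / threshold_value
}

#' Plot a coherency spectrum with its noise threshold
#'
#' @param x a `coherency_spectrum`.
#' @param null optional `null_threshold` to draw as the noise line.
#' @param detections optional `harmonic_detection` whose detected harmonics
#'   are starred.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot_coherency <- function(x, null = NULL, detections = NULL, ...) {
  plot(x$freqs, x$values, type = "l", xlab = "Frequency (Hz)",
       ylab = "Coherency", ylim = c(0, 1), ...)
  if (!is.null(null)) lines(null$freqs, null$threshold, lty = 2, col = "grey40")
  if (!is.null(detections)) {
    d <- detections[detections$detected, ]
    if (nrow(d)) points(d$bin_freq, d$coherency + 0.04, pch = 8)
  }
  invisible(x)
}
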