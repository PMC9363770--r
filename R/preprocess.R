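#' Filter specification
#'
#' Band-pass plus mains notch, applied zero-phase (forward-backward) so the
#' phase of the analysis frequencies is not biased: the whole coherency
#' analysis lives in phase space, and a causal filter would add
#' frequency-dependent phase offsets. The realized magnitude response can be
#' measured with [measure_filter_response()].
#'
#' @param bandpass `c(low, high)` pass-band corner frequencies, Hz.
#' @param notch `c(low, high)` band-stop corner frequencies, Hz.
#' @param hp_order,lp_order,notch_order Butterworth orders of the high-pass,
#'   low-pass and band-stop stages (single-pass; the zero-phase application
#'   doubles the effective order).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(bandpass = c(0.1, 70), notch = c(48, 52),
                        hp_order = 2, lp_order = 8, notch_order = 2) {
  stopifnot(length(bandpass) == 2L, bandpass[1] > 0, bandpass[1] < bandpass[2])
  stopifnot(length(notch) == 2L, notch[1] < notch[2])
  if (notch[1] <= bandpass[1] || notch[2] >= bandpass[2])
    stop("the notch must lie inside the pass-band")
  structure(list(bandpass = bandpass, notch = notch, hp_order = hp_order,
                 lp_order = lp_order, notch_order = notch_order,
                 family = "butterworth", zero_phase = TRUE),
            class = "filter_spec")
}

make_filters <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$bandpass[2] >= nyq)
    stop("pass-band upper edge must be below the Nyquist frequency")
  list(
    hp = signal::butter(spec$hp_order, spec$bandpass[1] / nyq, type = "high"),
    lp = signal::butter(spec$lp_order, spec$bandpass[2] / nyq, type = "low"),
    notch = signal::butter(spec$notch_order, spec$notch / nyq, type = "stop")
  )
}

filter_vector <- function(x, filts) {
  x <- signal::filtfilt(filts$hp, x)
  x <- signal::filtfilt(filts$lp, x)
  signal::filtfilt(filts$notch, x)
}

#' Apply the band-pass and notch filters to a trial set
#'
#' Each trial is filtered zero-phase with the chain described by `spec`.
#' The specification is recorded in the trial set's metadata.
#'
#' @param x a `trialset` (or a numeric vector of continuous samples, in which
#'   case `fs` must be given).
#' @param spec a [filter_spec()].
#' @param fs sampling rate, only for the vector method.
#' @return The filtered input, same shape and class.
#' @export
apply_filters <- function(x, spec = filter_spec(), fs = NULL) {
  if (is.numeric(x)) {
    stopifnot(!is.null(fs))
    return(filter_vector(x, make_filters(spec, fs)))
  }
  stopifnot(inherits(x, "trialset"))
  filts <- make_filters(spec, x$fs)
  x$data <- t(apply(x$data, 1L, filter_vector, filts = filts))
  x$params$filter <- unclass(spec)
  x
}

#' Measure the realized magnitude/phase response of a filter chain
#'
#' Passes long probe sinusoids through the zero-phase chain and reports gain
#' (dB) and residual phase shift (degrees) at each frequency.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @param freqs probe frequencies, Hz.
#' @param duration probe duration, s.
#' @return data.frame with columns `freq`, `gain_db`, `phase_deg`.
#' @export
measure_filter_response <- function(spec = filter_spec(), fs = 1000,
                                    freqs = c(0.1, 1, 4.2, 10, 50, 70, 80),
                                    duration = 12) {
  filts <- make_filters(spec, fs)
  t <- seq(0, duration, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  out <- lapply(freqs, function(f) {
    x <- cos(2 * pi * f * t)
    y <- filter_vector(x, filts)
    ph <- function(v) Arg(sum(v[mid] * exp(-2i * pi * f * (mid - 1) / fs)))
    data.frame(freq = f,
               gain_db = 20 * log10(sqrt(mean(y[mid]^2) / mean(x[mid]^2))),
               phase_deg = ((ph(y) - ph(x) + pi) %% (2 * pi) - pi) * 180 / pi)
  })
  do.call(rbind, out)
}

#' Segment a continuous recording into onset-aligned trials
#'
#' Cuts windows of `pre` seconds before and `post` seconds after each onset
#' event, so that the onset falls on the same sample index in every trial.
#' Events too close to the recording edges are dropped with a warning.
#'
#' @param samples numeric vector, continuous single-channel recording.
#' @param fs sampling rate, Hz.
#' @param onsets 1-based sample indices of stimulus onsets, strictly increasing.
#' @param pre,post window extents in seconds (`pre` >= 1, `post` >= 5 for the
#'   standard analysis).
#' @return A `trialset`.
#' @export
segment_trials <- function(samples, fs, onsets, pre = 1, post = 5) {
  stopifnot(is.numeric(samples), all(diff(onsets) > 0))
  n_pre <- round(pre * fs)
  n_post <- round(post * fs)
  ok <- (onsets - n_pre) >= 1 & (onsets + n_post - 1) <= length(samples)
  if (!any(ok)) stop("no onset has enough context to segment a trial")
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge were dropped",
                    sum(!ok)))
  dat <- t(vapply(onsets[ok],
                  function(o) samples[(o - n_pre):(o + n_post - 1)],
                  numeric(n_pre + n_post)))
  trialset(dat, fs = fs, onset = n_pre + 1L,
           params = list(onsets = onsets[ok], pre = pre, post = post))
}

#' Trial rejection criteria
#'
#' Single-channel stand-ins for artifact rejection: an absolute peak-to-peak
#' amplitude ceiling (blink/movement transients) and a robust z-score ceiling
#' on trial variance (noisy trials).
#'
#' @param peak_to_peak_max maximum allowed peak-to-peak amplitude, microvolts.
#' @param variance_zmax maximum allowed robust z-score of trial variance
#'   (median/MAD across trials).
#' @return An object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(peak_to_peak_max = 200, variance_zmax = 5) {
  stopifnot(peak_to_peak_max > 0, variance_zmax > 0)
  structure(list(peak_to_peak_max = peak_to_peak_max,
                 variance_zmax = variance_zmax),
            class = "rejection_criteria")
}

#' Reject contaminated trials
#'
#' Flags trials whose peak-to-peak amplitude or robust variance z-score
#' exceeds the criteria and removes them from the set.
#'
#' @param x a `trialset` (filtered, segmented).
#' @param criteria a [rejection_criteria()].
#' @return list with `trialset` (good trials only) and `report`, a data.frame
#'   with one row per input trial (peak-to-peak, variance z, decision, reason).
#' @export
reject_trials <- function(x, criteria = rejection_criteria()) {
  stopifnot(inherits(x, "trialset"), inherits(criteria, "rejection_criteria"))
  p2p <- apply(x$data, 1L, function(r) diff(range(r)))
  v <- apply(x$data, 1L, var)
  mv <- median(v); sv <- mad(v)
  vz <- if (sv > 0) (v - mv) / sv else rep(0, length(v))
  bad_p2p <- p2p > criteria$peak_to_peak_max
  bad_var <- vz > criteria$variance_zmax
  rejected <- bad_p2p | bad_var
  reason <- rep("", length(rejected))
  reason[bad_p2p] <- "peak_to_peak"
  reason[bad_var & !bad_p2p] <- "variance"
  reason[bad_var & bad_p2p] <- "peak_to_peak+variance"
  report <- data.frame(trial = seq_along(rejected), peak_to_peak = p2p,
                       variance_z = vz, rejected = rejected, reason = reason,
                       stringsAsFactors = FALSE)
  if (sum(!rejected) < 2L)
    stop("fewer than 2 trials survive rejection; the coherency analysis needs n >= 2")
  good <- subset_trials(x, !rejected)
  good$trials$good <- TRUE
  good$params$rejection <- list(criteria = unclass(criteria),
                                n_in = length(rejected),
                                n_rejected = sum(rejected))
  list(trialset = good, report = report)
}
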