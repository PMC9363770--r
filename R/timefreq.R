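# Morlet (Gabor) continuous wavelet transform of all trials, via FFT
# convolution with analytic Gaussian kernels. Returns per-cell trial-mean
# power, the mean unit phasor (for ITC), and optionally per-trial power.
cwt_trials <- function(x, freqs, n_cycles, hop = 0.05, keep_trials = FALSE) {
  stopifnot(inherits(x, "trialset"))
  fs <- x$fs
  S <- ncol(x$data)
  n <- nrow(x$data)
  stopifnot(length(n_cycles) == length(freqs), all(n_cycles > 0))
  sigma_t <- n_cycles / (2 * pi * freqs)
  pad_n <- ceiling(3 * max(sigma_t) * fs)
  pad_n <- min(pad_n, S - 1L)
  P <- stats::nextn(S + 2L * pad_n, c(2L, 3L, 5L))
  fgrid <- (seq_len(P) - 1) * fs / P
  # analytic kernels: Gaussian around +f only, doubled (Hilbert convention)
  kernels <- lapply(seq_along(freqs), function(j) {
    g <- 2 * exp(-(fgrid - freqs[j])^2 / (2 * (freqs[j] / n_cycles[j])^2))
    g[fgrid > fs / 2] <- 0
    g
  })
  # hop grid in seconds relative to onset, covering the whole trial
  t_lo <- -(x$onset - 1L) / fs
  t_hi <- (S - x$onset) / fs
  times <- seq(ceiling(t_lo / hop) * hop, floor(t_hi / hop) * hop, by = hop)
  cell_idx <- x$onset + round(times * fs)

  nt <- length(times); nf <- length(freqs)
  p_sum <- matrix(0, nt, nf)
  z_sum <- matrix(0 + 0i, nt, nf)
  trial_power <- if (keep_trials) array(0, c(n, nt, nf)) else NULL
  for (i in seq_len(n)) {
    xi <- x$data[i, ]
    xp <- c(rev(xi[seq_len(pad_n)]), xi, rev(xi[(S - pad_n + 1L):S]))
    xp <- c(xp, numeric(P - length(xp)))
    X <- fft(xp)
    for (j in seq_len(nf)) {
      w <- fft(X * kernels[[j]], inverse = TRUE)[pad_n + cell_idx] / P
      pw <- Mod(w)^2
      p_sum[, j] <- p_sum[, j] + pw
      z_sum[, j] <- z_sum[, j] + w / pmax(Mod(w), .Machine$double.eps)
      if (keep_trials) trial_power[i, , j] <- pw
    }
  }
  list(times = times, freqs = freqs, power = p_sum / n, phasor = z_sum / n,
       trial_power = trial_power, n_trials = n,
       params = list(n_cycles = n_cycles, hop = hop, sigma_t = sigma_t,
                     sigma_f = freqs / n_cycles, pad_n = pad_n))
}

#' Event-related spectral perturbation (ERSP)
#'
#' Morlet-wavelet time-frequency power of each trial, averaged across trials
#' and expressed in dB relative to the mean pre-onset baseline power at the
#' same frequency: `10*log10(P(t, f) / B(f))`. The default kernels use
#' `n_cycles = 2*f` (a fixed 0.5 Hz spectral sd and ~0.32 s temporal sd),
#' recorded in the output metadata. Baseline cells closer than `onset_buffer`
#' seconds to stimulus onset are excluded from the baseline mean to avoid
#' leakage of post-onset power into the baseline estimate.
#'
#' @param x a `trialset` with at least 1 s pre-onset baseline.
#' @param freqs analysis frequencies, Hz (default 1-30 Hz, 1 Hz spacing).
#' @param n_cycles Morlet cycle count per frequency (default `2 * freqs`).
#' @param hop time step of the output grid, s.
#' @param baseline_window `c(lo, hi)` in s relative to onset (hi <= 0).
#' @param onset_buffer seconds adjacent to onset excluded from the baseline.
#' @param keep_trials keep per-trial power (needed by [significance_mask()]).
#' @return An object of class `timefreq_map` with `times` (s, relative to
#'   onset), `freqs`, `values` (dB, times x freqs), `power`, `baseline`,
#'   `mask` (NULL until [significance_mask()] is applied), `type = "ersp"`.
#' @export
ersp <- function(x, freqs = 1:30, n_cycles = 2 * freqs, hop = 0.05,
                 baseline_window = c(-1, 0), onset_buffer = 0.45,
                 keep_trials = TRUE) {
  stopifnot(baseline_window[1] < baseline_window[2], baseline_window[2] <= 0)
  if ((x$onset - 1) / x$fs < -baseline_window[1] - 1 / x$fs)
    stop("trials do not cover the requested baseline window")
  cw <- cwt_trials(x, freqs, n_cycles, hop, keep_trials = keep_trials)
  bsel <- cw$times >= baseline_window[1] - 1e-9 &
    cw$times <= baseline_window[2] - onset_buffer + 1e-9
  if (!any(bsel)) stop("no time cells fall inside the usable baseline window")
  baseline <- colMeans(cw$power[bsel, , drop = FALSE])
  vals <- 10 * log10(sweep(cw$power, 2L, baseline, `/`))
  structure(list(times = cw$times, freqs = freqs, values = vals,
                 power = cw$power, baseline = baseline,
                 baseline_cells = which(bsel),
                 trial_baseline = if (!is.null(cw$trial_power))
                   cw$trial_power[, bsel, , drop = FALSE] else NULL,
                 mask = NULL, type = "ersp", n_trials = cw$n_trials,
                 params = c(cw$params,
                            list(baseline_window = baseline_window,
                                 onset_buffer = onset_buffer))),
            class = "timefreq_map")
}

#' Inter-trial coherence over time (ITC map)
#'
#' Resultant length of the per-trial wavelet phases in each time-frequency
#' cell: 1 where the oscillation is in the same phase in every trial, near 0
#' where phases are random.
#'
#' @inheritParams ersp
#' @return A `timefreq_map` with `type = "itc"`; `values` lie in [0, 1].
#' @export
itc_timecourse <- function(x, freqs = 1:30, n_cycles = 2 * freqs, hop = 0.05) {
  if (nrow(x$data) < 2L) stop("ITC needs at least 2 trials")
  cw <- cwt_trials(x, freqs, n_cycles, hop, keep_trials = FALSE)
  structure(list(times = cw$times, freqs = freqs, values = Mod(cw$phasor),
                 power = cw$power, baseline = NULL, mask = NULL,
                 type = "itc", n_trials = cw$n_trials, params = cw$params),
            class = "timefreq_map")
}

#' @export
print.timefreq_map <- function(x, ...) {
  cat(sprintf("<timefreq_map:%s> %d x %d cells (%.2f..%.2f s, %g..%g Hz), %d trials\n",
              x$type, length(x$times), length(x$freqs), min(x$times),
              max(x$times), min(x$freqs), max(x$freqs), x$n_trials))
  if (!is.null(x$mask))
    cat(sprintf("  significant cells: %.1f%%\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Bootstrap significance mask for a time-frequency map
#'
#' For ERSP maps, a per-cell two-sided test against a null built by
#' resampling baseline latencies: in each bootstrap iteration every trial
#' contributes its power at a random baseline cell, and the across-trial mean
#' forms one null draw per frequency. For ITC maps, cells are compared with
#' the `(1-alpha)` quantile of the resultant length of `n` uniform phases.
#' Flags are per-cell and uncorrected for multiple comparisons.
#'
#' @param map a `timefreq_map`.
#' @param B_perm bootstrap iterations (>= 100).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return The map with its `mask` slot filled (TRUE = significant).
#' @export
significance_mask <- function(map, B_perm = 200, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(map, "timefreq_map"), B_perm >= 100)
  with_seed(seed, {
    if (map$type == "ersp") {
      tb <- map$trial_baseline
      if (is.null(tb))
        stop("per-trial baseline power missing; rerun ersp() with keep_trials = TRUE")
      n <- dim(tb)[1]; nb <- dim(tb)[2]; nf <- dim(tb)[3]
      tb_mat <- matrix(tb, n * nb, nf)  # (trial, cell) unrolled by column
      null <- matrix(0, B_perm, nf)
      for (b in seq_len(B_perm)) {
        # resample trials (with replacement) and a baseline latency per trial,
        # so the null carries both across-trial sampling variance and the
        # within-trial choice of baseline latency
        tr <- sample.int(n, n, replace = TRUE)
        pick <- (sample.int(nb, n, replace = TRUE) - 1L) * n + tr
        null[b, ] <- colMeans(tb_mat[pick, , drop = FALSE])
      }
      qlo <- apply(null, 2L, quantile, probs = alpha / 2, names = FALSE)
      qhi <- apply(null, 2L, quantile, probs = 1 - alpha / 2, names = FALSE)
      map$mask <- sweep(map$power, 2L, qhi, `>`) | sweep(map$power, 2L, qlo, `<`)
    } else {
      ph <- matrix(runif(map$n_trials * B_perm, -pi, pi), map$n_trials)
      q <- quantile(Mod(colMeans(exp(1i * ph))), 1 - alpha, names = FALSE)
      map$mask <- map$values > q
    }
    map$params$mask <- list(B_perm = B_perm, alpha = alpha, seed = seed)
    map
  })
}

#' Band-averaged ERSP summary
#'
#' Mean dB change over a frequency band and post-onset window. Only cells
#' whose kernel center frequency lies strictly inside the band are used: a
#' cell centered exactly on a band edge measures half of its power outside
#' the band. By default all cells in the band/window are averaged; with
#' `use_mask = TRUE` only significant cells enter the mean.
#'
#' @param map an ERSP `timefreq_map`.
#' @param bands named list of `c(f_lo, f_hi)` bands, Hz.
#' @param window post-onset time window `c(lo, hi)`, s.
#' @param use_mask average only over significant cells (requires a mask).
#' @return data.frame with one row per band: `band`, `f_lo`, `f_hi`,
#'   `mean_delta_db`, `n_cells`, `prop_significant`, `significant`.
#' @export
band_summary <- function(map, bands = list(alpha = c(8, 12), beta = c(13, 30)),
                         window = c(0.5, 4.5), use_mask = FALSE) {
  stopifnot(inherits(map, "timefreq_map"), map$type == "ersp")
  tsel <- map$times >= window[1] - 1e-9 & map$times <= window[2] + 1e-9
  rows <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    fsel <- map$freqs > b[1] & map$freqs < b[2]
    if (!any(fsel))
      stop("band ", bn, " lies outside the map's frequency grid")
    cells <- map$values[tsel, fsel, drop = FALSE]
    msk <- if (!is.null(map$mask)) map$mask[tsel, fsel, drop = FALSE] else NULL
    sel <- if (use_mask) {
      if (is.null(msk)) stop("use_mask = TRUE requires a significance mask")
      msk
    } else matrix(TRUE, nrow(cells), ncol(cells))
    data.frame(band = bn, f_lo = b[1], f_hi = b[2],
               mean_delta_db = mean(cells[sel]),
               n_cells = sum(sel),
               prop_significant = if (!is.null(msk)) mean(msk) else NA_real_,
               significant = if (!is.null(msk)) mean(msk) > 0.5 else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare driven-harmonic estimates at two frequency resolutions
#'
#' Computes coherency and amplitude at the driven harmonic from FFT windows
#' of length `1/resolution` seconds. A precisely set stimulus harmonic that
#' falls on the fine grid but between the bins of a coarse grid loses peak
#' height at the coarse resolution; broadband signals are insensitive to the
#' choice.
#'
#' @param x a `trialset`.
#' @param f0 stimulus fundamental, Hz.
#' @param harmonic harmonic index to evaluate.
#' @param resolutions frequency resolutions to compare, Hz.
#' @return data.frame with one row per resolution: `resolution`, `window`,
#'   `bin_freq`, `bin_offset`, `coherency`, `amplitude`.
#' @export
resolution_comparison <- function(x, f0 = 2.1, harmonic = 2,
                                  resolutions = c(1, 0.2)) {
  target <- harmonic * f0
  rows <- lapply(resolutions, function(res) {
    win <- 1 / res
    sp <- trial_spectrum(x, window = win, fmin = max(res, target - 2),
                        fmax = target + 2)
    i <- which.min(abs(sp$freqs - target))
    z <- sp$coef[, i]
    N <- round(win * x$fs)
    amp <- mean(2 * Mod(z) / N)
    data.frame(resolution = res, window = win, bin_freq = sp$freqs[i],
               bin_offset = sp$freqs[i] - target,
               coherency = Mod(mean(z / pmax(Mod(z), .Machine$double.eps))),
               amplitude = amp,
               # bandwidth-normalised: comparable across resolutions for
               # broadband signals (a bin integrates `resolution` Hz of noise)
               amplitude_density = amp / sqrt(res))
  })
  do.call(rbind, rows)
}

#' Plot a time-frequency map
#' @param x a `timefreq_map`.
#' @param ... passed to [image()].
#' @return Invisibly, `x`.
#' @export
plot_timefreq <- function(x, ...) {
  image(x$times, x$freqs, x$values, xlab = "Time (s)", ylab = "Frequency (Hz)",
        col = hcl.colors(64, "RdBu", rev = TRUE), ...)
  abline(v = 0, lty = 2)
  invisible(x)
}
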