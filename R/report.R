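#' Psychophysics detection proportions
#'
#' Tabulates the proportion of trials in which depth movement was reported,
#' per participant and condition.
#'
#' @param responses data.frame with columns `participant`, `condition` and
#'   logical `detected` (one row per trial).
#' @return data.frame with `participant`, `condition`, `n_trials`,
#'   `n_detected`, `proportion` (0-1) and `percent`.
#' @export
detection_proportion <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("participant", "condition", "detected") %in% names(responses)))
  if (nrow(responses) == 0L) stop("no responses supplied")
  agg <- aggregate(detected ~ participant + condition, data = responses,
                   FUN = function(d) c(n = length(d), k = sum(d)))
  out <- data.frame(participant = agg$participant, condition = agg$condition,
                    n_trials = agg$detected[, "n"],
                    n_detected = agg$detected[, "k"])
  out$proportion <- out$n_detected / out$n_trials
  out$percent <- 100 * out$proportion
  out[order(out$participant, out$condition), , drop = FALSE]
}

#' Peak disparity angular velocity at a harmonic
#'
#' The disparity plane travels the full excursion `2 * disparity_amp` once
#' per half... once per period of the harmonic in question, so the peak
#' angular velocity detectable at harmonic frequency `f` is
#' `2 * disparity_amp * f` degrees per second (e.g. 0.05 deg at 12.6 Hz gives
#' 1.26 deg/s; at 6.3 Hz, 0.63 deg/s).
#'
#' @param disparity_amp disparity amplitude, degrees.
#' @param harmonic_freq harmonic frequency, Hz (vectorised).
#' @return Peak angular velocity, degrees/second.
#' @export
disparity_velocity <- function(disparity_amp, harmonic_freq) {
  stopifnot(all(disparity_amp >= 0), all(harmonic_freq > 0))
  2 * disparity_amp * harmonic_freq
}

#' Declarative configuration for a full analysis run
#'
#' Collects every parameter of the pipeline in one list so that a run is
#' fully determined by the configuration and its seeds.
#'
#' @param f0 stimulus fundamental, Hz.
#' @param n_participants,trials_per_condition synthetic dataset size.
#' @param latency_spread across-participant latency sd, s.
#' @param snr named vector of broadband time-domain SNR per condition.
#' @param window analysis window, s.
#' @param B,percentile null-threshold bootstrap settings.
#' @param K harmonics tested.
#' @param bands ERSP summary bands, Hz.
#' @param run_timefreq compute ERSP/ITC maps for the pooled sets.
#' @param timefreq_freqs ERSP/ITC frequency grid, Hz.
#' @param filter apply the band-pass/notch chain before analysis.
#' @param psychophysics list with `n_trials` and named `p_detect` per
#'   condition used to simulate the behavioural table, or NULL to skip.
#' @param seed master seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(f0 = 2.1, n_participants = 4,
                            trials_per_condition = 134, latency_spread = 0.01,
                            snr = c(correlated = 0.5, anticorrelated = 0.1),
                            window = 5, B = 2000, percentile = 95, K = 6,
                            bands = list(alpha = c(8, 12), beta = c(13, 30)),
                            run_timefreq = TRUE, timefreq_freqs = 1:30,
                            filter = TRUE, psychophysics = list(
                              n_trials = 160,
                              p_detect = c(correlated = 0.95, anticorrelated = 0.05)),
                            seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "analysis_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) trial sets, preprocess, compute per-participant and
#' pooled coherency with harmonic detection, optional time-frequency maps,
#' the psychophysics table and a run manifest. Every output file name is
#' recorded in the manifest together with its MD5 hash; identical
#' configuration and seeds reproduce identical outputs for the deterministic
#' stages.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if missing).
#' @param dataset optional named list of `trialset` objects (as produced by
#'   [generate_dataset()] or read from disk); when NULL the dataset is
#'   simulated from the configuration.
#' @return Invisibly, a list with `out_dir`, `manifest`, `detections` (per
#'   condition) and `band_summaries`.
#' @export
run_pipeline <- function(config = analysis_config(), out_dir, dataset = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  files <- character(0)

  dataset <- stage("simulate", {
    if (is.null(dataset)) {
      conds <- lapply(names(config$snr), function(cn) {
        list(response = response_preset(cn), target_time_snr = config$snr[[cn]])
      })
      names(conds) <- names(config$snr)
      generate_dataset(config$n_participants, config$trials_per_condition,
                       latency_spread = config$latency_spread,
                       seed = sub_seed(config$seed, 100L),
                       conditions = conds,
                       schedule = stimulus_schedule(f0 = config$f0))
    } else dataset
  })

  dataset <- stage("preprocess", {
    lapply(dataset, function(ts) {
      if (config$filter) ts <- apply_filters(ts)
      reject_trials(ts)$trialset
    })
  })

  conditions <- unique(unlist(lapply(dataset, function(ts) ts$trials$condition)))
  detections <- list()
  stage("coherency", {
    for (cn in conditions) {
      sets <- Filter(function(ts) ts$trials$condition[1] == cn, dataset)
      per_part <- lapply(sets, function(ts) {
        cs <- coherency(ts, window = config$window)
        null <- null_threshold(cs$n_trials, B = config$B,
                               percentile = config$percentile,
                               freqs = cs$freqs,
                               seed = sub_seed(config$seed, 200L))
        list(cs = cs, det = detect_harmonics(cs, null, config$f0, config$K))
      })
      pooled <- pool_trials(sets)
      cs <- coherency(pooled, window = config$window)
      null <- null_threshold(cs$n_trials, B = config$B,
                             percentile = config$percentile, freqs = cs$freqs,
                             seed = sub_seed(config$seed, 201L))
      det <- detect_harmonics(cs, null, config$f0, config$K)
      detections[[cn]] <- det
      files <- c(files,
        write_tsv(data.frame(freq = cs$freqs, coherency = cs$values,
                             threshold = null$threshold),
                  file.path(out_dir, sprintf("coherency_pooled_%s.tsv", cn))),
        write_tsv(as.data.frame(det),
                  file.path(out_dir, sprintf("detection_pooled_%s.tsv", cn))))
      for (nm in names(sets)) {
        pp <- per_part[[nm]]
        files <- c(files,
          write_tsv(as.data.frame(pp$det),
                    file.path(out_dir, sprintf("detection_%s.tsv", nm))))
      }
      files <- files
    }
  })

  band_summaries <- list()
  if (isTRUE(config$run_timefreq)) stage("timefreq", {
    for (cn in conditions) {
      sets <- Filter(function(ts) ts$trials$condition[1] == cn, dataset)
      pooled <- pool_trials(sets)
      m <- ersp(pooled, freqs = config$timefreq_freqs)
      m <- significance_mask(m, B_perm = 200,
                             seed = sub_seed(config$seed, 300L))
      band_summaries[[cn]] <- band_summary(m, bands = config$bands)
      grid <- expand.grid(time = m$times, freq = m$freqs)
      grid$ersp_db <- as.vector(m$values)
      grid$significant <- as.vector(m$mask)
      files <- c(files,
        write_tsv(grid, file.path(out_dir, sprintf("ersp_pooled_%s.tsv", cn))),
        write_tsv(band_summaries[[cn]],
                  file.path(out_dir, sprintf("bands_pooled_%s.tsv", cn))))
    }
  })

  if (!is.null(config$psychophysics)) stage("psychophysics", {
    pp <- config$psychophysics
    resp <- with_seed(sub_seed(config$seed, 400L), {
      do.call(rbind, lapply(seq_len(config$n_participants), function(p) {
        do.call(rbind, lapply(names(pp$p_detect), function(cn) {
          data.frame(participant = sprintf("P%02d", p), condition = cn,
                     detected = runif(pp$n_trials) < pp$p_detect[[cn]])
        }))
      }))
    })
    files <- c(files, write_tsv(detection_proportion(resp),
                                 file.path(out_dir, "psychophysics.tsv")))
  })

  manifest <- stage("manifest", {
    man <- list(
      package_version = as.character(utils::packageVersion("freqtag")),
      config = unclass(config),
      config_hash = config_hash(config),
      outputs = lapply(setNames(nm = basename(files)), function(f)
        unname(tools::md5sum(file.path(out_dir, f)))),
      detected_harmonics = lapply(detections, function(d) d$k[d$detected])
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(out_dir = out_dir, manifest = manifest,
                 detections = detections, band_summaries = band_summaries))
}
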