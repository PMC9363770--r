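#' Construct a trial set
#'
#' A `trialset` holds single-channel EEG trials as a rectangular matrix
#' (rows = trials, columns = samples), aligned so that the stimulus onset
#' falls on the same sample index in every trial, together with per-trial
#' metadata (participant, condition, good flag).
#'
#' @param data numeric matrix, `n_trials x n_samples`, in microvolts.
#' @param fs sampling rate in samples/s.
#' @param onset 1-based column index of stimulus onset (t = 0).
#' @param participant character or factor, one entry per trial (recycled).
#' @param condition character, one entry per trial (recycled).
#' @param good logical, one entry per trial (recycled); rejection flag.
#' @param params list of provenance/parameter metadata carried along.
#'
#' @return An object of class `trialset`.
#' @export
trialset <- function(data, fs, onset,
                     participant = NA_character_, condition = NA_character_,
                     good = TRUE, params = list()) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(onset, "onset", positive = TRUE)
  n <- nrow(data)
  if (onset > ncol(data)) stop("`onset` lies beyond the trial length")
  trials <- data.frame(
    participant = rep_len(as.character(participant), n),
    condition   = rep_len(as.character(condition), n),
    good        = rep_len(as.logical(good), n),
    stringsAsFactors = FALSE
  )
  structure(list(data = data, fs = fs, onset = as.integer(onset),
                 trials = trials, params = params),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  pre <- (x$onset - 1) / x$fs
  post <- (ncol(x$data) - x$onset + 1) / x$fs
  cat(sprintf("<trialset> %d trials x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  cat(sprintf("  onset at sample %d (%.3f s pre, %.3f s post)\n",
              x$onset, pre, post))
  cond <- table(x$trials$condition, useNA = "ifany")
  cat("  conditions:", paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
  cat(sprintf("  good trials: %d/%d\n", sum(x$trials$good), nrow(x$data)))
  invisible(x)
}

#' Number of trials in a trial set
#' @param x a `trialset`.
#' @return integer trial count.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "trialset"))
  nrow(x$data)
}

#' Subset trials of a trial set
#' @param x a `trialset`.
#' @param i integer or logical index over trials.
#' @return a `trialset` with the selected trials.
#' @export
subset_trials <- function(x, i) {
  stopifnot(inherits(x, "trialset"))
  out <- x
  out$data <- x$data[i, , drop = FALSE]
  out$trials <- x$trials[i, , drop = FALSE]
  rownames(out$trials) <- NULL
  out
}

#' Pool several trial sets at the trial level
#'
#' Concatenates trials from multiple sets (e.g. participants) into one set,
#' with no per-participant weighting: in phase space every trial carries the
#' weight of one. Sets are aligned at stimulus onset and trimmed to the
#' shortest common pre- and post-onset extent. The detection threshold for the
#' pooled set must be recomputed at the pooled trial count.
#'
#' @param ... `trialset` objects, or a single list of them.
#' @return A pooled `trialset`.
#' @export
pool_trials <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "trialset")) sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "trialset")))
  fs <- unique(vapply(sets, function(s) s$fs, 0))
  if (length(fs) != 1L) stop("cannot pool trial sets with mismatched sampling rates")
  pre  <- min(vapply(sets, function(s) s$onset - 1L, 0L))
  post <- min(vapply(sets, function(s) ncol(s$data) - s$onset + 1L, 0L))
  dat <- do.call(rbind, lapply(sets, function(s) {
    s$data[, (s$onset - pre):(s$onset + post - 1L), drop = FALSE]
  }))
  trials <- do.call(rbind, lapply(sets, function(s) s$trials))
  rownames(trials) <- NULL
  out <- trialset(dat, fs = fs, onset = pre + 1L, params = sets[[1L]]$params)
  out$trials <- trials
  out
}

#' Write a trial set to disk (TSV matrix + JSON sidecar)
#'
#' The sample matrix is written as a tab-separated file (rows = trials) and
#' the metadata (sampling rate, onset index, per-trial labels, parameters) as
#' a JSON sidecar next to it.
#'
#' @param x a `trialset`.
#' @param path path of the TSV file; the sidecar gets the same path with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(x, path) {
  stopifnot(inherits(x, "trialset"))
  write.table(format(x$data, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  meta <- list(fs = x$fs, onset_index = x$onset, trials = x$trials,
               params = x$params)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trial set written by [write_trialset()]
#' @param path path of the TSV file.
#' @return a `trialset`.
#' @export
read_trialset <- function(path) {
  dat <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(dat) <- NULL
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  out <- trialset(dat, fs = as.numeric(meta$fs),
                  onset = as.integer(meta$onset_index),
                  params = as.list(meta$params))
  out$trials <- as.data.frame(meta$trials)
  out
}

# Common pre/post extent (seconds) of a trialset.
trial_extent <- function(x) {
  c(pre = (x$onset - 1) / x$fs,
    post = (ncol(x$data) - x$onset + 1) / x$fs)
}
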