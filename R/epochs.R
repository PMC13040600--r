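#' Epoched multi-channel EEG container
#'
#' An `epoch_set` holds one subject x session x task block of segmented EEG:
#' a trials x channels x samples array in microvolts, the sampling rate, the
#' epoch start time relative to cue onset, and one row of trial metadata per
#' trial. Trials flagged in `trial_meta$rejected` are retained in the tensor
#' (downstream consumers drop them), mirroring common ERP-toolbox behaviour
#' where rejection marks rather than deletes.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param sfreq sampling frequency in Hz.
#' @param t0_ms epoch start relative to cue onset (ms, non-positive for
#'   pre-stimulus baselines).
#' @param trial_meta data.frame with one row per trial. Recognised columns:
#'   `subject_id`, `group` (`"HC"`/`"ID"`), `session` (`"post_encoding"`,
#'   `"post_sleep"`, `"delayed"`), `condition` (`"negative"`/`"neutral"`),
#'   `trial_index`, `rejected` (logical). Missing ones are filled with
#'   defaults.
#' @param channel_labels optional character vector of channel names.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, t0_ms, trial_meta = NULL,
                      channel_labels = NULL) {
  if (length(dim(data)) != 3L)
    stop_emotraj("`data` must be a trials x channels x samples array",
                 "emotraj_parameter_error")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop_emotraj("`sfreq` must be a positive scalar", "emotraj_parameter_error")
  n_trials <- dim(data)[1L]
  if (is.null(trial_meta)) {
    trial_meta <- data.frame(trial_index = seq_len(n_trials))
  }
  if (nrow(trial_meta) != n_trials)
    stop_emotraj(sprintf(
      "trial_meta has %d rows but data has %d trials",
      nrow(trial_meta), n_trials), "emotraj_format_error")
  if (is.null(trial_meta$trial_index))
    trial_meta$trial_index <- seq_len(n_trials)
  if (is.null(trial_meta$rejected))
    trial_meta$rejected <- rep(FALSE, n_trials)
  if (!is.null(trial_meta$condition)) {
    bad <- setdiff(unique(as.character(trial_meta$condition)), CONDITIONS)
    if (length(bad))
      stop_emotraj(paste0("unknown condition label(s): ",
                          paste(bad, collapse = ", ")),
                   "emotraj_format_error")
  }
  n_samples <- dim(data)[3L]
  end_ms <- t0_ms + 1000 * n_samples / sfreq
  if (n_samples > 0 && !(t0_ms <= 0 && end_ms >= 0))
    stop_emotraj("epoch window must bracket cue onset (t0_ms <= 0 <= end)",
                 "emotraj_parameter_error")
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(dim(data)[2L]))
  if (anyDuplicated(channel_labels))
    stop_emotraj("channel labels must be unique", "emotraj_format_error")
  structure(list(data = data, sfreq = sfreq, t0_ms = t0_ms,
                 trial_meta = trial_meta,
                 channel_labels = as.character(channel_labels)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  window: %g .. %g ms; rejected: %d/%d\n", x$t0_ms,
              x$t0_ms + 1000 * d[3] / x$sfreq,
              sum(x$trial_meta$rejected), d[1]))
  invisible(x)
}

#' Epoch time axis in milliseconds
#'
#' @param ep an `epoch_set`.
#' @return numeric vector of sample times (ms relative to cue onset).
#' @export
epoch_times <- function(ep) {
  n <- dim(ep$data)[3L]
  ep$t0_ms + (seq_len(n) - 1L) * 1000 / ep$sfreq
}

#' Continuous multi-channel recording
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param sfreq sampling frequency (Hz).
#' @param channel_labels character vector, one per channel, unique.
#' @param reference reference channel description (free text, e.g. "CPz").
#' @return Object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, sfreq, channel_labels = NULL,
                                 reference = "unknown") {
  samples <- as.matrix(samples)
  if (!is.numeric(sfreq) || sfreq <= 0)
    stop_emotraj("sfreq must be > 0", "emotraj_parameter_error")
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(nrow(samples)))
  if (anyDuplicated(channel_labels))
    stop_emotraj("channel labels must be unique", "emotraj_format_error")
  structure(list(samples = samples, sfreq = sfreq,
                 channel_labels = as.character(channel_labels),
                 reference = reference),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (ref: %s)\n",
              nrow(x$samples), ncol(x$samples), x$sfreq, x$reference))
  invisible(x)
}

## keep only trials usable for decoding: not rejected and, when a recall
## measure column is present, flagged correct on it
retained_trials <- function(ep, measure = NULL) {
  keep <- !ep$trial_meta$rejected
  if (!is.null(measure)) {
    col <- ep$trial_meta[[measure]]
    if (is.null(col))
      stop_emotraj(sprintf("trial_meta has no column '%s'", measure),
                   "emotraj_parameter_error")
    keep <- keep & (as.logical(col) %in% TRUE)
  }
  which(keep)
}

subset_epochs <- function(ep, idx) {
  epoch_set(ep$data[idx, , , drop = FALSE], ep$sfreq, ep$t0_ms,
            ep$trial_meta[idx, , drop = FALSE], ep$channel_labels)
}
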