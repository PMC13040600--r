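## Wake-EEG preprocessing: zero-phase windowed-sinc FIR filtering, integer
## resampling, common-average re-reference, baseline correction, and
## moving-window peak-to-peak artifact rejection. No DSP package with FIR
## design is available in the dependency set, so the filters are designed
## here (Hamming-window method, the common default in EEG toolchains).

## symmetric windowed-sinc low-pass kernel; cutoff as fraction of Nyquist
fir_lowpass_kernel <- function(fc_norm, n_taps) {
  stopifnot(n_taps %% 2 == 1)
  m <- (n_taps - 1) / 2
  k <- seq(-m, m)
  h <- fc_norm * sinc(fc_norm * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)   # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## automatic tap count from transition bandwidth (Hamming: ~3.3/tbw)
fir_ntaps <- function(tbw_norm, max_taps = 32767L) {
  n <- ceiling(3.3 / tbw_norm)
  n <- min(n, max_taps)
  if (n %% 2 == 0) n <- n + 1
  as.integer(max(n, 11L))
}

## zero-phase filtering of a channels x time matrix with a symmetric FIR
## kernel: single pass + exact group-delay compensation, reflection padding
apply_fir <- function(x, h) {
  m <- (length(h) - 1) / 2
  nt <- ncol(x)
  pad <- min(m, nt - 1)
  idx_pre <- seq(pad + 1, 2)
  idx_post <- seq(nt - 1, nt - pad)
  out <- matrix(0, nrow(x), nt)
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    vp <- c(2 * v[1] - v[idx_pre], v, 2 * v[nt] - v[idx_post])
    f <- stats::filter(vp, h, method = "convolution", sides = 2)
    out[ch, ] <- f[(pad + 1):(pad + nt)]
  }
  out
}

## cap the kernel so its half-length fits the signal (reflection padding
## needs m <= n_time - 1); short signals get a wider effective transition
cap_taps <- function(n_taps, n_time) {
  n <- min(n_taps, 2L * (n_time - 1L) + 1L)
  if (n %% 2 == 0) n <- n - 1L
  max(n, 3L)
}

band_kernel <- function(low_hz, high_hz, sfreq, n_time = Inf) {
  nyq <- sfreq / 2
  ## band-pass = low-pass(high) minus low-pass(low); transition bandwidths
  ## follow the usual EEG-toolchain auto rule (quarter of the edge, >= 2 Hz
  ## where possible, never wider than the edge itself)
  tbw_lo <- min(max(low_hz * 0.25, 2), low_hz)
  tbw_hi <- min(max(high_hz * 0.25, 2), nyq - high_hz)
  n_taps <- max(fir_ntaps(tbw_lo / nyq), fir_ntaps(tbw_hi / nyq))
  n_taps <- cap_taps(n_taps, n_time)
  hp_edge <- low_hz / nyq
  lp_edge <- high_hz / nyq
  h_lp <- fir_lowpass_kernel(lp_edge, n_taps)
  h_lo <- fir_lowpass_kernel(hp_edge, n_taps)
  h_lp - h_lo
}

notch_kernel <- function(notch_hz, sfreq, width_hz = 2, n_time = Inf) {
  nyq <- sfreq / 2
  n_taps <- cap_taps(fir_ntaps((width_hz / 2) / nyq), n_time)
  lo <- (notch_hz - width_hz) / nyq
  hi <- (notch_hz + width_hz) / nyq
  h_stop <- fir_lowpass_kernel(hi, n_taps) - fir_lowpass_kernel(lo, n_taps)
  delta <- numeric(n_taps); delta[(n_taps + 1) / 2] <- 1
  delta - h_stop
}

#' Band-pass filter, notch filter, and resample a continuous recording
#'
#' Zero-phase FIR (Hamming-window design) band-pass and notch, followed by
#' integer-factor decimation to `target_sfreq`. The band edges must leave the
#' pass-band below the target Nyquist frequency so decimation needs no extra
#' anti-alias filter.
#'
#' @param rec a [continuous_recording()].
#' @param band numeric length-2, `(low_Hz, high_Hz)` pass band.
#' @param notch_hz mains frequency to notch out, or `NULL` to skip.
#' @param target_sfreq output sampling rate (Hz); must divide `rec$sfreq`.
#' @return A filtered, resampled [continuous_recording()].
#' @export
filter_resample <- function(rec, band = c(0.1, 30), notch_hz = 50,
                            target_sfreq = rec$sfreq) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$sfreq / 2
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= nyq)
    stop_emotraj("band must satisfy 0 < low < high < Nyquist",
                 "emotraj_parameter_error")
  if (target_sfreq > rec$sfreq)
    stop_emotraj("target_sfreq must not exceed the input rate",
                 "emotraj_parameter_error")
  factor <- rec$sfreq / target_sfreq
  if (abs(factor - round(factor)) > 1e-9)
    stop_emotraj("target_sfreq must divide the input sampling rate",
                 "emotraj_parameter_error")
  if (band[2] >= target_sfreq / 2)
    stop_emotraj("band upper edge must lie below the target Nyquist",
                 "emotraj_parameter_error")
  x <- rec$samples
  x <- apply_fir(x, band_kernel(band[1], band[2], rec$sfreq, ncol(x)))
  if (!is.null(notch_hz) && !is.na(notch_hz)) {
    if (notch_hz >= nyq)
      stop_emotraj("notch frequency above Nyquist", "emotraj_parameter_error")
    x <- apply_fir(x, notch_kernel(notch_hz, rec$sfreq, n_time = ncol(x)))
  }
  factor <- as.integer(round(factor))
  if (factor > 1L)
    x <- x[, seq(1, ncol(x), by = factor), drop = FALSE]
  continuous_recording(x, target_sfreq, rec$channel_labels, rec$reference)
}

## in-memory record of applied preprocessing steps; the encoding-task chain
## order (re-reference -> baseline -> reject) is enforced unless force = TRUE
preproc_history <- function(ep) {
  h <- attr(ep, "preproc_history")
  if (is.null(h)) character(0) else h
}

check_order <- function(ep, step, later_steps, force) {
  done <- intersect(preproc_history(ep), later_steps)
  if (length(done) && !force)
    stop_emotraj(sprintf(
      "out-of-order preprocessing: '%s' requested after '%s' (use force = TRUE to override)",
      step, paste(done, collapse = "', '")), "emotraj_order_error")
}

push_step <- function(ep, step) {
  attr(ep, "preproc_history") <- c(preproc_history(ep), step)
  ep
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample, the mean over channels, so the channel mean is
#' exactly zero everywhere afterwards. Idempotent. Refuses to run after
#' baseline correction or artifact rejection unless `force = TRUE` (the
#' encoding-task chain order is re-reference, baseline, reject).
#'
#' @param ep an [epoch_set()] (or a [continuous_recording()]).
#' @param force override the chain-order check.
#' @return The re-referenced object.
#' @export
rereference_common_average <- function(ep, force = FALSE) {
  if (inherits(ep, "continuous_recording")) {
    if (nrow(ep$samples) < 2)
      stop_emotraj("common-average reference needs >= 2 channels",
                   "emotraj_parameter_error")
    ep$samples <- sweep(ep$samples, 2, colMeans(ep$samples))
    ep$reference <- "common-average"
    return(ep)
  }
  stopifnot(inherits(ep, "epoch_set"))
  check_order(ep, "rereference", c("baseline", "reject"), force)
  d <- dim(ep$data)
  if (d[2] < 2)
    stop_emotraj("common-average reference needs >= 2 channels",
                 "emotraj_parameter_error")
  ## mean over channels per trial x sample
  chan_mean <- apply(ep$data, c(1, 3), mean)
  ep$data <- ep$data - aperm(array(chan_mean, c(d[1], d[3], d[2])),
                             c(1, 3, 2))
  push_step(ep, "rereference")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from every sample. Windows are half-open `[start, end)` in ms
#' relative to cue onset.
#'
#' @param ep an [epoch_set()].
#' @param window numeric length-2 `(start_ms, end_ms)` with
#'   `start < end <= 0`, inside the epoch.
#' @param force override the chain-order check (baseline precedes rejection).
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, window = c(-500, 0), force = FALSE) {
  stopifnot(inherits(ep, "epoch_set"))
  check_order(ep, "baseline", "reject", force)
  if (length(window) != 2 || window[1] >= window[2] || window[2] > 0)
    stop_emotraj("baseline window must satisfy start < end <= 0",
                 "emotraj_parameter_error")
  t_ms <- epoch_times(ep)
  sel <- which(t_ms >= window[1] & t_ms < window[2])
  if (length(sel) == 0 || window[1] < min(t_ms) - 1e-9)
    stop_emotraj("baseline window outside the epoch", "emotraj_parameter_error")
  base <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  d <- dim(ep$data)
  ep$data <- ep$data - array(base, c(d[1], d[2], d[3]))
  push_step(ep, "baseline")
}

#' Artifact-rejection report
#'
#' @param n_total total trial count.
#' @param n_rejected rejected trial count.
#' @param worst_ptp per-trial worst peak-to-peak amplitude (microvolts).
#' @param subject_id optional subject identifier.
#' @return Object of class `rejection_report`.
#' @export
rejection_report <- function(n_total, n_rejected, worst_ptp = numeric(0),
                             subject_id = NA_character_) {
  if (n_rejected > n_total || n_total < 0)
    stop_emotraj("n_rejected must not exceed n_total", "emotraj_parameter_error")
  structure(list(subject_id = subject_id, n_total = n_total,
                 n_rejected = n_rejected,
                 fraction_rejected = if (n_total > 0) n_rejected / n_total else 0,
                 worst_ptp = worst_ptp),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %s: %d/%d rejected (%.1f%%)\n",
              x$subject_id, x$n_rejected, x$n_total,
              100 * x$fraction_rejected))
  invisible(x)
}

#' Flag trials with moving-window peak-to-peak artifacts
#'
#' Scans each trial and channel with windows of `win_ms`, advancing by
#' `step_ms`; a trial is flagged rejected when any window on any channel has
#' peak-to-peak amplitude (max minus min) exceeding `thresh_uv`. The last
#' window is anchored at the epoch end when the step does not tile exactly,
#' so every sample is covered. Rejected trials are flagged in
#' `trial_meta$rejected`, not deleted.
#'
#' @param ep an [epoch_set()].
#' @param win_ms window length (ms).
#' @param step_ms step between window onsets (ms); must satisfy
#'   `win_ms >= step_ms > 0`.
#' @param thresh_uv peak-to-peak threshold (microvolts).
#' @return list with elements `epochs` (flagged `epoch_set`) and `report`
#'   (a [rejection_report()]).
#' @export
reject_artifacts <- function(ep, win_ms = 200, step_ms = 100,
                             thresh_uv = 100) {
  stopifnot(inherits(ep, "epoch_set"))
  if (!(win_ms >= step_ms && step_ms > 0))
    stop_emotraj("need win_ms >= step_ms > 0", "emotraj_parameter_error")
  d <- dim(ep$data)
  win_n <- max(2L, as.integer(round(win_ms / 1000 * ep$sfreq)))
  step_n <- max(1L, as.integer(round(step_ms / 1000 * ep$sfreq)))
  if (win_n > d[3])
    stop_emotraj("window longer than the epoch", "emotraj_parameter_error")
  starts <- seq(1L, d[3] - win_n + 1L, by = step_n)
  if (tail(starts, 1) + win_n - 1L < d[3])
    starts <- c(starts, d[3] - win_n + 1L)   # anchor last window at end
  worst <- numeric(d[1])
  for (tr in seq_len(d[1])) {
    m <- matrix(ep$data[tr, , ], d[2], d[3])
    w <- 0
    for (s in starts) {
      seg <- m[, s:(s + win_n - 1L), drop = FALSE]
      ptp <- apply(seg, 1, max) - apply(seg, 1, min)
      w <- max(w, ptp)
    }
    worst[tr] <- w
  }
  rejected <- worst > thresh_uv
  ep$trial_meta$rejected <- ep$trial_meta$rejected | rejected
  ep <- push_step(ep, "reject")
  rep_ <- rejection_report(d[1], sum(rejected), worst,
                           subject_id = if (!is.null(ep$trial_meta$subject_id))
                             as.character(ep$trial_meta$subject_id[1]) else NA)
  list(epochs = ep, report = rep_)
}

#' Exclude subjects with excess artifact trials
#'
#' A subject is excluded when the rejected fraction strictly exceeds
#' `max_fraction` (a fraction of exactly `max_fraction` is retained).
#'
#' @param reports list of [rejection_report()] objects, one per subject.
#' @param max_fraction exclusion threshold (default 0.20).
#' @return Character vector of excluded subject ids.
#' @export
exclude_subjects <- function(reports, max_fraction = 0.20) {
  if (length(reports) == 0) return(character(0))
  ids <- vapply(reports, function(r) as.character(r$subject_id), "")
  frac <- vapply(reports, function(r) r$fraction_rejected, 0)
  ids[frac > max_fraction]
}
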