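## Minimal EDF (European Data Format) reader/writer.
## EDF is the interchange format for the overnight recordings; no EDF package
## is available in the dependency set, so the subset needed here (continuous
## EDF, one sampling rate across channels) is implemented directly against the
## published header layout: 256-byte fixed header, 256 bytes per signal of
## per-signal fields, then 2-byte little-endian integers record by record.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a continuous recording to an EDF file
#'
#' Samples are scaled to 16-bit integers using per-channel physical ranges,
#' so a write/read round trip is exact only up to 16-bit quantization.
#' All channels share one sampling rate; the record duration is chosen so
#' that samples-per-record is integral.
#'
#' @param rec a [continuous_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  ns <- nrow(rec$samples)
  sfreq <- rec$sfreq
  ## one-second records when sfreq is integral, else a single long record
  if (abs(sfreq - round(sfreq)) < 1e-9) {
    spr <- as.integer(round(sfreq)); rec_dur <- 1
    n_rec <- ceiling(ncol(rec$samples) / spr)
  } else {
    spr <- ncol(rec$samples); rec_dur <- spr / sfreq; n_rec <- 1L
  }
  n_samp <- n_rec * spr
  x <- rec$samples
  if (n_samp > ncol(x))  # zero-pad the tail record
    x <- cbind(x, matrix(0, ns, n_samp - ncol(x)))

  ## physical ranges must survive the 8-char ASCII header field, so format
  ## first and digitize against the values as written
  pm_str <- formatC(pmin(floor(apply(x, 1, min)), -1), format = "d")
  px_str <- formatC(pmax(ceiling(apply(x, 1, max)), 1), format = "d")
  if (any(nchar(pm_str) > 8) || any(nchar(px_str) > 8))
    stop_emotraj("physical range too wide for EDF header",
                 "emotraj_format_error")
  phys_min <- as.numeric(pm_str)
  phys_max <- as.numeric(px_str)
  dig_min <- -32768; dig_max <- 32767
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round(sweep(sweep(x, 1, phys_min, "-"), 1, scale, "/")) + dig_min
  dig[dig < dig_min] <- dig_min; dig[dig > dig_max] <- dig_max

  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field(paste("Startdate 01-JAN-2026 X X", rec$reference), 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(format(rec_dur, digits = 8), 8),
    edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  per(rec$channel_labels, 16)
  per(rep("", ns), 80)
  per(rep("uV", ns), 8)
  per(pm_str, 8)
  per(px_str, 8)
  per(rep(dig_min, ns), 8)
  per(rep(dig_max, ns), 8)
  per(rep("", ns), 80)
  per(rep(spr, ns), 8)
  per(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a continuous recording
#'
#' Supports continuous EDF with a common sampling rate across signals.
#' Physical dimensions of mV or V are converted to microvolts on read.
#'
#' @param path EDF file path.
#' @return A [continuous_recording()] with samples in microvolts.
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop_emotraj(paste0("no such file: ", path), "emotraj_format_error")
  con <- file(path, "rb"); on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256)
    stop_emotraj("truncated EDF header", "emotraj_format_error")
  fld <- function(from, len) trimws(substr(fixed, from, from + len - 1))
  hdr_bytes <- suppressWarnings(as.integer(fld(185, 8)))
  n_rec <- suppressWarnings(as.integer(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  ns <- suppressWarnings(as.integer(fld(253, 4)))
  if (is.na(ns) || ns <= 0 || is.na(n_rec) || is.na(rec_dur) ||
      is.na(hdr_bytes) || hdr_bytes != 256 * (1 + ns))
    stop_emotraj("malformed EDF header", "emotraj_format_error")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256 * ns)
    stop_emotraj("truncated EDF signal header", "emotraj_format_error")
  take <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns) - 1L, function(i)
      trimws(substr(sig_hdr, start + i * width + 1,
                    start + (i + 1) * width)), "")
  }
  labels <- take(0, 16)
  phys_dim <- take(96, 8)          # 16+80 bytes precede
  phys_min <- as.numeric(take(104, 8))
  phys_max <- as.numeric(take(112, 8))
  dig_min <- as.numeric(take(120, 8))
  dig_max <- as.numeric(take(128, 8))
  spr <- as.integer(take(216, 8))  # after the 80-byte prefilter field
  if (any(is.na(spr)) || any(spr <= 0))
    stop_emotraj("malformed EDF signal header", "emotraj_format_error")
  if (length(unique(spr)) != 1L)
    stop_emotraj("mixed sampling rates across channels are not supported",
                 "emotraj_unsupported_dialect_error")
  spr <- spr[1]
  need <- as.double(n_rec) * ns * spr
  raw_vals <- readBin(con, "integer", n = need, size = 2, endian = "little")
  if (length(raw_vals) < need)
    stop_emotraj("truncated EDF data section", "emotraj_format_error")
  out <- matrix(0, ns, n_rec * spr)
  arr <- array(raw_vals, dim = c(spr, ns, n_rec))
  for (ch in seq_len(ns))
    out[ch, ] <- as.vector(arr[, ch, ])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- sweep(sweep(out, 1, dig_min, "-"), 1, gain, "*")
  out <- sweep(out, 1, phys_min, "+")
  unit_scale <- ifelse(tolower(phys_dim) %in% c("mv"), 1000,
                       ifelse(tolower(phys_dim) %in% c("v"), 1e6, 1))
  out <- sweep(out, 1, unit_scale, "*")
  continuous_recording(out, sfreq = spr / rec_dur, channel_labels = labels,
                       reference = "as-recorded")
}
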