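#' Hypnogram: 30-s sleep-stage sequence with arousals and lights markers
#'
#' Stages use AASM codes `W, N1, N2, N3, R`, one per 30-second epoch.
#' `lights_off_epoch` and `lights_on_epoch` are 0-based epoch boundaries:
#' the in-bed period spans stage epochs `lights_off_epoch + 1` through
#' `lights_on_epoch` (1-based indexing), so a 20-epoch night with lights off
#' at 0 and on at 20 is 10 minutes in bed.
#'
#' @param stages character vector of stage codes.
#' @param lights_off_epoch 0-based boundary where time in bed starts.
#' @param lights_on_epoch 0-based boundary where time in bed ends.
#' @param arousals data.frame with columns `onset_s`, `duration_s` (onsets
#'   in seconds from the start of the stage sequence).
#' @param subject_id optional subject identifier.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, lights_off_epoch = 0,
                      lights_on_epoch = length(stages),
                      arousals = NULL, subject_id = NA_character_) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad))
    stop_emotraj(paste0("unknown stage code(s): ", paste(bad, collapse = ", ")),
                 "emotraj_format_error")
  if (!(lights_off_epoch < lights_on_epoch &&
        lights_on_epoch <= length(stages) && lights_off_epoch >= 0))
    stop_emotraj("need 0 <= lights_off < lights_on <= length(stages)",
                 "emotraj_format_error")
  if (is.null(arousals))
    arousals <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  span <- c(lights_off_epoch, lights_on_epoch) * 30
  if (nrow(arousals) &&
      any(arousals$onset_s < span[1] | arousals$onset_s > span[2]))
    stop_emotraj("arousal onsets must lie within the lights-off span",
                 "emotraj_format_error")
  structure(list(stages = stages, lights_off_epoch = lights_off_epoch,
                 lights_on_epoch = lights_on_epoch, arousals = arousals,
                 subject_id = subject_id),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat(sprintf("<hypnogram> %d x 30-s epochs (%s); lights off %d, on %d; %d arousals\n",
              length(x$stages),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
              x$lights_off_epoch, x$lights_on_epoch, nrow(x$arousals)))
  invisible(x)
}

#' Write a hypnogram to the plain-text stage format
#'
#' One stage code per line; `#`-prefixed header lines carry the lights
#' markers and arousal events (`# arousal: <onset_s> <duration_s>`).
#'
#' @param h a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  lines <- c(
    sprintf("# lights_off_epoch: %d", h$lights_off_epoch),
    sprintf("# lights_on_epoch: %d", h$lights_on_epoch),
    if (!is.na(h$subject_id)) sprintf("# subject_id: %s", h$subject_id),
    if (nrow(h$arousals))
      sprintf("# arousal: %g\t%g", h$arousals$onset_s, h$arousals$duration_s),
    h$stages)
  writeLines(lines, path)
  invisible(path)
}

#' Read a hypnogram from the plain-text stage format
#'
#' @param path file path.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path))
    stop_emotraj(paste0("no such file: ", path), "emotraj_format_error")
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get1 <- function(key, default = NA) {
    m <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  ar_lines <- grep("^#\\s*arousal:", lines, value = TRUE)
  arousals <- if (length(ar_lines)) {
    vals <- do.call(rbind, lapply(ar_lines, function(l) {
      as.numeric(strsplit(trimws(sub("^#\\s*arousal:", "", l)), "[\t ]+")[[1]])
    }))
    data.frame(onset_s = vals[, 1], duration_s = vals[, 2])
  } else NULL
  stages <- trimws(lines[!hdr])
  stages <- stages[nzchar(stages)]
  off <- get1("lights_off_epoch", "0")
  on_ <- get1("lights_on_epoch", as.character(length(stages)))
  hypnogram(stages, as.integer(off), as.integer(on_), arousals,
            subject_id = get1("subject_id", NA_character_))
}
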