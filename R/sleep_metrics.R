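#' Sleep macrostructure metrics from a hypnogram
#'
#' Computes, for one night (the span between the lights markers):
#' time in bed (TIB), total sleep time (TST), sleep onset latency (SOL,
#' to the first epoch of any sleep stage), wake after sleep onset (WASO,
#' all wake from sleep onset to lights on, terminal wake included), sleep
#' efficiency (SE = 100 * TST / TIB), stage time in minutes and as a
#' percentage of TST for N1/N2/N3/REM, the arousal index (events per hour
#' of TST), and the SWS x REM composite (product of the N3 and REM
#' proportions of TST). Under the WASO convention used here the identity
#' `TIB = SOL + TST + WASO` holds exactly.
#'
#' With no sleep epochs, TST and SE are 0 and SOL, stage percentages, the
#' arousal index and the composite are `NA` (flagged undefined).
#'
#' @param h a [hypnogram()].
#' @return Object of class `sleep_metrics`: a list with elements `TIB_min`,
#'   `TST_min`, `SOL_min`, `WASO_min`, `SE_pct`, `stage_min`, `stage_pct`
#'   (named vectors over N1/N2/N3/REM), `arousal_index_per_h`,
#'   `sws_rem_product`, `subject_id`.
#' @export
compute_sleep_metrics <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  idx <- (h$lights_off_epoch + 1):h$lights_on_epoch
  st <- h$stages[idx]
  n_epochs <- length(st)
  if (n_epochs < 1)
    stop_emotraj("no epochs between lights markers", "emotraj_parameter_error")
  epmin <- 0.5   # 30-s epochs
  TIB <- n_epochs * epmin
  sleep <- st != "W"
  TST <- sum(sleep) * epmin
  stage_min <- c(N1 = sum(st == "N1"), N2 = sum(st == "N2"),
                 N3 = sum(st == "N3"), REM = sum(st == "R")) * epmin
  if (TST == 0) {
    out <- list(TIB_min = TIB, TST_min = 0, SOL_min = NA_real_,
                WASO_min = 0, SE_pct = 0, stage_min = stage_min,
                stage_pct = stats::setNames(rep(NA_real_, 4), names(stage_min)),
                arousal_index_per_h = NA_real_, sws_rem_product = NA_real_,
                subject_id = h$subject_id)
    return(structure(out, class = "sleep_metrics"))
  }
  onset <- which(sleep)[1]
  SOL <- (onset - 1) * epmin
  WASO <- sum(!sleep[onset:n_epochs]) * epmin
  SE <- 100 * TST / TIB
  stage_pct <- 100 * stage_min / TST
  n_arousals <- nrow(h$arousals)
  ai <- n_arousals / (TST / 60)
  swsrem <- (stage_min[["N3"]] / TST) * (stage_min[["REM"]] / TST)
  structure(list(TIB_min = TIB, TST_min = TST, SOL_min = SOL,
                 WASO_min = WASO, SE_pct = SE, stage_min = stage_min,
                 stage_pct = stage_pct, arousal_index_per_h = ai,
                 sws_rem_product = swsrem, subject_id = h$subject_id),
            class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf("<sleep_metrics> TIB %.1f  TST %.1f  SOL %s  WASO %.1f  SE %.1f%%\n",
              x$TIB_min, x$TST_min,
              ifelse(is.na(x$SOL_min), "NA", sprintf("%.1f", x$SOL_min)),
              x$WASO_min, x$SE_pct))
  cat(sprintf("  min: N1 %.1f N2 %.1f N3 %.1f REM %.1f; arousal idx %s/h; SWSxREM %s\n",
              x$stage_min[["N1"]], x$stage_min[["N2"]], x$stage_min[["N3"]],
              x$stage_min[["REM"]],
              ifelse(is.na(x$arousal_index_per_h), "NA",
                     sprintf("%.2f", x$arousal_index_per_h)),
              ifelse(is.na(x$sws_rem_product), "NA",
                     sprintf("%.4f", x$sws_rem_product))))
  invisible(x)
}

#' SWS x REM composite from computed metrics
#'
#' Product of the N3 and REM proportions of total sleep time (proportions,
#' not percentages); bounded by 0.25 on the simplex, `NA` when TST is 0.
#'
#' @param m a `sleep_metrics` object.
#' @return Numeric scalar in `[0, 0.25]`, or `NA`.
#' @export
sws_rem_product <- function(m) {
  stopifnot(inherits(m, "sleep_metrics"))
  if (m$TST_min <= 0) return(NA_real_)
  (m$stage_min[["N3"]] / m$TST_min) * (m$stage_min[["REM"]] / m$TST_min)
}

#' Tabulate sleep metrics for many subjects
#'
#' @param metrics list of `sleep_metrics` objects.
#' @return data.frame, one row per night, columns `subject_id`, `TIB_min`,
#'   `TST_min`, `SOL_min`, `WASO_min`, `SE_pct`, `N1_pct`, `N2_pct`,
#'   `N3_pct`, `REM_pct`, `arousal_index`, `sws_rem`.
#' @export
sleep_metrics_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m) data.frame(
    subject_id = m$subject_id, TIB_min = m$TIB_min, TST_min = m$TST_min,
    SOL_min = m$SOL_min, WASO_min = m$WASO_min, SE_pct = m$SE_pct,
    N1_pct = m$stage_pct[["N1"]], N2_pct = m$stage_pct[["N2"]],
    N3_pct = m$stage_pct[["N3"]], REM_pct = m$stage_pct[["REM"]],
    arousal_index = m$arousal_index_per_h, sws_rem = m$sws_rem_product,
    stringsAsFactors = FALSE)))
}
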