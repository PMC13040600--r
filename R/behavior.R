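#' Per-subject memory decay scores
#'
#' Decay = subject-level mean accuracy at `post_sleep` minus at `delayed`,
#' computed per emotion from the behavioral table. For
#' `measure = "objective"`, accuracy is the fraction of `"correct"`
#' responses; with `exclude_pass = TRUE`, `"pass"` trials are removed from
#' the denominator so incorrect recall reflects only incorrect judgments.
#' Other measures (`"subjective"`, `"identification"`, `"combined"`,
#' `"gist"`) are averaged as 0/1 or proportions; `"combined"` scores a cue
#' correct when both subjective and objective recall succeed.
#'
#' @param tbl behavioral table (see [simulate_behavior()]).
#' @param measure one of `"objective"`, `"subjective"`, `"combined"`,
#'   `"identification"`, `"gist"`.
#' @param emotion `"negative"` or `"neutral"`.
#' @param exclude_pass drop `"pass"` trials from the objective denominator.
#' @return Named numeric vector of decay scores by subject id; subjects
#'   missing a session are dropped with a warning, subjects with an empty
#'   denominator get `NA`.
#' @export
decay_scores <- function(tbl, measure = "objective", emotion = "negative",
                         exclude_pass = FALSE) {
  measure <- match.arg(measure, c("objective", "subjective", "combined",
                                  "identification", "gist"))
  emotion <- match.arg(emotion, CONDITIONS)
  sub <- tbl[tbl$emotion == emotion &
               tbl$session %in% c("post_sleep", "delayed"), , drop = FALSE]
  score_rows <- function(d) {
    switch(measure,
      objective = {
        if (exclude_pass) d <- d[d$objective_recall != "pass", , drop = FALSE]
        if (!nrow(d)) return(NA_real_)
        mean(d$objective_recall == "correct")
      },
      subjective = mean(d$subjective_recall),
      combined = mean(d$subjective_recall == 1 &
                        d$objective_recall == "correct"),
      identification = mean(d$identification, na.rm = TRUE),
      gist = mean(d$gist, na.rm = TRUE))
  }
  ids <- unique(sub$subject_id)
  out <- vapply(ids, function(id) {
    ps <- sub[sub$subject_id == id & sub$session == "post_sleep", , drop = FALSE]
    dl <- sub[sub$subject_id == id & sub$session == "delayed", , drop = FALSE]
    if (!nrow(ps) || !nrow(dl)) return(NA_real_)
    score_rows(ps) - score_rows(dl)
  }, 0)
  miss <- vapply(ids, function(id) {
    !all(c("post_sleep", "delayed") %in% sub$session[sub$subject_id == id])
  }, TRUE)
  if (any(miss)) {
    warning("dropping subject(s) missing a session: ",
            paste(ids[miss], collapse = ", "))
    out <- out[!miss]
  }
  out
}

#' Per-subject affect-change scores
#'
#' Change = mean rating at `delayed` minus at `post_sleep`, per emotion
#' (so a negative arousal change is an arousal reduction over the week).
#'
#' @param tbl behavioral table.
#' @param rating `"valence"` or `"arousal"`.
#' @param emotion `"negative"` or `"neutral"`.
#' @return Named numeric vector of change scores by subject id.
#' @export
affect_change_scores <- function(tbl, rating = "arousal",
                                 emotion = "negative") {
  rating <- match.arg(rating, c("valence", "arousal"))
  emotion <- match.arg(emotion, CONDITIONS)
  sub <- tbl[tbl$emotion == emotion &
               tbl$session %in% c("post_sleep", "delayed"), , drop = FALSE]
  ids <- unique(sub$subject_id)
  out <- vapply(ids, function(id) {
    ps <- sub[sub$subject_id == id & sub$session == "post_sleep", rating]
    dl <- sub[sub$subject_id == id & sub$session == "delayed", rating]
    if (!length(ps) || !length(dl)) return(NA_real_)
    mean(dl, na.rm = TRUE) - mean(ps, na.rm = TRUE)
  }, 0)
  drop <- is.na(out) & !vapply(ids, function(id)
    all(c("post_sleep", "delayed") %in% sub$session[sub$subject_id == id]),
    TRUE)
  if (any(drop)) {
    warning("dropping subject(s) missing a session: ",
            paste(ids[drop], collapse = ", "))
    out <- out[!drop]
  }
  out
}

#' Spearman rank correlation (average ranks on ties)
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  cor(rank(x), rank(y))
}

## two-sided p for Spearman's rho via the t approximation
spearman_p <- function(rho, n) {
  if (is.na(rho) || n < 4) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values (one family).
#' @return Adjusted p-values in the input order, monotone in raw p and
#'   capped at 1.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Spearman correlations between sleep metrics and a behavioral outcome,
#' FDR-corrected within the metric family
#'
#' Correlates each sleep-metric column with the outcome across subjects and
#' applies Benjamini-Hochberg within the family (one behavioral outcome x
#' group). The canonical family of 9 is TST, SE, WASO, the four stage
#' percentages, the arousal index, and the SWS x REM composite.
#'
#' @param sleep data.frame of per-subject sleep metrics with a `subject_id`
#'   column (see [sleep_metrics_table()]).
#' @param outcome named numeric vector of per-subject outcome values (names
#'   are subject ids), e.g. from [decay_scores()].
#' @param metrics character vector of metric columns; defaults to the
#'   9-metric family.
#' @param group optional group label recorded in the output.
#' @param outcome_name label recorded in the output.
#' @return data.frame (`group`, `sleep_metric`, `outcome`, `rho`, `p_raw`,
#'   `p_fdr`, `n`, `unreliable`); rows with fewer than 4 pairs are flagged
#'   unreliable.
#' @export
spearman_fdr <- function(sleep, outcome,
                         metrics = c("TST_min", "SE_pct", "WASO_min",
                                     "N1_pct", "N2_pct", "N3_pct",
                                     "REM_pct", "arousal_index", "sws_rem"),
                         group = NA_character_, outcome_name = "outcome") {
  missing_m <- setdiff(metrics, names(sleep))
  if (length(missing_m))
    stop_emotraj(paste0("sleep table lacks metric column(s): ",
                        paste(missing_m, collapse = ", ")),
                 "emotraj_parameter_error")
  ids <- intersect(sleep$subject_id, names(outcome))
  rows <- lapply(metrics, function(mcol) {
    x <- sleep[[mcol]][match(ids, sleep$subject_id)]
    y <- outcome[ids]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    rho <- if (n >= 2) spearman_rho(x[ok], y[ok]) else NA_real_
    data.frame(group = group, sleep_metric = mcol, outcome = outcome_name,
               rho = rho, p_raw = spearman_p(rho, n), n = n,
               unreliable = n < 4, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_fdr[ok] <- bh_adjust(out$p_raw[ok])
  out[, c("group", "sleep_metric", "outcome", "rho", "p_raw", "p_fdr",
          "n", "unreliable")]
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed
#' normal p, and Cohen's `q = atanh(r1) - atanh(r2)`.
#'
#' @param r1,n1 first correlation and its sample size.
#' @param r2,n2 second correlation and its sample size.
#' @return list(`z`, `p_twotailed`, `cohens_q`).
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_emotraj("|r| must be < 1 for the Fisher transform",
                 "emotraj_parameter_error")
  if (n1 < 4 || n2 < 4)
    stop_emotraj("need n >= 4 in both groups", "emotraj_parameter_error")
  q <- atanh(r1) - atanh(r2)
  z <- q / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_twotailed = 2 * pnorm(-abs(z)), cohens_q = q)
}

huber_weights <- function(r, k = 1.345) {
  w <- rep(1, length(r))
  big <- abs(r) > k
  w[big] <- k / abs(r[big])
  w
}

#' Huber robust linear regression (IRLS)
#'
#' Iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345, 95% Gaussian efficiency) and MAD scale re-estimated each
#' iteration, run to convergence (max coefficient change < `tol` or
#' `max_iter` sweeps). Standard errors use the classical Huber correction
#' `sum(psi^2) / (n - p) / mean(psi')^2 * (X'X)^{-1}`.
#'
#' @param y response vector.
#' @param X predictor matrix or data.frame (an intercept column is added).
#' @param k Huber tuning constant (default 1.345).
#' @param max_iter,tol IRLS budget and convergence tolerance.
#' @return list with `coefficients`, `se`, `t`, `p`, `scale`, `iterations`,
#'   `converged`, `weights`.
#' @export
huber_regression <- function(y, X, k = 1.345, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Xd); p <- ncol(Xd)
  if (n <= p)
    stop_emotraj("need more observations than predictors",
                 "emotraj_parameter_error")
  qrX <- qr(Xd)
  if (qrX$rank < p) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):p]]
    stop_emotraj(paste0("rank-deficient design; collinear column(s): ",
                        paste(bad, collapse = ", ")),
                 "emotraj_parameter_error")
  }
  beta <- qr.coef(qrX, y)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    r <- y - Xd %*% beta
    s <- median(abs(r)) / 0.6745
    if (s < 1e-10) { converged <- TRUE; break }   # (near-)exact fit
    w <- huber_weights(as.vector(r) / s, k)
    fit <- lm.wfit(Xd, y, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  r <- as.vector(y - Xd %*% beta)
  s <- median(abs(r)) / 0.6745
  if (s < 1e-10) s <- sqrt(sum(r^2) / max(1, n - p)) + 1e-10
  u <- r / s
  psi <- pmin(pmax(u, -k), k)
  dpsi <- as.numeric(abs(u) <= k)
  kappa <- mean(dpsi)
  v <- s^2 * sum(psi^2) / (n - p) / kappa^2
  XtXinv <- chol2inv(chol(crossprod(Xd)))
  se <- sqrt(pmax(0, diag(XtXinv) * v))
  tv <- as.vector(beta) / se
  structure(list(coefficients = stats::setNames(as.vector(beta),
                                                colnames(Xd)),
                 se = stats::setNames(se, colnames(Xd)),
                 t = stats::setNames(tv, colnames(Xd)),
                 p = stats::setNames(2 * pt(-abs(tv), df = n - p),
                                     colnames(Xd)),
                 scale = s, iterations = it, converged = converged,
                 weights = huber_weights(u, k)),
            class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  cat("<huber_fit> coefficients:\n")
  print(round(cbind(estimate = x$coefficients, se = x$se, t = x$t, p = x$p), 5))
  invisible(x)
}

#' Flag subjects beyond +/- k SD of the grand mean
#'
#' Participant-level sensitivity trimming: values more than `k` standard
#' deviations from the mean of `values` are flagged for exclusion.
#'
#' @param values named per-subject vector.
#' @param k SD multiple (default 3).
#' @return Character vector of flagged subject ids.
#' @export
trim_sd_subjects <- function(values, k = 3) {
  v <- values[is.finite(values)]
  if (length(v) < 3) return(character(0))
  m <- mean(v); s <- sd(v)
  if (s == 0) return(character(0))
  names(v)[abs(v - m) > k * s]
}
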