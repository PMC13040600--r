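#' Decoding configuration
#'
#' Settings for per-timepoint binary emotion decoding with a linear SVM and
#' temporal generalization.
#'
#' @param n_folds cross-validation folds for within-session decoding
#'   (default 4).
#' @param n_repeats repeats of the whole CV/subsampling scheme (default 50).
#' @param time_step_ms spacing of the decoding grid in ms (default 20);
#'   never finer than the sample period.
#' @param window_ms `(start_ms, end_ms)` restriction of the decoding grid,
#'   or `NULL` for the full epoch (the recall-task convention is
#'   `c(-200, 3000)`).
#' @param C SVM regularization constant (default 1).
#' @param pseudo_trial_size average this many same-class trials into one
#'   pseudo-trial before cross-validation (default 1 = single trials).
#' @param measure optional trial-selection column of `trial_meta`; only
#'   trials flagged correct on it (e.g. `"objective_correct"`) enter
#'   decoding.
#' @param max_epochs,tol SVM optimizer budget and stopping tolerance.
#' @param seed integer seed controlling subsampling, folds, and the
#'   optimizer's sweep order.
#' @return Object of class `decoding_config`.
#' @export
decoding_config <- function(n_folds = 4, n_repeats = 50, time_step_ms = 20,
                            window_ms = NULL, C = 1, pseudo_trial_size = 1,
                            measure = NULL, max_epochs = 500, tol = 1e-3,
                            seed = 1L) {
  if (n_folds < 2) stop_emotraj("n_folds must be >= 2", "emotraj_parameter_error")
  if (n_repeats < 1) stop_emotraj("n_repeats must be >= 1", "emotraj_parameter_error")
  if (time_step_ms <= 0) stop_emotraj("time_step_ms must be > 0",
                                      "emotraj_parameter_error")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 time_step_ms = time_step_ms, window_ms = window_ms,
                 classifier = "linear_svm", C = C,
                 balance = "subsample",
                 pseudo_trial_size = as.integer(pseudo_trial_size),
                 measure = measure, max_epochs = as.integer(max_epochs),
                 tol = tol, seed = as.integer(seed)),
            class = "decoding_config")
}

#' Train/test-time accuracy matrix for one subject and session pair
#'
#' @param accuracy numeric matrix, train times x test times, proportion
#'   correct (balanced accuracy).
#' @param times_ms decoding grid (ms).
#' @param train_session,test_session session tokens.
#' @param subject_id subject identifier.
#' @return Object of class `decoding_result` with `chance = 0.5`.
#' @export
decoding_result <- function(accuracy, times_ms, train_session, test_session,
                            subject_id = NA_character_) {
  accuracy <- as.matrix(accuracy)
  if (any(accuracy < 0 | accuracy > 1, na.rm = TRUE))
    stop_emotraj("accuracies must lie in [0, 1]", "emotraj_format_error")
  if (nrow(accuracy) != length(times_ms) || ncol(accuracy) != length(times_ms))
    stop_emotraj("accuracy dims must match the times grid",
                 "emotraj_format_error")
  structure(list(accuracy = accuracy, times_ms = times_ms,
                 train_session = train_session, test_session = test_session,
                 subject_id = subject_id, chance = 0.5),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s: train %s -> test %s; %d x %d grid; mean acc %.3f\n",
              x$subject_id, x$train_session, x$test_session,
              nrow(x$accuracy), ncol(x$accuracy), mean(x$accuracy)))
  invisible(x)
}

## decoding grid as 0-based sample indices + times
decode_grid <- function(ep, cfg) {
  t_ms <- epoch_times(ep)
  step_n <- max(1L, as.integer(round(cfg$time_step_ms / 1000 * ep$sfreq)))
  idx <- seq(1L, length(t_ms), by = step_n)
  if (!is.null(cfg$window_ms)) {
    keep <- t_ms[idx] >= cfg$window_ms[1] & t_ms[idx] <= cfg$window_ms[2]
    idx <- idx[keep]
  }
  if (!length(idx))
    stop_emotraj("decoding window excludes every sample",
                 "emotraj_parameter_error")
  list(idx0 = idx - 1L, times_ms = t_ms[idx])
}

cond_sign <- function(cond) ifelse(cond == "negative", 1L, -1L)

## average groups of k same-class trials into pseudo-trials (random grouping)
make_pseudo <- function(dat, y, k) {
  if (k <= 1L) return(list(dat = dat, y = y))
  keep_dat <- list(); keep_y <- integer(0)
  for (cls in c(1L, -1L)) {
    j <- sample(which(y == cls))
    ng <- length(j) %/% k
    if (ng == 0) next
    for (g in seq_len(ng)) {
      grp <- j[((g - 1) * k + 1):(g * k)]
      m <- apply(dat[grp, , , drop = FALSE], c(2, 3), mean)
      keep_dat[[length(keep_dat) + 1L]] <- m
      keep_y <- c(keep_y, cls)
    }
  }
  d <- dim(dat)
  arr <- array(0, c(length(keep_y), d[2], d[3]))
  for (i in seq_along(keep_y)) arr[i, , ] <- keep_dat[[i]]
  list(dat = arr, y = keep_y)
}

#' Within-session temporal-generalization decoding
#'
#' For each repeat, the two classes are balanced by randomly subsampling the
#' majority class, trials are assigned to stratified folds, and for each
#' fold a linear SVM is trained at every grid time on the channel voltages
#' (z-scored with training-fold statistics) and evaluated at every grid
#' time of the held-out fold. Accuracies (balanced) are averaged over folds
#' and repeats.
#'
#' @param ep an [epoch_set()] holding one subject x session.
#' @param cfg a [decoding_config()].
#' @return A [decoding_result()] with `train_session == test_session`.
#' @export
decode_within_session <- function(ep, cfg = decoding_config()) {
  stopifnot(inherits(ep, "epoch_set"))
  keep <- retained_trials(ep, cfg$measure)
  y_all <- cond_sign(ep$trial_meta$condition[keep])
  n_pos <- sum(y_all == 1L); n_neg <- sum(y_all == -1L)
  k <- cfg$pseudo_trial_size
  if (min(n_pos, n_neg) %/% max(1L, k) < cfg$n_folds)
    stop_emotraj(sprintf(
      "insufficient trials per class (%d vs %d) for %d folds",
      n_pos, n_neg, cfg$n_folds), "emotraj_insufficient_data_error")
  grid <- decode_grid(ep, cfg)
  dat <- ep$data[keep, , , drop = FALSE]
  session <- as.character(ep$trial_meta$session[keep][1])
  sid <- as.character(ep$trial_meta$subject_id[keep][1])

  with_seed(cfg$seed, {
    acc_sum <- 0
    n_mats <- 0L
    for (r in seq_len(cfg$n_repeats)) {
      n_bal <- min(n_pos, n_neg)
      sel <- c(sample(which(y_all == 1L), n_bal),
               sample(which(y_all == -1L), n_bal))
      dat_r <- dat[sel, , , drop = FALSE]
      y_r <- y_all[sel]
      ps <- make_pseudo(dat_r, y_r, k)
      dat_r <- ps$dat; y_r <- ps$y
      folds <- integer(length(y_r))
      for (cls in c(1L, -1L)) {
        j <- which(y_r == cls)
        folds[j] <- sample(rep(seq_len(cfg$n_folds), length.out = length(j)))
      }
      for (f in seq_len(cfg$n_folds)) {
        tr <- folds != f; te <- !tr
        a <- decode_tg_cpp(dat_r[tr, , , drop = FALSE], y_r[tr],
                           dat_r[te, , , drop = FALSE], y_r[te],
                           grid$idx0, grid$idx0,
                           cfg$C, cfg$max_epochs, cfg$tol)
        acc_sum <- acc_sum + a
        n_mats <- n_mats + 1L
      }
    }
    decoding_result(acc_sum / n_mats, grid$times_ms, session, session, sid)
  })
}

#' Between-session temporal-generalization decoding
#'
#' Trains on all retained trials of one session and tests on all retained
#' trials of another (no cross-validation: the sessions are independent
#' sets). Per repeat, each session is balanced by random subsampling;
#' results are averaged over repeats.
#'
#' @param ep_train,ep_test [epoch_set()] objects for the same subject with
#'   identical channel sets and time axes.
#' @param cfg a [decoding_config()].
#' @return A [decoding_result()].
#' @export
decode_between_sessions <- function(ep_train, ep_test,
                                    cfg = decoding_config()) {
  stopifnot(inherits(ep_train, "epoch_set"), inherits(ep_test, "epoch_set"))
  if (!identical(ep_train$channel_labels, ep_test$channel_labels) ||
      dim(ep_train$data)[2] != dim(ep_test$data)[2])
    stop_emotraj("channel sets differ between sessions",
                 "emotraj_alignment_error")
  if (abs(ep_train$sfreq - ep_test$sfreq) > 1e-9 ||
      abs(ep_train$t0_ms - ep_test$t0_ms) > 1e-9 ||
      dim(ep_train$data)[3] != dim(ep_test$data)[3])
    stop_emotraj("time axes differ between sessions",
                 "emotraj_alignment_error")
  keep_tr <- retained_trials(ep_train, cfg$measure)
  keep_te <- retained_trials(ep_test, cfg$measure)
  y_tr <- cond_sign(ep_train$trial_meta$condition[keep_tr])
  y_te <- cond_sign(ep_test$trial_meta$condition[keep_te])
  if (min(sum(y_tr == 1), sum(y_tr == -1)) < 2 ||
      min(sum(y_te == 1), sum(y_te == -1)) < 1)
    stop_emotraj("insufficient trials per class",
                 "emotraj_insufficient_data_error")
  grid <- decode_grid(ep_train, cfg)
  dat_tr <- ep_train$data[keep_tr, , , drop = FALSE]
  dat_te <- ep_test$data[keep_te, , , drop = FALSE]
  s_tr <- as.character(ep_train$trial_meta$session[keep_tr][1])
  s_te <- as.character(ep_test$trial_meta$session[keep_te][1])
  sid <- as.character(ep_train$trial_meta$subject_id[keep_tr][1])

  with_seed(cfg$seed, {
    acc_sum <- 0
    for (r in seq_len(cfg$n_repeats)) {
      bal <- function(y) {
        nb <- min(sum(y == 1), sum(y == -1))
        c(sample(which(y == 1), nb), sample(which(y == -1), nb))
      }
      i_tr <- bal(y_tr); i_te <- bal(y_te)
      a <- decode_tg_cpp(dat_tr[i_tr, , , drop = FALSE], y_tr[i_tr],
                         dat_te[i_te, , , drop = FALSE], y_te[i_te],
                         grid$idx0, grid$idx0, cfg$C, cfg$max_epochs, cfg$tol)
      acc_sum <- acc_sum + a
    }
    decoding_result(acc_sum / cfg$n_repeats, grid$times_ms, s_tr, s_te, sid)
  })
}

#' The 3 x 3 session grid of decoding results for one subject
#'
#' Diagonal cells are within-session cross-validated decoding; off-diagonal
#' cells are between-session generalization, computed separately for both
#' train/test orders.
#'
#' @param subject a subject record (list with `subject_id` and `sessions`,
#'   a named list of three [epoch_set()] objects), e.g. one element of
#'   [simulate_eeg_sessions()].
#' @param cfg a [decoding_config()].
#' @return 3 x 3 list-matrix of [decoding_result()] objects with
#'   train sessions in rows and test sessions in columns.
#' @export
build_session_matrix <- function(subject, cfg = decoding_config()) {
  miss <- setdiff(SESSIONS, names(subject$sessions))
  if (length(miss))
    stop_emotraj(paste0("missing session(s): ", paste(miss, collapse = ", ")),
                 "emotraj_insufficient_data_error")
  out <- matrix(list(), 3, 3, dimnames = list(SESSIONS, SESSIONS))
  for (a in SESSIONS) {
    for (b in SESSIONS) {
      cfg_ab <- cfg
      cfg_ab$seed <- child_seed(cfg$seed, subject$subject_id, a, b)
      out[[a, b]] <- if (a == b)
        decode_within_session(subject$sessions[[a]], cfg_ab)
      else
        decode_between_sessions(subject$sessions[[a]], subject$sessions[[b]],
                                cfg_ab)
    }
  }
  out
}
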