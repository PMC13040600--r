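## small decodable epoch set: constant offset on one channel inside a window
offset_epochs <- function(n_per_class = 16, n_channels = 4, n_samples = 50,
                          sfreq = 100, t0_ms = -100, offset = 5,
                          win = 26:40, noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  dat <- array(rnorm(n * n_channels * n_samples, sd = noise_sd),
               c(n, n_channels, n_samples))
  cond <- rep(c("negative", "neutral"), each = n_per_class)
  dat[cond == "negative", 1, win] <- dat[cond == "negative", 1, win] + offset
  meta <- data.frame(subject_id = "S01", session = "post_encoding",
                     condition = cond, trial_index = 1:n, rejected = FALSE,
                     stringsAsFactors = FALSE)
  epoch_set(dat, sfreq, t0_ms, meta)
}

test_that("separable classes reach ceiling inside the window; oracle agrees", {
  ep <- offset_epochs(offset = 8)
  cfg <- decoding_config(n_repeats = 3, time_step_ms = 100, seed = 2)
  res <- decode_within_session(ep, cfg)
  t_in <- which(res$times_ms >= 160 & res$times_ms <= 280)
  t_out <- which(res$times_ms <= 0)
  expect_gt(mean(res$accuracy[t_in, t_in]), 0.95)
  expect_lt(mean(res$accuracy[t_out, t_out]), 0.75)
  ## independent nearest-centroid oracle at a window sample
  y <- ifelse(ep$trial_meta$condition == "negative", 1, -1)
  tr <- seq_along(y) %% 2 == 0
  oracle <- nc_decode(ep$data[tr, , , drop = FALSE], y[tr],
                      ep$data[!tr, , , drop = FALSE], y[!tr], 30, 30)
  expect_gt(oracle, 0.95)
})

test_that("decoding is deterministic under a fixed seed", {
  ep <- offset_epochs()
  cfg <- decoding_config(n_repeats = 2, time_step_ms = 100, seed = 9)
  r1 <- decode_within_session(ep, cfg)
  r2 <- decode_within_session(ep, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  cfg2 <- cfg; cfg2$seed <- 10
  r3 <- decode_within_session(ep, cfg2)
  expect_false(identical(r1$accuracy, r3$accuracy))
})

test_that("signal-free data with permuted labels decodes at chance", {
  set.seed(33)
  accs <- vapply(1:6, function(s) {
    ep <- offset_epochs(offset = 0, seed = 100 + s)
    ep$trial_meta$condition <- sample(ep$trial_meta$condition)
    cfg <- decoding_config(n_repeats = 3, time_step_ms = 50, seed = s)
    mean(decode_within_session(ep, cfg)$accuracy)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("trial order permutation leaves expected accuracy unchanged", {
  ep <- offset_epochs(offset = 8)
  cfg <- decoding_config(n_repeats = 4, time_step_ms = 100, seed = 5)
  r1 <- decode_within_session(ep, cfg)
  set.seed(6)
  perm <- sample(dim(ep$data)[1])
  ep2 <- epoch_set(ep$data[perm, , , drop = FALSE], ep$sfreq, ep$t0_ms,
                   ep$trial_meta[perm, ], ep$channel_labels)
  r2 <- decode_within_session(ep2, cfg)
  expect_lt(max(abs(mean(r1$accuracy) - mean(r2$accuracy))), 0.05)
})

test_that("the trial-selection measure gates decoding trials", {
  ep <- offset_epochs(offset = 8, n_per_class = 24)
  ## poison half the trials with label-flipping signal, flag them incorrect
  bad <- c(1:12, 25:36)
  ep$data[bad, 1, 26:40] <- -ep$data[bad, 1, 26:40]
  ep$trial_meta$objective_correct <- !(seq_len(48) %in% bad)
  cfg_all <- decoding_config(n_repeats = 3, time_step_ms = 100, seed = 3)
  cfg_sel <- decoding_config(n_repeats = 3, time_step_ms = 100, seed = 3,
                             measure = "objective_correct")
  acc_all <- decode_within_session(ep, cfg_all)$accuracy
  acc_sel <- decode_within_session(ep, cfg_sel)$accuracy
  t_in <- 4   # grid time 200 ms, inside the injected window
  expect_gt(mean(acc_sel[t_in, t_in]), 0.9)
  expect_lt(mean(acc_all[t_in, t_in]), mean(acc_sel[t_in, t_in]) - 0.2)
  expect_error(decode_within_session(
    ep, decoding_config(measure = "nonexistent")),
    class = "emotraj_parameter_error")
})

test_that("rejected trials never enter decoding", {
  ep <- offset_epochs(offset = 8, n_per_class = 20)
  ## corrupt 8 trials per class and flag them rejected
  ep$data[c(1:8, 21:28), , ] <- 0
  ep$trial_meta$rejected[c(1:8, 21:28)] <- TRUE
  cfg <- decoding_config(n_repeats = 2, time_step_ms = 100, seed = 4)
  res <- decode_within_session(ep, cfg)
  expect_gt(res$accuracy[4, 4], 0.9)  # grid time 200 ms
})

test_that("insufficient trials raise the dedicated error", {
  ep <- offset_epochs(n_per_class = 3)
  expect_error(decode_within_session(ep, decoding_config(n_folds = 4)),
               class = "emotraj_insufficient_data_error")
})

test_that("between-session: self-pair is optimistic, mismatches error", {
  ep <- offset_epochs(offset = 3, noise_sd = 2)
  cfg <- decoding_config(n_repeats = 3, time_step_ms = 100, seed = 7)
  within <- decode_within_session(ep, cfg)
  self_pair <- decode_between_sessions(ep, ep, cfg)
  expect_gte(mean(self_pair$accuracy) + 1e-9, mean(within$accuracy))

  ep2 <- offset_epochs(n_channels = 5)
  expect_error(decode_between_sessions(ep, ep2, cfg),
               class = "emotraj_alignment_error")
  ep3 <- offset_epochs()
  ep3$t0_ms <- -200
  expect_error(decode_between_sessions(ep, ep3, cfg),
               class = "emotraj_alignment_error")
})

test_that("session grid: 9 cells, 3 within, all accuracies in [0, 1]", {
  cfg_sim <- sim_config(n_subjects_per_group = c(HC = 0, ID = 1),
                        n_trials_per_condition = 10, n_channels = 6,
                        sfreq = 50, epoch_window = c(-200, 800),
                        effect_window = c(200, 700), snr = c(HC = 0, ID = 2),
                        seed = 12)
  rec <- simulate_subject_eeg(cfg_sim, "ID01")
  cfg <- decoding_config(n_folds = 2, n_repeats = 2, time_step_ms = 200,
                         seed = 8)
  grid <- build_session_matrix(rec, cfg)
  expect_equal(dim(grid), c(3, 3))
  n_within <- 0
  for (a in rownames(grid)) for (b in colnames(grid)) {
    r <- grid[[a, b]]
    expect_s3_class(r, "decoding_result")
    expect_equal(r$train_session, a)
    expect_equal(r$test_session, b)
    expect_true(all(r$accuracy >= 0 & r$accuracy <= 1))
    if (a == b) n_within <- n_within + 1
  }
  expect_equal(n_within, 3)

  rec$sessions$delayed <- NULL
  expect_error(build_session_matrix(rec, cfg),
               class = "emotraj_insufficient_data_error")
})
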