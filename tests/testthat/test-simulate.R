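small_cfg <- function(...) {
  sim_config(n_subjects_per_group = 2, n_trials_per_condition = 12,
             n_channels = 8, sfreq = 100, epoch_window = c(-200, 800),
             effect_window = c(200, 700), seed = 7, ...)
}

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(n_trials_per_condition = 0),
               class = "emotraj_configuration_error")
  expect_error(sim_config(n_channels = -1),
               class = "emotraj_configuration_error")
  expect_error(sim_config(snr = -0.5),
               class = "emotraj_configuration_error")
  expect_error(sim_config(stability_rho = 1.5),
               class = "emotraj_configuration_error")
  bad_tm <- default_sleep <- sim_config()$sleep_params$transition
  bad_tm[2, ] <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(sim_config(sleep_params = list(transition = bad_tm)),
               class = "emotraj_configuration_error")
  expect_error(sim_config(seed = NA),
               class = "emotraj_configuration_error")
})

test_that("identical config and seed give bit-identical output", {
  c1 <- small_cfg()
  c2 <- small_cfg()
  s1 <- simulate_subject_eeg(c1, "ID01")
  s2 <- simulate_subject_eeg(c2, "ID01")
  expect_identical(s1$sessions$post_sleep$data, s2$sessions$post_sleep$data)
  h1 <- simulate_hypnogram(c1, "HC01")
  h2 <- simulate_hypnogram(c2, "HC01")
  expect_identical(h1$stages, h2$stages)
  expect_identical(h1$arousals, h2$arousals)
  b1 <- simulate_behavior(c1, simulate_hypnograms(c1))
  b2 <- simulate_behavior(c2, simulate_hypnograms(c2))
  expect_identical(b1, b2)
  ## a different seed changes the draw
  c3 <- sim_config(n_subjects_per_group = 2, n_trials_per_condition = 12,
                   n_channels = 8, sfreq = 100, epoch_window = c(-200, 800),
                   effect_window = c(200, 700), seed = 8)
  s3 <- simulate_subject_eeg(c3, "ID01")
  expect_false(identical(s1$sessions$post_sleep$data,
                         s3$sessions$post_sleep$data))
})

test_that("labels are balanced and metadata well-formed in every session", {
  subs <- simulate_eeg_sessions(small_cfg())
  expect_length(subs, 4)
  for (rec in subs) {
    expect_setequal(names(rec$sessions), c("post_encoding", "post_sleep",
                                           "delayed"))
    for (sess in names(rec$sessions)) {
      ep <- rec$sessions[[sess]]
      tab <- table(ep$trial_meta$condition)
      expect_lte(abs(tab[["negative"]] - tab[["neutral"]]), 1)
      expect_equal(unique(ep$trial_meta$subject_id), rec$subject_id)
      expect_equal(unique(ep$trial_meta$group), rec$group)
      expect_equal(dim(ep$data)[1], nrow(ep$trial_meta))
    }
  }
})

test_that("high snr with stable patterns is separable within and between
          sessions (nearest-centroid oracle)", {
  cfg <- small_cfg(snr = 5, stability_rho = 1)
  rec <- simulate_subject_eeg(cfg, "ID01")
  t_ms <- epoch_times(rec$sessions$post_encoding)
  eff <- which(t_ms >= 300 & t_ms < 600)   # well inside the effect window
  acc_within <- mean(nc_within_accuracy(rec$sessions$post_encoding, eff))
  expect_gt(acc_within, 0.95)
  ## between sessions: train on session 1, test on session 3
  y1 <- ifelse(rec$sessions$post_encoding$trial_meta$condition == "negative",
               1, -1)
  y3 <- ifelse(rec$sessions$delayed$trial_meta$condition == "negative", 1, -1)
  acc_bet <- mean(vapply(eff, function(t)
    nc_decode(rec$sessions$post_encoding$data, y1,
              rec$sessions$delayed$data, y3, t, t), 0))
  expect_gt(acc_bet, 0.95)
})

test_that("unstable patterns (rho = 0) decode within but not between sessions", {
  cfg <- small_cfg(snr = 5, stability_rho = 0)
  within <- vapply(1:8, function(s) {
    cfg$seed <- cfg$seed + s
    rec <- simulate_subject_eeg(cfg, "HC01")
    t_ms <- epoch_times(rec$sessions$post_encoding)
    eff <- which(t_ms >= 300 & t_ms < 600)
    mean(nc_within_accuracy(rec$sessions$post_encoding, eff))
  }, 0)
  expect_gt(mean(within), 0.9)

  ## between-session transfer is governed by the projection of one session's
  ## class-difference pattern onto the other's; at rho = 0 that alignment is
  ## symmetric around zero, so expected transfer accuracy is chance
  align <- vapply(1:200, function(s) {
    cfg2 <- sim_config(n_subjects_per_group = c(HC = 1, ID = 0),
                       n_trials_per_condition = 4, n_channels = 8,
                       sfreq = 100, epoch_window = c(-200, 800),
                       effect_window = c(200, 700), snr = 5,
                       stability_rho = 0, seed = s)
    rec <- simulate_subject_eeg(cfg2, "HC01")
    diffpat <- function(ep, t) {
      neg <- ep$trial_meta$condition == "negative"
      apply(ep$data[neg, , t, drop = FALSE], 2, mean) -
        apply(ep$data[!neg, , t, drop = FALSE], 2, mean)
    }
    p1 <- diffpat(rec$sessions$post_encoding, 70)
    p3 <- diffpat(rec$sessions$delayed, 70)
    sum(p1 * p3) / sqrt(sum(p1^2) * sum(p3^2))
  }, 0)
  expect_lt(abs(mean(align)), 0.1)
  expect_lt(abs(mean(align > 0) - 0.5), 0.1)
})

test_that("between-session separability is non-decreasing in stability_rho", {
  mean_acc <- function(rho) {
    vals <- vapply(1:10, function(s) {
      cfg <- sim_config(n_subjects_per_group = c(HC = 1, ID = 0),
                        n_trials_per_condition = 12, n_channels = 8,
                        sfreq = 100, epoch_window = c(-200, 800),
                        effect_window = c(200, 700), snr = 1.5,
                        stability_rho = rho, seed = 100 + s)
      rec <- simulate_subject_eeg(cfg, "HC01")
      t_ms <- epoch_times(rec$sessions$post_encoding)
      eff <- which(t_ms >= 300 & t_ms < 600)
      y1 <- ifelse(rec$sessions$post_encoding$trial_meta$condition ==
                     "negative", 1, -1)
      y2 <- ifelse(rec$sessions$post_sleep$trial_meta$condition ==
                     "negative", 1, -1)
      mean(vapply(eff, function(t)
        nc_decode(rec$sessions$post_encoding$data, y1,
                  rec$sessions$post_sleep$data, y2, t, t), 0))
    }, 0)
    mean(vals)
  }
  accs <- vapply(c(0, 0.5, 1), mean_acc, 0)
  expect_true(all(diff(accs) >= -0.02))  # non-decreasing up to MC error
  expect_gt(accs[3], accs[1] + 0.1)
})

test_that("hypnogram generator respects the chain and the arousal rate", {
  ## REM unreachable when its column is zero and the chain starts awake
  tm <- default_sleep_params()$transition
  tm[, "R"] <- 0
  tm <- tm / rowSums(tm)
  cfg <- small_cfg(sleep_params = list(transition = tm, tib_min = 120))
  h <- simulate_hypnogram(cfg, "HC01")
  expect_equal(sum(h$stages == "R"), 0)
  expect_equal(compute_sleep_metrics(h)$stage_min[["REM"]], 0)

  ## zero arousal rate -> no events, arousal index 0
  cfg0 <- small_cfg(sleep_params = list(arousal_rate_per_h = 0,
                                        tib_min = 120))
  h0 <- simulate_hypnogram(cfg0, "HC01")
  expect_equal(nrow(h0$arousals), 0)
  m0 <- compute_sleep_metrics(h0)
  if (m0$TST_min > 0) expect_equal(m0$arousal_index_per_h, 0)

  ## stage proportions over sleep epochs sum to 1
  hh <- simulate_hypnogram(small_cfg(), "ID02")
  mm <- compute_sleep_metrics(hh)
  expect_equal(sum(mm$stage_min) / mm$TST_min, 1, tolerance = 1e-12)
})

test_that("long-run stage occupancy matches the stationary distribution", {
  tm <- default_sleep_params()$transition
  pi_oracle <- stationary_dist(tm)
  cfg <- sim_config(n_subjects_per_group = c(HC = 1, ID = 0),
                    sleep_params = list(tib_min = 480), seed = 31)
  counts <- setNames(numeric(5), c("W", "N1", "N2", "N3", "R"))
  for (night in 1:100) {
    h <- simulate_hypnogram(cfg, paste0("night", night))
    tab <- table(factor(h$stages, levels = names(counts)))
    counts <- counts + as.numeric(tab)
  }
  props <- counts / sum(counts)
  expect_lt(max(abs(props - pi_oracle)), 0.02)
})

test_that("behavior: flat logits and zero intercept SD give equal cell means", {
  gp <- default_group_params()
  gp$recall_logits[] <- 0.5
  gp$subject_sd <- 0
  gp$decay_effect <- 0
  gp$pass_prob <- 0
  cfg <- sim_config(n_subjects_per_group = 30, n_cues_per_condition = 24,
                    n_trials_per_condition = 12, n_channels = 2, sfreq = 50,
                    epoch_window = c(-200, 800), group_params = gp,
                    sleep_behavior_rho = 0,
                    sleep_params = list(tib_min = 60), seed = 77)
  beh <- simulate_behavior(cfg, simulate_hypnograms(cfg))
  cell_means <- aggregate(objective_recall == "correct" ~ group + emotion +
                            session, data = beh, FUN = mean)
  p_expect <- plogis(0.5)
  ## binomial MC error at ~30 subj x 24 cues per cell
  expect_lt(max(abs(cell_means[[4]] - p_expect)), 0.04)
})

test_that("behavior requires a hypnogram for every subject", {
  cfg <- small_cfg()
  hyps <- simulate_hypnograms(cfg)
  hyps[["ID02"]] <- NULL
  err <- tryCatch(simulate_behavior(cfg, hyps), error = identity)
  expect_s3_class(err, "emotraj_configuration_error")
  expect_match(conditionMessage(err), "ID02")
})

test_that("configured HC > ID negative decay shows the right sign consistently", {
  signs <- vapply(1:30, function(s) {
    cfg <- sim_config(n_subjects_per_group = 12, n_trials_per_condition = 12,
                      n_channels = 2, sfreq = 50, epoch_window = c(-200, 800),
                      sleep_params = list(tib_min = 60), seed = 500 + s)
    beh <- simulate_behavior(cfg, simulate_hypnograms(cfg))
    d <- decay_scores(beh, "objective", "negative")
    roster <- unique(beh[, c("subject_id", "group")])
    hc <- mean(d[roster$subject_id[roster$group == "HC"]], na.rm = TRUE)
    id <- mean(d[roster$subject_id[roster$group == "ID"]], na.rm = TRUE)
    hc > id
  }, TRUE)
  expect_gte(mean(signs), 0.95)
})
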