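#' Simulation configuration for the synthetic multi-session study
#'
#' Describes the statistical world the downstream analyses assume: two
#' groups (healthy controls `HC`, insomnia disorder `ID`), three recall
#' sessions (`post_encoding`, `post_sleep`, `delayed`), epoched EEG with an
#' emotion-discriminative spatial pattern whose cross-session stability is
#' one knob (`stability_rho`), first-order-Markov hypnograms, and per-cue
#' behavioral outcomes whose negative-memory decay can be latently coupled
#' to the realized SWS x REM composite.
#'
#' `snr` and `stability_rho` may be scalars or named per-group vectors
#' (`c(HC = ..., ID = ...)`). The EEG amplitude knobs are arbitrary in
#' physical units (no empirical effect size exists in microvolts); defaults
#' reproduce the qualitative group dissociation: a stable, decodable emotion
#' pattern in ID and an unstable, near-absent one in HC.
#'
#' @param n_subjects_per_group subjects per group; scalar or
#'   `c(HC = , ID = )` (defaults 35 HC, 34 ID).
#' @param n_trials_per_condition EEG trials per emotion condition per
#'   session (default 72 = 24 cues x 3 recall runs).
#' @param n_cues_per_condition distinct memory cues per emotion (default 24).
#' @param n_channels EEG channels (default 64).
#' @param sfreq sampling rate, Hz (default 250).
#' @param epoch_window `(start_ms, end_ms)` of each epoch (default -500..3000).
#' @param snr amplitude of the class-difference pattern relative to noise
#'   RMS; scalar or per-group (default `c(HC = 0.02, ID = 0.5)`).
#' @param stability_rho correlation of the discriminative spatial pattern
#'   across sessions, in `[0, 1]`; scalar or per-group
#'   (default `c(HC = 0, ID = 1)`).
#' @param effect_window `(start_ms, end_ms)` where the class difference is
#'   nonzero (default 500..3000).
#' @param noise_uv noise RMS per channel in microvolts (default 10).
#' @param group_params list of behavioral parameters; see Details. Partial
#'   lists are merged over the defaults.
#' @param sleep_params list: `transition` (5x5 row-stochastic matrix over
#'   W/N1/N2/N3/R), `tib_min` (time in bed, minutes), `arousal_rate_per_h`
#'   (Poisson rate per hour of sleep), `init_stage`.
#' @param sleep_behavior_rho target latent correlation between SWS x REM and
#'   negative-memory decay, per group (default `c(HC = -0.45, ID = 0)`).
#' @param seed integer seed; all generator output is a deterministic
#'   function of the config including this seed.
#'
#' @details `group_params` fields: `recall_logits` — 2 x 2 x 3 array
#' (group x emotion x session) of cell logits for objective recall;
#' `subject_sd` — SD of the subject random intercept on the logit scale;
#' `decay_effect` — how strongly the decay latent shifts the delayed-session
#' negative logits; `pass_prob` — probability that an objective response is
#' "pass"; `subjective_shift` — logit offset of subjective over objective
#' recall; `rating_means` — 2 x 2 x 3 x 2 array (group x emotion x session x
#' {valence, arousal}) of latent rating means on the 1-9 scale;
#' `rating_sd` — latent rating noise SD.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = c(HC = 35, ID = 34),
                       n_trials_per_condition = 72,
                       n_cues_per_condition = 24,
                       n_channels = 64,
                       sfreq = 250,
                       epoch_window = c(-500, 3000),
                       snr = c(HC = 0.02, ID = 0.5),
                       stability_rho = c(HC = 0, ID = 1),
                       effect_window = c(500, 3000),
                       noise_uv = 10,
                       group_params = list(),
                       sleep_params = list(),
                       sleep_behavior_rho = c(HC = -0.45, ID = 0),
                       seed = 1L) {
  per_group <- function(x, name) {
    if (length(x) == 1L) x <- c(HC = unname(x), ID = unname(x))
    if (!all(GROUPS %in% names(x)))
      stop_emotraj(sprintf("`%s` must be scalar or named over HC/ID", name),
                   "emotraj_configuration_error")
    x[GROUPS]
  }
  nspg <- per_group(n_subjects_per_group, "n_subjects_per_group")
  if (any(nspg < 0) || sum(nspg) < 1 ||
      n_trials_per_condition < 1 || n_channels < 1)
    stop_emotraj("subject, trial, and channel counts must be positive",
                 "emotraj_configuration_error")
  snr <- per_group(snr, "snr")
  rho <- per_group(stability_rho, "stability_rho")
  if (any(snr < 0))
    stop_emotraj("snr must be >= 0", "emotraj_configuration_error")
  if (any(rho < 0 | rho > 1))
    stop_emotraj("stability_rho must lie in [0, 1]",
                 "emotraj_configuration_error")
  gp <- modifyList(default_group_params(), group_params)
  if (length(gp$recall_logits) == 1L)   # scalar convenience: flat cells
    gp$recall_logits <- array(gp$recall_logits, c(2, 2, 3),
                              dimnames = list(GROUPS, CONDITIONS, SESSIONS))
  if (any(!is.finite(gp$recall_logits)))
    stop_emotraj("recall_logits must be finite", "emotraj_configuration_error")
  if (gp$pass_prob <= 0 && gp$pass_prob != 0 || gp$pass_prob >= 1)
    stop_emotraj("pass_prob must lie in [0, 1)", "emotraj_configuration_error")
  sp <- modifyList(default_sleep_params(), sleep_params)
  tm <- as.matrix(sp$transition)
  if (!all(dim(tm) == c(5, 5)) ||
      any(abs(rowSums(tm) - 1) > 1e-8) || any(tm < 0))
    stop_emotraj("sleep transition matrix must be 5x5 row-stochastic",
                 "emotraj_configuration_error")
  dimnames(tm) <- list(STAGES, STAGES)
  sp$transition <- tm
  if (sp$tib_min <= 0)
    stop_emotraj("tib_min must be > 0", "emotraj_configuration_error")
  if (length(seed) != 1L || is.na(seed))
    stop_emotraj("an explicit integer seed is required",
                 "emotraj_configuration_error")
  structure(list(
    n_subjects_per_group = nspg,
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_cues_per_condition = as.integer(n_cues_per_condition),
    n_channels = as.integer(n_channels), sfreq = sfreq,
    epoch_window = epoch_window, snr = snr, stability_rho = rho,
    effect_window = effect_window, noise_uv = noise_uv,
    group_params = gp, sleep_params = sp,
    sleep_behavior_rho = per_group(sleep_behavior_rho, "sleep_behavior_rho"),
    seed = as.integer(seed)), class = "sim_config")
}

default_group_params <- function() {
  rl <- array(0, c(2, 2, 3), dimnames = list(GROUPS, CONDITIONS, SESSIONS))
  ## near-ceiling recall after encoding, mild overnight loss, and a 7-day
  ## drop that is much smaller for negative cues in ID than in HC
  rl["HC", "negative", ] <- c(2.2, 1.8, 0.0)
  rl["HC", "neutral", ]  <- c(2.2, 1.8, 0.3)
  rl["ID", "negative", ] <- c(2.2, 1.8, 1.2)
  rl["ID", "neutral", ]  <- c(2.2, 1.8, 0.4)
  rm_ <- array(0, c(2, 2, 3, 2),
               dimnames = list(GROUPS, CONDITIONS, SESSIONS,
                               c("valence", "arousal")))
  ## negative memories become less negative / less arousing over the week,
  ## more so in HC (affect dissipation); neutral stays flat
  rm_["HC", "negative", , "valence"] <- c(2.5, 2.8, 3.6)
  rm_["ID", "negative", , "valence"] <- c(2.5, 2.8, 3.1)
  rm_["HC", "neutral", , "valence"]  <- c(5.0, 5.0, 5.1)
  rm_["ID", "neutral", , "valence"]  <- c(5.0, 5.0, 5.1)
  rm_["HC", "negative", , "arousal"] <- c(6.5, 6.2, 5.0)
  rm_["ID", "negative", , "arousal"] <- c(6.5, 6.2, 5.8)
  rm_["HC", "neutral", , "arousal"]  <- c(3.0, 3.0, 3.0)
  rm_["ID", "neutral", , "arousal"]  <- c(3.0, 3.0, 3.0)
  list(recall_logits = rl, subject_sd = 0.5, decay_effect = 1.2,
       pass_prob = 0.10, subjective_shift = 0.3,
       rating_means = rm_, rating_sd = 1.0)
}

default_sleep_params <- function() {
  tm <- rbind(
    W  = c(0.88, 0.09, 0.03, 0.00, 0.00),
    N1 = c(0.09, 0.50, 0.39, 0.00, 0.02),
    N2 = c(0.02, 0.03, 0.85, 0.07, 0.03),
    N3 = c(0.01, 0.00, 0.10, 0.88, 0.01),
    R  = c(0.02, 0.03, 0.05, 0.00, 0.90))
  colnames(tm) <- STAGES
  list(transition = tm, tib_min = 480, arousal_rate_per_h = 10,
       init_stage = "W")
}

#' Subject roster implied by a simulation config
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `subject_id`, `group`.
#' @export
sim_subjects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  do.call(rbind, lapply(GROUPS, function(g) {
    n <- config$n_subjects_per_group[[g]]
    if (n < 1) return(NULL)
    data.frame(subject_id = sprintf("%s%02d", g, seq_len(n)),
               group = g, stringsAsFactors = FALSE)
  }))
}

## 1/f-amplitude ("pink") noise via FFT shaping, unit variance
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # fold to two-sided frequency index
  X <- X / sqrt(f)
  X[1] <- 0
  v <- Re(fft(X, inverse = TRUE)) / n
  v / sd(v)
}

## spatially correlated noise for one trial: channels x samples
sim_noise <- function(n_channels, n_samples, mix) {
  w <- matrix(rnorm(n_channels * n_samples), n_channels)
  p <- t(vapply(seq_len(n_channels), function(i) pink_noise(n_samples),
                numeric(n_samples)))
  out <- mix %*% (sqrt(0.5) * p + sqrt(0.5) * w)  # equal pink/white power
  out / sqrt(mean(out^2))
}

#' Simulate epoched EEG for all subjects and sessions
#'
#' Each trial is `spatial pattern x class sign x amplitude envelope` over the
#' effect window plus spatially correlated 1/f-plus-white noise. The
#' session-specific discriminative pattern correlates with the session-1
#' pattern at `stability_rho`; labels are balanced by construction.
#'
#' @param config a [sim_config()].
#' @return Named list (by subject id) of subject records; each record is a
#'   list with `subject_id`, `group`, and `sessions` — a named list of three
#'   [epoch_set()] objects.
#' @export
simulate_eeg_sessions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  roster <- sim_subjects(config)
  out <- vector("list", nrow(roster))
  names(out) <- roster$subject_id
  for (i in seq_len(nrow(roster))) {
    out[[i]] <- simulate_subject_eeg(config, roster$subject_id[i],
                                     roster$group[i])
  }
  out
}

#' Simulate epoched EEG for a single subject
#'
#' @param config a [sim_config()].
#' @param subject_id subject identifier (e.g. `"HC01"`).
#' @param group `"HC"` or `"ID"`; looked up from the roster when `NULL`.
#' @return Subject record (see [simulate_eeg_sessions()]).
#' @export
simulate_subject_eeg <- function(config, subject_id, group = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(group)) {
    roster <- sim_subjects(config)
    group <- roster$group[match(subject_id, roster$subject_id)]
    if (is.na(group))
      stop_emotraj(paste0("unknown subject: ", subject_id),
                   "emotraj_configuration_error")
  }
  nch <- config$n_channels
  n_per <- config$n_trials_per_condition
  win <- config$epoch_window
  n_samp <- as.integer(round((win[2] - win[1]) / 1000 * config$sfreq))
  t_ms <- win[1] + (seq_len(n_samp) - 1L) * 1000 / config$sfreq
  rho <- config$stability_rho[[group]]
  snr <- config$snr[[group]]

  with_seed(child_seed(config$seed, "eeg", subject_id), {
    shared <- rnorm(nch)
    mix_raw <- matrix(rnorm(nch * nch, sd = 1 / sqrt(nch)), nch)
    mix <- diag(nch) + 0.5 * mix_raw    # mild random spatial covariance
    env <- rep(0, n_samp)
    in_eff <- t_ms >= config$effect_window[1] & t_ms < config$effect_window[2]
    if (any(in_eff)) {
      k <- sum(in_eff)
      env[in_eff] <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))  # Hann
    }
    sessions <- vector("list", 3L)
    names(sessions) <- SESSIONS
    for (s in seq_along(SESSIONS)) {
      uniq <- rnorm(nch)
      pat <- sqrt(rho) * shared + sqrt(1 - rho) * uniq
      pat <- pat / sqrt(sum(pat^2))
      n_tr <- 2L * n_per
      lab <- sample(rep(CONDITIONS, n_per))
      dat <- array(0, c(n_tr, nch, n_samp))
      amp <- snr * config$noise_uv
      for (tr in seq_len(n_tr)) {
        sgn <- if (lab[tr] == "negative") 1 else -1
        noise <- config$noise_uv * sim_noise(nch, n_samp, mix)
        dat[tr, , ] <- noise + sgn * amp * outer(pat, env)
      }
      cue <- integer(n_tr)
      for (cc in CONDITIONS) {
        j <- which(lab == cc)
        cue[j] <- ((seq_along(j) - 1L) %% config$n_cues_per_condition) + 1L
      }
      meta <- data.frame(subject_id = subject_id, group = group,
                         session = SESSIONS[s], condition = lab,
                         cue_id = paste0(substr(lab, 1, 3), cue),
                         trial_index = seq_len(n_tr), rejected = FALSE,
                         stringsAsFactors = FALSE)
      sessions[[s]] <- epoch_set(dat, config$sfreq, win[1], meta)
    }
    list(subject_id = subject_id, group = group, sessions = sessions)
  })
}

#' Simulate one night's hypnogram
#'
#' First-order Markov stage sequence at 30-s resolution from lights-off to
#' lights-on; arousal events arrive as a Poisson process during sleep epochs
#' at the configured hourly rate.
#'
#' @param config a [sim_config()].
#' @param subject_id optional subject id; used to derive a subject-specific
#'   seed and stored on the hypnogram.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(config, subject_id = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$sleep_params
  n_ep <- as.integer(round(sp$tib_min * 2))
  seed <- if (is.na(subject_id)) child_seed(config$seed, "hyp")
          else child_seed(config$seed, "hyp", subject_id)
  with_seed(seed, {
    st <- character(n_ep)
    cur <- sp$init_stage
    for (i in seq_len(n_ep)) {
      cur <- sample(STAGES, 1L, prob = sp$transition[cur, ])
      st[i] <- cur
    }
    sleep_idx <- which(st != "W")
    arousals <- NULL
    if (length(sleep_idx) && sp$arousal_rate_per_h > 0) {
      tst_h <- length(sleep_idx) * 30 / 3600
      k <- rpois(1, sp$arousal_rate_per_h * tst_h)
      if (k > 0) {
        ep_pick <- sample(sleep_idx, k, replace = TRUE)
        onset <- (ep_pick - 1) * 30 + runif(k, 0, 30)
        arousals <- data.frame(onset_s = sort(onset),
                               duration_s = runif(k, 3, 15))
      }
    }
    hypnogram(st, lights_off_epoch = 0, lights_on_epoch = n_ep,
              arousals = arousals, subject_id = subject_id)
  })
}

#' Simulate hypnograms for the whole roster
#'
#' @param config a [sim_config()].
#' @return Named list of [hypnogram()] objects, keyed by subject id.
#' @export
simulate_hypnograms <- function(config) {
  roster <- sim_subjects(config)
  out <- lapply(roster$subject_id, function(id)
    simulate_hypnogram(config, id))
  names(out) <- roster$subject_id
  out
}

#' Simulate the behavioral table
#'
#' Per-cue recall outcomes from cell logits plus a subject random intercept;
#' "pass" is generated only for objective recall; 1-9 valence/arousal ratings
#' come from a latent Gaussian with fixed half-integer thresholds shared
#' across groups. In groups with nonzero `sleep_behavior_rho`, the subject's
#' negative-memory decay latent is correlated with the normal scores of
#' their realized SWS x REM composite at the configured rho (the latent
#' shifts all delayed-session negative memory logits).
#'
#' Verbal-recall measures (identification, gist, ratings) exist only for
#' `post_sleep` and `delayed`; they are `NA` at `post_encoding`, except that
#' baseline (pre-encoding) ratings are attached to the `post_encoding` rows.
#'
#' @param config a [sim_config()].
#' @param hypnograms named list of [hypnogram()] objects covering every
#'   subject in the roster (e.g. from [simulate_hypnograms()]).
#' @return data.frame with one row per subject x session x cue and columns
#'   `subject_id`, `group`, `session`, `cue_id`, `emotion`,
#'   `subjective_recall`, `objective_recall`, `identification`, `gist`,
#'   `valence`, `arousal`.
#' @export
simulate_behavior <- function(config, hypnograms) {
  stopifnot(inherits(config, "sim_config"))
  roster <- sim_subjects(config)
  missing <- setdiff(roster$subject_id, names(hypnograms))
  if (length(missing))
    stop_emotraj(paste0("missing hypnogram for subject(s): ",
                        paste(missing, collapse = ", ")),
                 "emotraj_configuration_error")
  gp <- config$group_params
  n_cues <- config$n_cues_per_condition

  swsrem <- vapply(roster$subject_id, function(id) {
    m <- compute_sleep_metrics(hypnograms[[id]])
    v <- m$sws_rem_product
    if (is.na(v)) 0 else v
  }, 0)

  rows <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    id <- roster$subject_id[i]; g <- roster$group[i]
    in_g <- roster$group == roster$group[i]
    r <- rank(swsrem[in_g])[match(id, roster$subject_id[in_g])]
    z_s <- qnorm((r - 0.5) / sum(in_g))
    rho <- config$sleep_behavior_rho[[g]]
    rows[[i]] <- with_seed(child_seed(config$seed, "beh", id), {
      u <- rnorm(1, 0, gp$subject_sd)
      d_lat <- rho * z_s + sqrt(max(0, 1 - rho^2)) * rnorm(1)
      per_sess <- lapply(SESSIONS, function(sess) {
        per_emo <- lapply(CONDITIONS, function(emo) {
          logit <- gp$recall_logits[g, emo, sess] + u
          if (sess == "delayed" && emo == "negative")
            logit <- logit - gp$decay_effect * d_lat
          p <- plogis(logit)
          correct <- rbinom(n_cues, 1, p)
          is_pass <- rbinom(n_cues, 1, gp$pass_prob) == 1
          objective <- ifelse(is_pass, "pass",
                              ifelse(correct == 1, "correct", "incorrect"))
          subj <- rbinom(n_cues, 1,
                         plogis(logit + gp$subjective_shift))
          verbal <- sess != "post_encoding"
          ident <- if (verbal) rbinom(n_cues, 1, p) else rep(NA_integer_, n_cues)
          gist <- if (verbal) plogis(rnorm(n_cues, logit, 1))
                  else rep(NA_real_, n_cues)
          mu_v <- gp$rating_means[g, emo, sess, "valence"]
          mu_a <- gp$rating_means[g, emo, sess, "arousal"]
          lat_v <- rnorm(n_cues, mu_v + 0.3 * u, gp$rating_sd)
          lat_a <- rnorm(n_cues, mu_a + 0.3 * u, gp$rating_sd)
          data.frame(subject_id = id, group = g, session = sess,
                     cue_id = paste0(substr(emo, 1, 3), seq_len(n_cues)),
                     emotion = emo,
                     subjective_recall = subj, objective_recall = objective,
                     identification = ident, gist = gist,
                     valence = pmin(pmax(round(lat_v), 1), 9),
                     arousal = pmin(pmax(round(lat_a), 1), 9),
                     stringsAsFactors = FALSE)
        })
        do.call(rbind, per_emo)
      })
      do.call(rbind, per_sess)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
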