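## Config-driven orchestration: simulate -> preprocess -> decode -> cluster
## -> sleepmetrics -> correlate. One YAML config with one block per stage;
## an explicit top-level seed is mandatory and every stage derives its own
## child seeds from it, so a rerun with the same config reproduces all
## outputs bit-identically.

PIPELINE_STAGES <- c("simulate", "preprocess", "decode", "cluster",
                     "sleepmetrics", "correlate")

#' Run the full analysis pipeline from a YAML config
#'
#' Executes the canonical stage order, writing all artifacts under the
#' config's `out_dir` and a run manifest (`manifest.json`) listing the
#' config hash, seed, package version, per-stage outputs with md5 checksums,
#' and per-stage status. Any stage failure aborts with an error naming the
#' stage.
#'
#' @param config_path path to a YAML file. Top level: `seed` (mandatory),
#'   `out_dir`, plus one optional block per stage (`simulate`, `preprocess`,
#'   `decode`, `cluster`, `sleepmetrics`, `correlate`). Unknown top-level
#'   keys are rejected.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config_path, quiet = FALSE) {
  if (!file.exists(config_path))
    stop_emotraj(paste0("no such config: ", config_path),
                 "emotraj_configuration_error")
  cfg <- yaml::read_yaml(config_path)
  known <- c("seed", "out_dir", PIPELINE_STAGES)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_emotraj(paste0("unknown config key(s)/stage name(s): ",
                        paste(unknown, collapse = ", ")),
                 "emotraj_configuration_error")
  if (is.null(cfg$seed))
    stop_emotraj("config must set an explicit integer `seed`",
                 "emotraj_configuration_error")
  seed <- as.integer(cfg$seed)
  out_dir <- if (is.null(cfg$out_dir)) "emotraj_run" else cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[emotraj] ", ...)

  manifest <- list(
    config_hash = digest::digest(cfg[setdiff(names(cfg), "out_dir")]),
    seed = seed,
    package_version = as.character(utils::packageVersion("emotraj")),
    stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    say("stage: ", name)
    outputs <- tryCatch(fun(), error = function(e)
      stop_emotraj(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   "emotraj_stage_error"))
    manifest$stages[[name]] <<- list(
      status = "ok", outputs = outputs,
      md5 = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  }

  run_stage("simulate", function()
    stage_simulate(cfg, seed, out_dir, state))
  run_stage("preprocess", function()
    stage_preprocess(cfg, out_dir, state))
  run_stage("decode", function()
    stage_decode(cfg, seed, out_dir, state))
  run_stage("cluster", function()
    stage_cluster(cfg, seed, out_dir, state))
  run_stage("sleepmetrics", function()
    stage_sleepmetrics(out_dir, state))
  run_stage("correlate", function()
    stage_correlate(cfg, out_dir, state))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(cfg, seed, out_dir, state) {
  args <- cfg$simulate
  if (!is.null(args$n_subjects_per_group))
    args$n_subjects_per_group <- unlist(args$n_subjects_per_group)
  for (nm in c("epoch_window", "effect_window", "snr", "stability_rho",
               "sleep_behavior_rho"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  sc <- do.call(sim_config, c(args, list(seed = seed)))
  state$sim_config <- sc
  state$subjects <- simulate_eeg_sessions(sc)
  state$hypnograms <- simulate_hypnograms(sc)
  state$behavior <- simulate_behavior(sc, state$hypnograms)

  ep_dir <- file.path(out_dir, "epochs")
  hyp_dir <- file.path(out_dir, "hypnograms")
  dir.create(ep_dir, showWarnings = FALSE)
  dir.create(hyp_dir, showWarnings = FALSE)
  outputs <- character(0)
  for (rec in state$subjects) {
    for (sess in names(rec$sessions)) {
      prefix <- file.path(ep_dir, paste0(rec$subject_id, "_", sess))
      write_epochs(rec$sessions[[sess]], prefix)
      outputs <- c(outputs, paste0(prefix, c(".dat", ".json", "_meta.csv")))
    }
  }
  for (id in names(state$hypnograms)) {
    p <- file.path(hyp_dir, paste0(id, ".hyp"))
    write_hypnogram(state$hypnograms[[id]], p)
    outputs <- c(outputs, p)
  }
  beh_path <- file.path(out_dir, "behavior.csv")
  write.csv(state$behavior, beh_path, row.names = FALSE)
  c(outputs, beh_path)
}

stage_preprocess <- function(cfg, out_dir, state) {
  args <- cfg$preprocess
  baseline <- if (is.null(args$baseline)) NULL else unlist(args$baseline)
  thresh <- if (is.null(args$reject_uv)) 100 else args$reject_uv
  max_frac <- if (is.null(args$max_reject_fraction)) 0.20
              else args$max_reject_fraction
  reports <- list()
  for (id in names(state$subjects)) {
    rec <- state$subjects[[id]]
    n_tot <- 0L; n_rej <- 0L
    for (sess in names(rec$sessions)) {
      ep <- rec$sessions[[sess]]
      ep <- rereference_common_average(ep)
      bl <- baseline
      if (is.null(bl)) bl <- c(ep$t0_ms, 0)
      if (bl[1] < ep$t0_ms) bl[1] <- ep$t0_ms
      ep <- baseline_correct(ep, bl)
      rr <- reject_artifacts(ep, thresh_uv = thresh)
      rec$sessions[[sess]] <- rr$epochs
      n_tot <- n_tot + rr$report$n_total
      n_rej <- n_rej + rr$report$n_rejected
    }
    state$subjects[[id]] <- rec
    reports[[id]] <- rejection_report(n_tot, n_rej, subject_id = id)
  }
  state$excluded <- exclude_subjects(reports, max_frac)
  rej_path <- file.path(out_dir, "rejection_report.csv")
  write.csv(data.frame(
    subject_id = names(reports),
    n_total = vapply(reports, `[[`, 0, "n_total"),
    n_rejected = vapply(reports, `[[`, 0, "n_rejected"),
    fraction_rejected = vapply(reports, `[[`, 0, "fraction_rejected"),
    excluded = names(reports) %in% state$excluded),
    rej_path, row.names = FALSE)
  rej_path
}

stage_decode <- function(cfg, seed, out_dir, state) {
  args <- cfg$decode
  measure <- args$measure
  if (is.null(measure)) measure <- "objective_correct"
  if (identical(measure, "none")) measure <- NULL
  dcfg <- decoding_config(
    n_folds = if (is.null(args$folds)) 4 else args$folds,
    n_repeats = if (is.null(args$repeats)) 50 else args$repeats,
    time_step_ms = if (is.null(args$step_ms)) 20 else args$step_ms,
    window_ms = if (is.null(args$window_ms)) NULL else unlist(args$window_ms),
    measure = measure, seed = child_seed(seed, "decode"))
  beh <- state$behavior
  keep_ids <- setdiff(names(state$subjects), state$excluded)
  grids <- list()
  for (id in keep_ids) {
    rec <- state$subjects[[id]]
    if (!is.null(measure)) {
      for (sess in names(rec$sessions)) {
        ep <- rec$sessions[[sess]]
        b <- beh[beh$subject_id == id & beh$session == sess, ]
        ok_cues <- b$cue_id[b$objective_recall == "correct"]
        ep$trial_meta[[measure]] <- ep$trial_meta$cue_id %in% ok_cues
        rec$sessions[[sess]] <- ep
      }
    }
    grids[[id]] <- build_session_matrix(rec, dcfg)
  }
  state$decoding <- grids
  dec_path <- file.path(out_dir, "decoding_mean_accuracy.csv")
  rows <- list()
  for (id in names(grids))
    for (a in SESSIONS) for (b in SESSIONS) {
      r <- grids[[id]][[a, b]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = state$subjects[[id]]$group,
        train_session = a, test_session = b,
        mean_accuracy = mean(r$accuracy))
    }
  write.csv(do.call(rbind, rows), dec_path, row.names = FALSE)
  dec_path
}

stage_cluster <- function(cfg, seed, out_dir, state) {
  args <- cfg$cluster
  ccfg <- cluster_config(
    n_permutations = if (is.null(args$permutations)) 10000
                     else args$permutations,
    alpha = if (is.null(args$alpha)) 0.05 else args$alpha,
    seed = child_seed(seed, "cluster"))
  groups_of <- vapply(state$decoding, function(g) NA_character_, "")
  for (id in names(state$decoding))
    groups_of[id] <- state$subjects[[id]]$group
  tables <- list()
  for (a in SESSIONS) for (b in SESSIONS) {
    maps <- list(HC = list(), ID = list())
    for (id in names(state$decoding)) {
      g <- groups_of[id]
      maps[[g]][[length(maps[[g]]) + 1L]] <-
        state$decoding[[id]][[a, b]]$accuracy
    }
    for (g in GROUPS) {
      if (length(maps[[g]]) < 2) next
      res <- onesample_cluster_test(maps[[g]], 0.5, ccfg)
      tb <- cluster_table(res)
      if (nrow(tb)) {
        tb$test <- "onesample"; tb$group <- g
        tb$train_session <- a; tb$test_session <- b
        tables[[length(tables) + 1L]] <- tb
      }
    }
    if (length(maps$ID) >= 2 && length(maps$HC) >= 2) {
      res2 <- twosample_cluster_test(maps$ID, maps$HC, ccfg)
      tb <- cluster_table(res2)
      if (nrow(tb)) {
        tb$test <- "twosample_ID_minus_HC"; tb$group <- "ID-HC"
        tb$train_session <- a; tb$test_session <- b
        tables[[length(tables) + 1L]] <- tb
      }
    }
  }
  cl_path <- file.path(out_dir, "clusters.csv")
  out <- if (length(tables)) do.call(rbind, tables) else
    data.frame(cluster_id = integer(0))
  write.csv(out, cl_path, row.names = FALSE)
  cl_path
}

stage_sleepmetrics <- function(out_dir, state) {
  metrics <- lapply(state$hypnograms, compute_sleep_metrics)
  state$sleep_table <- sleep_metrics_table(metrics)
  p <- file.path(out_dir, "sleep_metrics.csv")
  write.csv(state$sleep_table, p, row.names = FALSE)
  p
}

stage_correlate <- function(cfg, out_dir, state) {
  args <- cfg$correlate
  measure <- if (is.null(args$measure)) "objective" else args$measure
  emotion <- if (is.null(args$emotion)) "negative" else args$emotion
  exclude_pass <- isTRUE(args$exclude_pass)
  beh <- state$behavior
  beh <- beh[!(beh$subject_id %in% state$excluded), ]
  sleep <- state$sleep_table
  roster <- unique(beh[, c("subject_id", "group")])
  decay <- decay_scores(beh, measure, emotion, exclude_pass)
  if (!is.null(args$trim_sd)) {
    flagged <- trim_sd_subjects(decay, args$trim_sd)
    decay <- decay[!(names(decay) %in% flagged)]
  }
  reports <- list(); comparisons <- list()
  rho_n <- list()
  for (g in GROUPS) {
    ids <- roster$subject_id[roster$group == g]
    dg <- decay[names(decay) %in% ids]
    rep_g <- spearman_fdr(sleep[sleep$subject_id %in% ids, ], dg,
                          group = g,
                          outcome_name = paste0(emotion, "_", measure,
                                                "_decay"))
    reports[[g]] <- rep_g
    row <- rep_g[rep_g$sleep_metric == "sws_rem", ]
    rho_n[[g]] <- list(rho = row$rho, n = row$n)
  }
  if (all(vapply(rho_n, function(x) is.finite(x$rho) && x$n >= 4, TRUE))) {
    fz <- fisher_z_compare(rho_n$HC$rho, rho_n$HC$n,
                           rho_n$ID$rho, rho_n$ID$n)
    comparisons[[1]] <- data.frame(
      metric = "sws_rem", outcome = paste0(emotion, "_", measure, "_decay"),
      z = fz$z, p = fz$p_twotailed, cohens_q = fz$cohens_q)
  }
  cor_path <- file.path(out_dir, "correlations.csv")
  cmp_path <- file.path(out_dir, "correlation_comparisons.csv")
  write.csv(do.call(rbind, reports), cor_path, row.names = FALSE)
  write.csv(if (length(comparisons)) comparisons[[1]] else
    data.frame(metric = character(0)), cmp_path, row.names = FALSE)
  c(cor_path, cmp_path)
}
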