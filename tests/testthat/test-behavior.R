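## a tiny deterministic behavioral table: 2 subjects x 2 sessions x 10 cues
beh_fixture <- function() {
  mk <- function(id, sess, correct_n, pass_n = 0, valence = 5, arousal = 5) {
    obj <- c(rep("correct", correct_n), rep("pass", pass_n),
             rep("incorrect", 10 - correct_n - pass_n))
    data.frame(subject_id = id, group = "HC", session = sess,
               cue_id = paste0("neg", 1:10), emotion = "negative",
               subjective_recall = as.integer(obj == "correct"),
               objective_recall = obj, identification = NA_integer_,
               gist = NA_real_, valence = valence, arousal = arousal,
               stringsAsFactors = FALSE)
  }
  rbind(mk("S1", "post_sleep", 8, valence = 3, arousal = 6),
        mk("S1", "delayed", 6, valence = 4, arousal = 4.5),
        mk("S2", "post_sleep", 5, valence = 5, arousal = 5),
        mk("S2", "delayed", 5, valence = 5, arousal = 5))
}

test_that("decay scores: hand computation, zero case, pass handling", {
  tbl <- beh_fixture()
  d <- decay_scores(tbl, "objective", "negative")
  expect_equal(d[["S1"]], 0.8 - 0.6)
  expect_equal(d[["S2"]], 0)

  ## all trials 'pass' with exclude_pass -> empty denominator -> NA
  tbl2 <- tbl
  tbl2$objective_recall[tbl2$subject_id == "S1"] <- "pass"
  d2 <- decay_scores(tbl2, "objective", "negative", exclude_pass = TRUE)
  expect_true(is.na(d2[["S1"]]))
  expect_equal(d2[["S2"]], 0)

  ## excluding pass changes the denominator
  tbl3 <- beh_fixture()
  tbl3$objective_recall[tbl3$subject_id == "S1" &
                          tbl3$session == "delayed"] <-
    c(rep("correct", 6), rep("pass", 2), rep("incorrect", 2))
  d3 <- decay_scores(tbl3, "objective", "negative", exclude_pass = TRUE)
  expect_equal(d3[["S1"]], 0.8 - 6 / 8)
})

test_that("decay scores drop subjects missing a session, with warning", {
  tbl <- beh_fixture()
  tbl <- tbl[!(tbl$subject_id == "S2" & tbl$session == "delayed"), ]
  expect_warning(d <- decay_scores(tbl, "objective", "negative"), "S2")
  expect_equal(names(d), "S1")
})

test_that("affect change: hand computation and degenerate n = 1", {
  tbl <- beh_fixture()
  ch <- affect_change_scores(tbl, "arousal", "negative")
  expect_equal(ch[["S1"]], 4.5 - 6.0)
  expect_equal(ch[["S2"]], 0)
  chv <- affect_change_scores(tbl, "valence", "negative")
  expect_equal(chv[["S1"]], 1)

  one <- tbl[tbl$cue_id == "neg1", ]
  ch1 <- affect_change_scores(one, "arousal", "negative")
  expect_equal(ch1[["S1"]], -1.5)
})

test_that("Spearman equals Pearson on ranks and is monotone-invariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30) + 0.5 * x
    expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)))
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, y^3 + 10 * y), spearman_rho(x, y))
  }
  expect_equal(spearman_rho(1:10, 2 * (1:10) + 1), 1)
})

test_that("BH adjustment matches the hand-worked fixture and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.005, 0.02, 0.03)), c(0.015, 0.03, 0.03))
  p_eq <- rep(0.04, 5)
  expect_equal(bh_adjust(p_eq), p_eq)

  set.seed(42)
  ok_oracle <- ok_ref <- ok_bounds <- ok_monotone <- TRUE
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)
    adj <- bh_adjust(p)
    ok_oracle <- ok_oracle && isTRUE(all.equal(adj, bh_bruteforce(p)))
    ok_ref <- ok_ref && isTRUE(all.equal(adj, p.adjust(p, "BH")))
    ok_bounds <- ok_bounds && all(adj <= 1)
    ok_monotone <- ok_monotone && all(diff(adj[order(p)]) >= -1e-15)
  }
  expect_true(ok_oracle)
  expect_true(ok_ref)
  expect_true(ok_bounds)
  expect_true(ok_monotone)
})

test_that("spearman_fdr builds the 9-metric family with FDR within it", {
  set.seed(9)
  n <- 30
  sleep <- data.frame(subject_id = paste0("S", 1:n),
                      TST_min = rnorm(n, 400, 30), SE_pct = rnorm(n, 90, 4),
                      WASO_min = rnorm(n, 30, 10), N1_pct = rnorm(n, 5, 2),
                      N2_pct = rnorm(n, 50, 5), N3_pct = rnorm(n, 20, 5),
                      REM_pct = rnorm(n, 20, 5),
                      arousal_index = rnorm(n, 10, 3),
                      sws_rem = rnorm(n, 0.04, 0.01))
  outcome <- setNames(2 * sleep$sws_rem + rnorm(n, 0, 0.001),
                      sleep$subject_id)
  rep_ <- spearman_fdr(sleep, outcome, group = "HC")
  expect_equal(nrow(rep_), 9)
  expect_true(all(rep_$p_fdr >= rep_$p_raw - 1e-15))
  expect_true(all(abs(rep_$rho) <= 1))
  expect_gt(rep_$rho[rep_$sleep_metric == "sws_rem"], 0.95)
  expect_lt(rep_$p_fdr[rep_$sleep_metric == "sws_rem"], 0.001)
  expect_error(spearman_fdr(sleep[, 1:3], outcome),
               class = "emotraj_parameter_error")
})

test_that("Fisher z comparison matches the closed form", {
  eq <- fisher_z_compare(0.4, 30, 0.4, 25)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_twotailed, 1)
  expect_equal(eq$cohens_q, 0)

  fz <- fisher_z_compare(0.5, 30, 0, 30)
  expect_equal(fz$cohens_q, atanh(0.5), tolerance = 1e-10)
  expect_equal(fz$z, atanh(0.5) / sqrt(2 / 27), tolerance = 1e-10)
  expect_equal(fz$z, 2.018, tolerance = 1e-3)
  expect_equal(fz$cohens_q, 0.549, tolerance = 1e-3)
  expect_equal(fz$p_twotailed, 2 * pnorm(-abs(fz$z)), tolerance = 1e-12)

  sw <- fisher_z_compare(0, 30, 0.5, 30)
  expect_equal(sw$z, -fz$z)
  expect_equal(sw$cohens_q, -fz$cohens_q)
  expect_equal(sw$p_twotailed, fz$p_twotailed)

  expect_error(fisher_z_compare(1, 30, 0, 30),
               class = "emotraj_parameter_error")
  expect_error(fisher_z_compare(0.5, 3, 0, 30),
               class = "emotraj_parameter_error")
})

test_that("Huber regression reduces to OLS on clean data", {
  set.seed(14)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X[, "a"] - 0.5 * X[, "b"] + rnorm(n, 0, 0.4)
  hub <- huber_regression(y, X)
  ols <- coef(lm(y ~ X))
  ## clean data: Huber and OLS agree closely (all residuals small)
  expect_lt(max(abs(hub$coefficients - ols)), 0.05)
  expect_true(hub$converged)

  ## noiseless data: exact agreement
  y0 <- 1 + 2 * X[, "a"] - 0.5 * X[, "b"]
  hub0 <- huber_regression(y0, X)
  expect_lt(max(abs(hub0$coefficients - c(1, 2, -0.5))), 1e-6)
})

test_that("Huber beats OLS under a gross outlier (known truth oracle)", {
  set.seed(15)
  wins <- 0
  for (i in 1:20) {
    n <- 40
    X <- cbind(a = rnorm(n))
    y <- 1 + 2 * X[, "a"] + rnorm(n, 0, 0.3)
    y[1] <- y[1] + 50
    hub <- huber_regression(y, X)$coefficients
    ols <- coef(lm(y ~ X))
    err_h <- sum((hub - c(1, 2))^2)
    err_o <- sum((ols - c(1, 2))^2)
    if (err_h < err_o) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("Huber agrees with an established IRLS implementation", {
  skip_if_not_installed("MASS")
  set.seed(16)
  n <- 80
  X <- cbind(a = rnorm(n), b = runif(n))
  y <- 0.5 + X[, "a"] + 3 * X[, "b"] + rnorm(n, 0, 0.5)
  y[c(3, 10)] <- y[c(3, 10)] + c(8, -12)
  hub <- huber_regression(y, X)
  rlm_fit <- MASS::rlm(y ~ X, k = 1.345, maxit = 100)
  expect_lt(max(abs(hub$coefficients - coef(rlm_fit))), 0.02)
})

test_that("Huber degenerate cases: constant response, collinear design", {
  X <- cbind(a = rnorm(20))
  yc <- rep(3.5, 20)
  hub <- huber_regression(yc, X)
  expect_equal(unname(hub$coefficients), c(3.5, 0), tolerance = 1e-8)

  X2 <- cbind(a = 1:20, b = 2 * (1:20))
  err <- tryCatch(huber_regression(rnorm(20), X2), error = identity)
  expect_s3_class(err, "emotraj_parameter_error")
  expect_match(conditionMessage(err), "b")
})

test_that("participant-level +/- 3 SD trimming flags only true extremes", {
  set.seed(17)
  v <- setNames(c(rnorm(30), 10), c(paste0("S", 1:30), "OUT"))
  expect_equal(trim_sd_subjects(v, 3), "OUT")
  expect_equal(trim_sd_subjects(v[1:30], 3), character(0))
})
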