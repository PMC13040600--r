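# Independent oracles used against the package's own implementations.

# nearest-centroid temporal-generalization decoder: train class centroids at
# one time sample, classify held-out trials at another; no SVM, no shared
# code with the package classifier
nc_decode <- function(dat_tr, y_tr, dat_te, y_te, t_train, t_test) {
  mu_pos <- apply(dat_tr[y_tr == 1, , t_train, drop = FALSE], 2, mean)
  mu_neg <- apply(dat_tr[y_tr == -1, , t_train, drop = FALSE], 2, mean)
  pred <- apply(dat_te[, , t_test, drop = FALSE], 1, function(x) {
    x <- as.vector(x)
    if (sum((x - mu_pos)^2) < sum((x - mu_neg)^2)) 1 else -1
  })
  mean(pred == y_te)
}

# held-out nearest-centroid accuracy over a whole time grid (within-set
# split-half), averaged per class
nc_within_accuracy <- function(ep, t_idx) {
  y <- ifelse(ep$trial_meta$condition == "negative", 1, -1)
  n <- length(y)
  tr <- seq_len(n) %% 2 == 0
  vapply(t_idx, function(t)
    nc_decode(ep$data[tr, , , drop = FALSE], y[tr],
              ep$data[!tr, , , drop = FALSE], y[!tr], t, t), 0)
}

# brute-force Benjamini-Hochberg step-up: find largest k with
# p_(k) <= k/m * q by direct scan, report adjusted p by definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- m / seq(i, m) * sort(p)[seq(i, m)]
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# stationary distribution of a Markov chain via eigen-decomposition
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# random valid hypnogram for property tests
random_hypnogram <- function(n_epochs = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- sample(c("W", "N1", "N2", "N3", "R"), n_epochs, replace = TRUE,
               prob = c(0.2, 0.1, 0.4, 0.15, 0.15))
  hypnogram(st, 0, n_epochs)
}

# tiny epoch_set fixture: trials x channels x samples filled by a function
make_epochs <- function(n_trials = 4, n_channels = 3, n_samples = 100,
                        sfreq = 100, t0_ms = -200, fill = 0,
                        conditions = NULL) {
  dat <- array(fill, c(n_trials, n_channels, n_samples))
  if (is.null(conditions))
    conditions <- rep(c("negative", "neutral"), length.out = n_trials)
  meta <- data.frame(subject_id = "S01", session = "post_encoding",
                     condition = conditions,
                     trial_index = seq_len(n_trials), rejected = FALSE,
                     stringsAsFactors = FALSE)
  epoch_set(dat, sfreq, t0_ms, meta)
}
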