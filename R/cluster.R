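#' Cluster-permutation configuration
#'
#' @param n_permutations Monte-Carlo permutations (default 10000). When the
#'   exact arrangement count (2^n sign patterns, or group-label
#'   combinations) does not exceed this, the null is enumerated
#'   exhaustively instead.
#' @param alpha cluster-level significance threshold (default 0.05).
#' @param cluster_forming_alpha pointwise two-tailed threshold used to form
#'   clusters (default 0.05, converted to a t quantile).
#' @param seed integer seed for the permutation draws.
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(n_permutations = 10000, alpha = 0.05,
                           cluster_forming_alpha = 0.05, seed = 1L) {
  if (!(alpha > 0 && alpha < 1))
    stop_emotraj("alpha must lie in (0, 1)", "emotraj_parameter_error")
  if (n_permutations < 100)
    stop_emotraj("n_permutations must be >= 100", "emotraj_parameter_error")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 cluster_forming_alpha = cluster_forming_alpha,
                 adjacency = "grid_4conn", statistic = "sum_t",
                 seed = as.integer(seed)),
            class = "cluster_config")
}

as_map_array <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) return(maps)
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    if (any(!vapply(maps, function(m) identical(dim(m), dims), TRUE)))
      stop_emotraj("all maps must share dimensions", "emotraj_input_error")
    arr <- array(0, c(length(maps), dims))
    for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]
    return(arr)
  }
  stop_emotraj("maps must be a list of matrices or a 3-D array",
               "emotraj_input_error")
}

build_cluster_result <- function(res, cfg, n_eff) {
  nr <- nrow(res$t_map); nc <- ncol(res$t_map)
  pval <- function(mass) {
    ## tolerance keeps ties (e.g. the observed arrangement re-appearing in
    ## an exhaustive null) robust to floating-point noise
    thr <- abs(mass) - 1e-9 * max(1, abs(mass))
    if (isTRUE(res$exhaustive)) mean(res$null_max >= thr)
    else (1 + sum(res$null_max >= thr)) / (length(res$null_max) + 1)
  }
  clusters <- list()
  add <- function(mass_vec, sign) {
    for (ci in seq_along(mass_vec)) {
      lab <- sign * ci
      cells <- which(res$labels == lab, arr.ind = TRUE)
      clusters[[length(clusters) + 1L]] <<- list(
        cluster_id = length(clusters) + 1L, sign = sign,
        cells = cells, n_cells = nrow(cells),
        mass = mass_vec[ci], p_corrected = pval(mass_vec[ci]))
    }
  }
  add(res$pos_mass, 1L)
  add(res$neg_mass, -1L)
  mask <- matrix(FALSE, nr, nc)
  for (cl in clusters)
    if (cl$p_corrected <= cfg$alpha) mask[cl$cells] <- TRUE
  structure(list(clusters = clusters, significance_mask = mask,
                 observed_t_map = res$t_map, null_max_mass = res$null_max,
                 exhaustive = isTRUE(res$exhaustive), config = cfg),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(vapply(x$clusters, function(c) c$p_corrected <= x$config$alpha,
                    TRUE))
  cat(sprintf("<cluster_result> %d cluster(s), %d significant at alpha %.3g%s\n",
              length(x$clusters), sig, x$config$alpha,
              if (x$exhaustive) " (exhaustive null)" else ""))
  for (cl in x$clusters)
    cat(sprintf("  #%d %s: %d cells, mass %.2f, p = %.4g\n", cl$cluster_id,
                if (cl$sign > 0) "pos" else "neg", cl$n_cells, cl$mass,
                cl$p_corrected))
  invisible(x)
}

check_maps <- function(arr, min_n) {
  if (dim(arr)[1] < min_n)
    stop_emotraj(sprintf("need at least %d subjects", min_n),
                 "emotraj_insufficient_data_error")
  if (any(!is.finite(arr)))
    stop_emotraj("maps contain NaN or non-finite cells", "emotraj_input_error")
}

#' One-sample cluster-based permutation test against chance
#'
#' Pointwise one-sample t statistics of `maps - chance` are thresholded at
#' the two-tailed `cluster_forming_alpha` t quantile; suprathreshold cells
#' are clustered by 4-connectivity and scored by their mass (sum of t). The
#' null is the permutation distribution of the maximum absolute cluster
#' mass under random sign flips of the per-subject centered maps (enumerated
#' exhaustively when 2^n is within the permutation budget), giving
#' two-tailed family-wise control; Monte-Carlo p-values use the add-one
#' rule and are never 0.
#'
#' @param maps list of per-subject accuracy matrices (or a subjects x
#'   train-times x test-times array).
#' @param chance chance level subtracted from every map (default 0.5).
#' @param cfg a [cluster_config()].
#' @return A `cluster_result`: `clusters` (cells, mass, corrected p),
#'   `significance_mask`, `observed_t_map`, `null_max_mass`.
#' @export
onesample_cluster_test <- function(maps, chance = 0.5,
                                   cfg = cluster_config()) {
  arr <- as_map_array(maps)
  check_maps(arr, 2L)
  n <- dim(arr)[1]; nr <- dim(arr)[2]; nc <- dim(arr)[3]
  x <- matrix(arr - chance, n, nr * nc)   # column-major cells
  tcrit <- qt(1 - cfg$cluster_forming_alpha / 2, df = n - 1)
  res <- with_seed(cfg$seed,
                   onesample_perm_cpp(x, nr, nc, tcrit, cfg$n_permutations))
  build_cluster_result(res, cfg, length(res$null_max))
}

#' Two-sample cluster-based permutation test (group A minus group B)
#'
#' Pointwise independent-samples (pooled-variance) t statistics of A - B,
#' clustered and scored as in [onesample_cluster_test()]. The null permutes
#' group membership preserving group sizes.
#'
#' @param maps_A,maps_B per-group lists of subject accuracy matrices (or
#'   subjects x times x times arrays) sharing dimensions.
#' @param cfg a [cluster_config()].
#' @return A `cluster_result`.
#' @export
twosample_cluster_test <- function(maps_A, maps_B, cfg = cluster_config()) {
  arrA <- as_map_array(maps_A)
  arrB <- as_map_array(maps_B)
  check_maps(arrA, 2L); check_maps(arrB, 2L)
  if (!identical(dim(arrA)[-1], dim(arrB)[-1]))
    stop_emotraj("group maps must share dimensions", "emotraj_input_error")
  nA <- dim(arrA)[1]; nB <- dim(arrB)[1]
  nr <- dim(arrA)[2]; nc <- dim(arrA)[3]
  x <- rbind(matrix(arrA, nA, nr * nc), matrix(arrB, nB, nr * nc))
  tcrit <- qt(1 - cfg$cluster_forming_alpha / 2, df = nA + nB - 2)
  res <- with_seed(cfg$seed,
                   twosample_perm_cpp(x, nA, nr, nc, tcrit,
                                      cfg$n_permutations))
  build_cluster_result(res, cfg, length(res$null_max))
}

#' Tabulate clusters from a cluster test
#'
#' @param result a `cluster_result`.
#' @param times_ms optional decoding-grid times used to report extents.
#' @return data.frame with one row per cluster: `cluster_id`, `sign`,
#'   `n_cells`, `mass`, `p_corrected`, and train/test-time extents.
#' @export
cluster_table <- function(result, times_ms = NULL) {
  if (!length(result$clusters))
    return(data.frame(cluster_id = integer(0), sign = integer(0),
                      n_cells = integer(0), mass = numeric(0),
                      p_corrected = numeric(0)))
  do.call(rbind, lapply(result$clusters, function(cl) {
    ext <- function(i) {
      rng <- range(cl$cells[, i])
      if (!is.null(times_ms)) times_ms[rng] else rng
    }
    tr <- ext(1); te <- ext(2)
    data.frame(cluster_id = cl$cluster_id, sign = cl$sign,
               n_cells = cl$n_cells, mass = cl$mass,
               p_corrected = cl$p_corrected,
               train_from = tr[1], train_to = tr[2],
               test_from = te[1], test_to = te[2])
  }))
}
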