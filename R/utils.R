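#' @keywords internal
"_PACKAGE"

#' @useDynLib emotraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rpois plogis qnorm qt pt pnorm sd cor
#'   fft median setNames lm.wfit
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

SESSIONS <- c("post_encoding", "post_sleep", "delayed")
GROUPS <- c("HC", "ID")
CONDITIONS <- c("negative", "neutral")
STAGES <- c("W", "N1", "N2", "N3", "R")

stop_emotraj <- function(msg, class) {
  stop(structure(class = c(class, "emotraj_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

## deterministic child seeds (kept < 2^31) for nested simulation stages
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- digest::digest(key, algo = "crc32")
  as.integer(strtoi(substr(h, 1, 7), 16L))
}
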