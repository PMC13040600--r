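## Epoch container: <prefix>.dat (float64 little-endian tensor, R
## column-major trials x channels x samples), <prefix>.json sidecar with
## dims/sfreq/t0_ms/channel labels, <prefix>_meta.csv trial metadata.

container_paths <- function(prefix) {
  list(dat = paste0(prefix, ".dat"), json = paste0(prefix, ".json"),
       meta = paste0(prefix, "_meta.csv"))
}

#' Write an epoch set to the on-disk container
#'
#' @param ep an [epoch_set()].
#' @param prefix path prefix; `<prefix>.dat`, `<prefix>.json` and
#'   `<prefix>_meta.csv` are written.
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(ep, prefix) {
  stopifnot(inherits(ep, "epoch_set"))
  p <- container_paths(prefix)
  dir.create(dirname(p$dat), recursive = TRUE, showWarnings = FALSE)
  con <- file(p$dat, "wb")
  writeBin(as.vector(ep$data), con, size = 8, endian = "little")
  close(con)
  side <- list(format = "emotraj-epochs", version = 1L,
               dims = dim(ep$data), sfreq = ep$sfreq, t0_ms = ep$t0_ms,
               channel_labels = ep$channel_labels,
               meta_file = basename(p$meta))
  jsonlite::write_json(side, p$json, auto_unbox = TRUE, digits = NA)
  write.csv(ep$trial_meta, p$meta, row.names = FALSE)
  invisible(prefix)
}

#' Read an epoch set from the on-disk container
#'
#' @param prefix path prefix used by [write_epochs()].
#' @return An [epoch_set()].
#' @export
read_epochs <- function(prefix) {
  p <- container_paths(prefix)
  if (!file.exists(p$json))
    stop_emotraj(paste0("missing sidecar: ", p$json), "emotraj_format_error")
  if (!file.exists(p$dat))
    stop_emotraj(paste0("missing tensor file: ", p$dat), "emotraj_format_error")
  side <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  dims <- as.integer(side$dims)
  n <- prod(dims)
  con <- file(p$dat, "rb")
  vals <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
  close(con)
  if (length(vals) != n)
    stop_emotraj("tensor size does not match sidecar dims",
                 "emotraj_format_error")
  meta_path <- file.path(dirname(p$json), side$meta_file)
  if (!file.exists(meta_path))
    stop_emotraj(paste0("missing trial metadata: ", meta_path),
                 "emotraj_format_error")
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  if (dims[1] > 0 && nrow(meta) != dims[1])
    stop_emotraj("trial metadata row count does not match tensor",
                 "emotraj_format_error")
  if (dims[1] == 0) meta <- meta[integer(0), , drop = FALSE]
  epoch_set(array(vals, dims), side$sfreq, side$t0_ms, meta,
            side$channel_labels)
}
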