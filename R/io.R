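# On-disk interchange: raw little-endian float64 matrix + JSON metadata
# sidecar for recordings, JSON for ground truth, CSV for metrics.
# The binary matrix is stored channel-major (channel 1 samples, channel 2
# samples, ...) so a round trip is bit-identical.

#' Write a recording to a binary matrix + JSON sidecar
#'
#' Creates `<prefix>.bin` (float64, little-endian, channel-major) and
#' `<prefix>.json` (sampling rate, channels, blocks, session, units,
#' processing log, dimensions).
#'
#' @param rec an [emg_recording()].
#' @param prefix output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$signal)), con, size = 8, endian = "little")
  meta <- list(format = "emgait-rec", version = 1L,
               fs = rec$fs, n_channels = nrow(rec$signal),
               n_samples = ncol(rec$signal),
               channels = rec$channels, blocks = rec$blocks,
               session = rec$session, units = rec$units,
               processing_log = rec$processing_log,
               endian = "little", dtype = "float64")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix (or the `.json` sidecar path itself).
#' @return an [emg_recording()], bit-identical to what was written.
#' @export
read_recording <- function(prefix) {
  prefix <- sub("\\.json$", "", prefix)
  json_path <- paste0(prefix, ".json")
  bin_path <- paste0(prefix, ".bin")
  if (!file.exists(json_path))
    abort(sprintf("sidecar not found: %s", json_path), "emgait_parse")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (f in c("fs", "n_channels", "n_samples", "channels", "blocks"))
    if (is.null(meta[[f]]))
      abort(sprintf("sidecar missing required field '%s'", f),
            "emgait_metadata")
  if (!file.exists(bin_path))
    abort(sprintf("signal file not found: %s", bin_path), "emgait_parse")
  n <- meta$n_channels * meta$n_samples
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n)
    abort(sprintf("signal file truncated: expected %d doubles, got %d",
                  n, length(x)), "emgait_parse")
  sig <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  emg_recording(sig, meta$fs, meta$channels, meta$blocks,
                session = meta$session %||% "without_exo",
                units = meta$units %||% "a.u.",
                processing_log = meta$processing_log %||% character())
}

#' Write / read simulation ground truth as JSON
#'
#' @param gt an `emg_ground_truth` from [generate_recording()].
#' @param path JSON file path.
#' @return `write_ground_truth`: `path` invisibly; `read_ground_truth`: the
#'   parsed ground truth.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$artifact_times_s <- as.numeric(gt$artifact_times_s %||% numeric())
  structure(gt, class = "emg_ground_truth")
}

#' Write per-cycle metrics as long-format CSV
#'
#' @param metrics data frame from [metrics_for_cycles()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
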