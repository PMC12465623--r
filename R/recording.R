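# EMGRecording container: channels x samples matrix with block annotations.

#' Create an EMG recording object
#'
#' Container for a multi-channel surface EMG recording with per-sample block
#' annotations. The signal is stored as a channels x samples matrix; blocks
#' are labelled, contiguous, non-overlapping sample intervals given as
#' 1-based *inclusive* `(start_sample, end_sample)` pairs.
#'
#' @param signal numeric matrix, channels x samples. Row names, if absent,
#'   are taken from `channels$label`.
#' @param fs sampling rate in samples/s.
#' @param channels data frame with columns `label`, `muscle`, `side`
#'   (side in `"L"`/`"R"`). Labels must be unique.
#' @param blocks data frame with columns `label` (one of `"OFF-PRE"`, `"ON"`,
#'   `"OFF-POST"`), `start_sample`, `end_sample` (1-based inclusive).
#' @param session `"without_exo"` or `"with_exo"`.
#' @param units character scalar describing signal units (default `"a.u."`).
#' @param processing_log character vector of applied processing stages.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs, channels, blocks,
                          session = "without_exo", units = "a.u.",
                          processing_log = character()) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  rec <- structure(
    list(signal = signal, fs = fs, channels = as.data.frame(channels),
         blocks = as.data.frame(blocks), session = session, units = units,
         processing_log = as.character(processing_log)),
    class = "emg_recording")
  rownames(rec$signal) <- rec$channels$label
  validate_recording(rec)
  rec
}

#' Validate an EMG recording
#'
#' Checks the structural invariants: finite signal (no NaN/Inf), positive
#' sampling rate, unique channel labels, and contiguous non-overlapping
#' blocks that exactly tile the signal extent.
#'
#' @param rec an `emg_recording`.
#' @return `rec`, invisibly. Throws a classed `emgait_validation` error on
#'   the first violated invariant, naming the offending field.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$signal))
    abort("field 'signal': must be a channels x samples matrix", "emgait_validation")
  if (!is_number(rec$fs) || rec$fs <= 0)
    abort("field 'fs': sampling rate must be a positive number", "emgait_validation")
  if (anyNA(rec$signal) || any(!is.finite(rec$signal)))
    abort("field 'signal': contains NaN/Inf values", "emgait_validation")
  if (nrow(rec$channels) != nrow(rec$signal))
    abort("field 'channels': row count does not match signal rows", "emgait_validation")
  if (anyDuplicated(rec$channels$label))
    abort("field 'channels': labels must be unique", "emgait_validation")
  if (!all(rec$session %in% c("without_exo", "with_exo")))
    abort("field 'session': must be 'without_exo' or 'with_exo'", "emgait_validation")
  b <- rec$blocks
  if (nrow(b) < 1L)
    abort("field 'blocks': at least one block required", "emgait_validation")
  ord <- order(b$start_sample)
  b <- b[ord, , drop = FALSE]
  n <- ncol(rec$signal)
  if (b$start_sample[1] != 1L || b$end_sample[nrow(b)] != n)
    abort("field 'blocks': blocks must tile the signal extent", "emgait_validation")
  if (any(b$end_sample < b$start_sample))
    abort("field 'blocks': end_sample < start_sample", "emgait_validation")
  if (nrow(b) > 1L && any(b$start_sample[-1] != b$end_sample[-nrow(b)] + 1L))
    abort("field 'blocks': blocks must be contiguous and non-overlapping", "emgait_validation")
  invisible(rec)
}

#' Sample indices of a named block
#' @param rec an `emg_recording`.
#' @param block block label.
#' @return integer vector of sample indices.
#' @export
block_samples <- function(rec, block) {
  i <- match(block, rec$blocks$label)
  if (is.na(i))
    abort(sprintf("unknown block '%s'", block), "emgait_lookup")
  seq.int(rec$blocks$start_sample[i], rec$blocks$end_sample[i])
}

#' Start time of a named block, in seconds from recording start
#' @noRd
block_start_s <- function(rec, block) {
  i <- match(block, rec$blocks$label)
  if (is.na(i)) abort(sprintf("unknown block '%s'", block), "emgait_lookup")
  (rec$blocks$start_sample[i] - 1) / rec$fs
}

#' Row index of a channel label
#' @noRd
channel_index <- function(rec, channel) {
  i <- match(channel, rec$channels$label)
  if (is.na(i))
    abort(sprintf("unknown channel '%s'", channel), "emgait_lookup")
  i
}

#' Extract one channel's samples, optionally within one block
#' @param rec an `emg_recording`.
#' @param channel channel label.
#' @param block optional block label; `NULL` returns the full trace.
#' @return numeric vector.
#' @export
channel_signal <- function(rec, channel, block = NULL) {
  i <- channel_index(rec, channel)
  x <- rec$signal[i, ]
  if (!is.null(block)) x <- x[block_samples(rec, block)]
  as.numeric(x)
}

#' Append a stage descriptor to the processing log
#' @noRd
log_stage <- function(rec, descriptor) {
  rec$processing_log <- c(rec$processing_log, descriptor)
  rec
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%s, %s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$session, x$units))
  cat("  channels:", paste(x$channels$label, collapse = " "), "\n")
  for (i in seq_len(nrow(x$blocks)))
    cat(sprintf("  block %-8s [%d, %d] (%.1f s)\n", x$blocks$label[i],
                x$blocks$start_sample[i], x$blocks$end_sample[i],
                (x$blocks$end_sample[i] - x$blocks$start_sample[i] + 1) / x$fs))
  if (length(x$processing_log))
    cat("  processing:", paste(x$processing_log, collapse = " -> "), "\n")
  invisible(x)
}
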