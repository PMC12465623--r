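# Per-cycle amplitude metrics: RMS and integrated EMG (iEMG).
# Both are computed on the filtered, artifact-removed wide-band signal
# within cycle boundaries (not on the 1 Hz envelope): RMS measures the
# activation level, iEMG the time-integral of rectified activity ("effort"),
# in signal units x seconds. An option allows envelope-based computation for
# sensitivity analyses.

#' Root mean square of a signal segment
#'
#' @param segment numeric vector (non-empty).
#' @param fs sampling rate (unused; kept for interface symmetry).
#' @return `sqrt(mean(segment^2))`.
#' @export
compute_rms <- function(segment, fs = NULL) {
  if (!length(segment)) abort("empty segment", "emgait_precondition")
  sqrt(mean(segment^2))
}

#' Integrated EMG of a signal segment
#'
#' Trapezoidal integral of the rectified segment over its duration,
#' in signal units x seconds.
#'
#' @param segment numeric vector (non-empty).
#' @param fs sampling rate in Hz.
#' @return the integral value.
#' @export
compute_iemg <- function(segment, fs) {
  if (!length(segment)) abort("empty segment", "emgait_precondition")
  r <- abs(segment)
  if (length(r) == 1L) return(0)
  (sum(r) - (r[1] + r[length(r)]) / 2) / fs
}

#' Per-cycle metrics for segmented gait cycles
#'
#' Computes one row of metrics (RMS, iEMG, duration) per selected cycle and
#' per requested channel, slicing the given recording at the cycle
#' boundaries of `cycles` (reference-channel boundaries propagate to all
#' channels so every muscle shares the same cycle definitions).
#'
#' @param rec an [emg_recording()] holding the artifact-removed band-passed
#'   signal (use the `filtered` element of [preprocess()]); pass the
#'   `envelope` element instead for envelope-based sensitivity analyses.
#' @param cycles a `gait_cycle_set` (from [segment_gait()]) or a
#'   `gait_segmentation` list of them.
#' @param channels channel labels to compute metrics for; default all
#'   channels of `rec`.
#' @return data frame with columns `session`, `channel`, `block`,
#'   `cycle_index`, `duration_s`, `rms`, `iemg`.
#' @export
metrics_for_cycles <- function(rec, cycles, channels = rec$channels$label) {
  if (inherits(cycles, "gait_segmentation")) {
    return(do.call(rbind, lapply(cycles, metrics_for_cycles, rec = rec,
                                 channels = channels)))
  }
  b <- cycle_boundaries_samples(cycles, selected_only = TRUE)
  n <- ncol(rec$signal)
  if (nrow(b) && (min(b$start) < 1L || max(b$end) > n))
    abort("cycle boundary outside signal extent", "emgait_bounds")
  rows <- lapply(channels, function(ch) {
    i <- channel_index(rec, ch)
    if (!nrow(b)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(b)), function(k) {
      seg <- rec$signal[i, b$start[k]:b$end[k]]
      data.frame(session = rec$session, channel = ch, block = cycles$block,
                 cycle_index = b$cycle_index[k],
                 duration_s = length(seg) / rec$fs,
                 rms = compute_rms(seg),
                 iemg = compute_iemg(seg, rec$fs))
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(session = character(), channel = character(),
                      block = character(), cycle_index = integer(),
                      duration_s = numeric(), rms = numeric(),
                      iemg = numeric())
  rownames(out) <- NULL
  out
}
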