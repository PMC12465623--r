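# Five-stage artifact-robust EMG preprocessing chain:
#   band-pass -> line notch -> stimulation-harmonic comb -> (rectify ->
#   median smooth -> low-pass envelope).
# All IIR stages are applied zero-phase (forward-backward) so burst timing is
# never skewed by phase lag; the effective order therefore doubles.

#' Zero-phase IIR filtering with reflection padding
#'
#' Forward-backward application of the rational filter `b/a`. The signal is
#' extended at both ends by odd (point-mirrored) reflection before filtering
#' so start-up transients fall outside the retained span.
#'
#' @param b,a filter coefficient vectors.
#' @param x numeric signal.
#' @param pad pad length in samples (clipped to `length(x) - 1`).
#' @return filtered signal, same length as `x`.
#' @export
zero_phase_filter <- function(b, a, x, pad = 3 * max(length(a), length(b))) {
  n <- length(x)
  p <- max(1L, min(n - 1L, as.integer(round(pad))))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(p + 1):(p + n)]
}

# Apply a filter zero-phase per channel, optionally to selected blocks only.
# Block-wise filtering extends the block with the recording's own
# neighbouring samples (falling back to reflection at the recording edges)
# so block boundaries do not excite avoidable filter transients.
filter_recording <- function(rec, b, a, pad, blocks = NULL) {
  if (is.null(blocks)) {
    for (i in seq_len(nrow(rec$signal)))
      rec$signal[i, ] <- zero_phase_filter(b, a, rec$signal[i, ], pad)
    return(rec)
  }
  n <- ncol(rec$signal)
  p <- max(1L, as.integer(round(pad)))
  for (blk in blocks) {
    idx <- block_samples(rec, blk)
    i0 <- max(1L, idx[1] - p)
    i1 <- min(n, idx[length(idx)] + p)
    off <- idx[1] - i0
    for (i in seq_len(nrow(rec$signal))) {
      y <- zero_phase_filter(b, a, rec$signal[i, i0:i1], pad)
      rec$signal[i, idx] <- y[(off + 1):(off + length(idx))]
    }
  }
  rec
}

#' Band-pass filter a recording
#'
#' Zero-phase 2nd-order Butterworth band-pass (default 20-500 Hz), the
#' standard surface-EMG analysis band.
#'
#' @param rec an [emg_recording()].
#' @param low_hz,high_hz corner frequencies in Hz.
#' @param order Butterworth order of the underlying one-pass design.
#' @return the filtered recording, stage appended to `processing_log`.
#' @export
bandpass <- function(rec, low_hz = 20, high_hz = 500, order = 2) {
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    abort("band edges must satisfy 0 < low_hz < high_hz < fs/2",
          "emgait_parameter")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  rec <- filter_recording(rec, bf$b, bf$a, pad = round(3 * rec$fs / low_hz))
  log_stage(rec, sprintf("bandpass(%g-%g Hz, order %d, zero-phase)",
                         low_hz, high_hz, order))
}

# Second-order notch section: unit-circle zeros at +/- theta, poles at
# radius r on the same angles (pole-zero placement). Gain normalised at the
# reference frequency ref_hz (defaults to DC).
notch_biquad <- function(f0_hz, fs, pole_radius, ref_hz = 0) {
  th <- 2 * pi * f0_hz / fs
  b <- c(1, -2 * cos(th), 1)
  a <- c(1, -2 * pole_radius * cos(th), pole_radius^2)
  g <- Mod(eval_tf(a, ref_hz, fs)) / Mod(eval_tf(b, ref_hz, fs))
  list(b = g * b, a = a)
}

# Evaluate a polynomial in z^-1 at frequency f on the unit circle.
eval_tf <- function(coef, f_hz, fs) {
  sum(coef * exp(-1i * 2 * pi * f_hz / fs * (seq_along(coef) - 1)))
}

#' Notch filter a recording
#'
#' Zero-phase second-order notch (unit-circle zeros, nearby poles) removing
#' power-line interference, 50 Hz by default.
#'
#' @param rec an [emg_recording()].
#' @param f0_hz notch frequency in Hz.
#' @param pole_radius pole radius in (0, 1); controls notch bandwidth
#'   (0.9985 at 2048 Hz gives roughly a 1 Hz notch: bandwidth ~ fs (1 - r) / pi).
#' @param harmonics number of line harmonics to notch (1 = fundamental only).
#' @return the filtered recording, stage logged.
#' @export
notch <- function(rec, f0_hz = 50, pole_radius = 0.9985, harmonics = 1) {
  if (!(f0_hz > 0 && f0_hz * harmonics < rec$fs / 2))
    abort("notch frequency must satisfy 0 < f0_hz * harmonics < fs/2",
          "emgait_parameter")
  pad <- round(5 / (1 - pole_radius))  # ~5 ring time constants
  for (k in seq_len(harmonics)) {
    sec <- notch_biquad(k * f0_hz, rec$fs, pole_radius)
    rec <- filter_recording(rec, sec$b, sec$a, pad = pad)
  }
  log_stage(rec, sprintf("notch(%g Hz x%d, r=%g, zero-phase)",
                         f0_hz, harmonics, pole_radius))
}

#' Stimulation specification
#'
#' Parameters of the stimulation-artifact comb filter: fundamental frequency,
#' highest harmonic, pole radius (notch bandwidth) and the blocks the comb is
#' applied to (by default only the ON block, where the artifact exists).
#'
#' @param stim_freq_hz stimulation fundamental, Hz (default 30).
#' @param max_harmonic highest harmonic index; `NULL` selects the largest k
#'   with `k * stim_freq_hz < fs/2` at design time.
#' @param pole_radius pole radius in (0, 1), default 0.9985 (about a 1 Hz notch at 2048 Hz).
#' @param apply_to character vector of block labels (default `"ON"`).
#' @return list of class `stimulation_spec`.
#' @export
stimulation_spec <- function(stim_freq_hz = 30, max_harmonic = NULL,
                             pole_radius = 0.9985, apply_to = "ON") {
  if (!is_number(stim_freq_hz) || stim_freq_hz <= 0)
    abort("field 'stim_freq_hz': must be > 0", "emgait_validation")
  if (!is_number(pole_radius) || pole_radius <= 0 || pole_radius >= 1)
    abort("field 'pole_radius': must be in (0, 1)", "emgait_validation")
  structure(list(stim_freq_hz = stim_freq_hz, max_harmonic = max_harmonic,
                 pole_radius = pole_radius, apply_to = apply_to),
            class = "stimulation_spec")
}

#' Design the stimulation-harmonic comb filter
#'
#' Pole-zero placement: for every harmonic `k * stim_freq_hz` below Nyquist a
#' second-order section puts a zero pair exactly on the unit circle at the
#' harmonic angle and a pole pair at radius `pole_radius` on the same angles,
#' giving narrow notches with unit gain in between. Each section's gain is
#' normalised at the frequency midway to the next harmonic.
#'
#' @param spec a [stimulation_spec()].
#' @param fs sampling rate in Hz.
#' @return object of class `comb_filter`: fields `sections` (list of
#'   `b`/`a` biquads), `harmonics_hz`, `fs`, `spec`.
#' @export
design_harmonic_comb <- function(spec, fs) {
  f0 <- spec$stim_freq_hz
  kmax <- spec$max_harmonic
  if (is.null(kmax)) kmax <- floor((fs / 2 - 1e-9) / f0)
  if (kmax < 1 || f0 * kmax >= fs / 2)
    abort("comb design error: stim_freq_hz * max_harmonic must be < fs/2",
          "emgait_design")
  sections <- lapply(seq_len(kmax), function(k) {
    mid <- min((k + 0.5) * f0, (k * f0 + fs / 2) / 2)
    notch_biquad(k * f0, fs, spec$pole_radius, ref_hz = mid)
  })
  structure(list(sections = sections, harmonics_hz = f0 * seq_len(kmax),
                 fs = fs, spec = spec),
            class = "comb_filter")
}

#' Magnitude response of a designed filter
#'
#' Direct evaluation of the rational transfer function on the unit circle.
#' For zero-phase (forward-backward) application the applied magnitude is
#' the square of this one-pass response.
#'
#' @param filt a `comb_filter`, or a list with `b`/`a` coefficients.
#' @param f_hz frequencies in Hz.
#' @param fs sampling rate; taken from the filter object if present.
#' @return numeric vector of one-pass magnitudes `|H(f)|`.
#' @export
filter_magnitude <- function(filt, f_hz, fs = filt$fs) {
  one <- function(b, a, f) Mod(eval_tf(b, f, fs)) / Mod(eval_tf(a, f, fs))
  if (inherits(filt, "comb_filter")) {
    sapply(f_hz, function(f)
      prod(vapply(filt$sections, function(s) one(s$b, s$a, f), numeric(1))))
  } else {
    vapply(f_hz, function(f) one(filt$b, filt$a, f), numeric(1))
  }
}

#' Remove the stimulation artifact with the harmonic comb
#'
#' Applies the comb of [design_harmonic_comb()] zero-phase, section by
#' section, to the blocks named in `spec$apply_to` only (default: the ON
#' block). Other blocks are returned bit-identical.
#'
#' @param rec an [emg_recording()].
#' @param spec a [stimulation_spec()].
#' @return the filtered recording, stage logged.
#' @export
remove_stim_artifact <- function(rec, spec = stimulation_spec()) {
  comb <- design_harmonic_comb(spec, rec$fs)
  sos <- do.call(rbind, lapply(comb$sections, function(s) c(s$b, s$a)))
  blocks <- intersect(spec$apply_to, rec$blocks$label)
  pad <- round(5 / (1 - spec$pole_radius))  # ~5 ring time constants
  sos_zero_phase <- function(x) {
    n <- length(x)
    p <- max(1L, min(n - 1L, pad))
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- sos_filter(xp, sos)
    y <- rev(sos_filter(rev(y), sos))
    y[(p + 1):(p + n)]
  }
  n <- ncol(rec$signal)
  for (blk in blocks) {
    idx <- block_samples(rec, blk)
    i0 <- max(1L, idx[1] - pad)          # context-pad with true neighbours
    i1 <- min(n, idx[length(idx)] + pad)
    off <- idx[1] - i0
    for (i in seq_len(nrow(rec$signal))) {
      y <- sos_zero_phase(rec$signal[i, i0:i1])
      rec$signal[i, idx] <- y[(off + 1):(off + length(idx))]
    }
  }
  log_stage(rec, sprintf("comb(%g Hz x%d, r=%g, blocks=%s, zero-phase)",
                         spec$stim_freq_hz, length(comb$sections),
                         spec$pole_radius, paste(blocks, collapse = "+")))
}

#' Running-median smoothing
#'
#' Per-channel running median; rejects impulsive residuals (stimulation
#' remnants, cable/exoskeleton interference spikes) that survive the linear
#' stages. The window is forced to the nearest odd sample count.
#'
#' @param rec an [emg_recording()].
#' @param window_s window length in seconds (default 0.1).
#' @return the smoothed recording, stage logged.
#' @export
median_smooth <- function(rec, window_s = 0.1) {
  k <- round(window_s * rec$fs)
  if (k < 3)
    abort("median window too short: window_s * fs must be >= 3 samples",
          "emgait_parameter")
  k <- odd_window(k)
  for (i in seq_len(nrow(rec$signal)))
    rec$signal[i, ] <- runmed(rec$signal[i, ], k, endrule = "median")
  log_stage(rec, sprintf("median(%d samples)", k))
}

#' Envelope specification
#'
#' @param cutoff_hz low-pass corner in Hz (default 1).
#' @param order Butterworth order (default 2).
#' @param cadence_hz optional measured cycle rate; the effective cutoff is
#'   `max(cutoff_hz, cadence_hz)` so at least one envelope oscillation per
#'   gait cycle is preserved at slow walking speeds.
#' @param median_window_s optional running-median window (seconds) applied to
#'   the rectified signal before low-pass smoothing; `NULL` disables it.
#' @return list of class `envelope_spec`.
#' @export
envelope_spec <- function(cutoff_hz = 1, order = 2, cadence_hz = NULL,
                          median_window_s = NULL) {
  structure(list(cutoff_hz = cutoff_hz, order = order,
                 cadence_hz = cadence_hz, median_window_s = median_window_s),
            class = "envelope_spec")
}

#' Linear-envelope extraction
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass at 1 Hz (optionally raised to the measured cadence), optionally
#' with running-median smoothing of the rectified signal in between. Output
#' is non-negative up to filter ringing.
#'
#' @param rec an [emg_recording()].
#' @param spec an [envelope_spec()].
#' @return the envelope recording, stage logged.
#' @export
envelope <- function(rec, spec = envelope_spec()) {
  cutoff <- spec$cutoff_hz
  if (!is.null(spec$cadence_hz)) cutoff <- max(cutoff, spec$cadence_hz)
  if (!(cutoff > 0 && cutoff < rec$fs / 2))
    abort("envelope cutoff must be in (0, fs/2)", "emgait_parameter")
  rec$signal <- abs(rec$signal)
  rec <- log_stage(rec, "rectify")
  if (!is.null(spec$median_window_s))
    rec <- median_smooth(rec, spec$median_window_s)
  bf <- signal::butter(spec$order, cutoff / (rec$fs / 2), type = "low")
  rec <- filter_recording(rec, bf$b, bf$a, pad = round(3 * rec$fs / cutoff))
  log_stage(rec, sprintf("envelope(lowpass %g Hz, order %d, zero-phase)",
                         cutoff, spec$order))
}

#' Run the full preprocessing chain
#'
#' Band-pass (20-500 Hz) -> 50 Hz notch -> stimulation-harmonic comb on the
#' ON block -> envelope path (rectify -> 0.1 s median -> cadence-adjusted
#' 1 Hz low-pass). Returns both the wide-band artifact-removed signal (the
#' input to amplitude metrics) and the envelope (the input to gait-cycle
#' segmentation).
#'
#' @param rec an [emg_recording()].
#' @param low_hz,high_hz,bp_order band-pass parameters.
#' @param notch_hz line frequency (set `NULL` to skip the notch).
#' @param stim a [stimulation_spec()] or `NULL` to skip the comb.
#' @param env an [envelope_spec()]; its `median_window_s` defaults to 0.1 s
#'   here.
#' @return list of class `emg_preprocessed` with elements `filtered` and
#'   `envelope`, both [emg_recording()]s.
#' @export
preprocess <- function(rec, low_hz = 20, high_hz = 500, bp_order = 2,
                       notch_hz = 50, stim = stimulation_spec(),
                       env = envelope_spec(median_window_s = 0.1)) {
  rec <- bandpass(rec, low_hz, high_hz, bp_order)
  if (!is.null(notch_hz)) rec <- notch(rec, notch_hz)
  if (!is.null(stim)) rec <- remove_stim_artifact(rec, stim)
  env_rec <- envelope(rec, env)
  structure(list(filtered = rec, envelope = env_rec),
            class = "emg_preprocessed")
}
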