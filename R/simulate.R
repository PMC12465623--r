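# Synthetic gait-EMG simulator with known ground truth.
#
# Each channel is burst-envelope-modulated band-limited noise (carrier shaped
# to the surface-EMG band), plus a 50 Hz line sinusoid, plus a biphasic
# stimulation pulse train during the ON block only, plus sparse low-frequency
# motion transients and broadband background noise. Cycle-start times, the
# injected pre->post effects and the stimulation pulse times are returned as
# ground truth so every downstream stage can be validated.

#' Default muscle set for the simulator
#'
#' Seven muscles x two sides following the SENIAM surface-EMG vocabulary used
#' for gait studies. Burst onsets/durations are expressed as fractions of the
#' gait cycle and follow typical gait activation timing; the tibialis
#' anterior (TiAn) burst rises through terminal swing and peaks at heel
#' strike, i.e. it is centred on the cycle boundary (onset at 87.5% of the
#' preceding cycle). This is the cycle-start convention shared with the
#' segmentation stage, which anchors its template at the reference muscle's
#' envelope peak. Right-side bursts are shifted by half a cycle where that
#' keeps the burst inside a single cycle.
#'
#' @return data frame with columns `muscle`, `side`, `label`,
#'   `burst_onset_frac`, `burst_duration_frac`, `burst_amplitude`.
#' @export
default_muscle_set <- function() {
  m <- rbind(
    data.frame(muscle = "TiAn", onset = 0.875, dur = 0.25, amp = 1.0),
    data.frame(muscle = "GaLa", onset = 0.30, dur = 0.30, amp = 1.0),
    data.frame(muscle = "ReFe", onset = 0.05, dur = 0.20, amp = 1.0),
    data.frame(muscle = "BiFe", onset = 0.80, dur = 0.18, amp = 0.8),
    data.frame(muscle = "GlMe", onset = 0.02, dur = 0.30, amp = 0.7),
    data.frame(muscle = "ErSp", onset = 0.08, dur = 0.15, amp = 0.5),
    data.frame(muscle = "ReAb", onset = 0.50, dur = 0.20, amp = 0.3))
  left <- data.frame(muscle = m$muscle, side = "L",
                     burst_onset_frac = m$onset,
                     burst_duration_frac = m$dur, burst_amplitude = m$amp)
  ro <- (m$onset + 0.5) %% 1
  ro <- ifelse(ro + m$dur > 1, pmax(0, 1 - m$dur), ro)  # keep burst within the cycle
  right <- data.frame(muscle = m$muscle, side = "R",
                      burst_onset_frac = ro,
                      burst_duration_frac = m$dur, burst_amplitude = m$amp)
  out <- rbind(left, right)
  out$label <- paste(out$muscle, out$side, sep = "_")
  out[, c("muscle", "side", "label", "burst_onset_frac",
          "burst_duration_frac", "burst_amplitude")]
}

#' Simulation configuration
#'
#' Parameters of the synthetic gait-EMG generator. Defaults emulate the
#' recording conditions the analysis is designed for: three 3-minute walking
#' blocks sampled at 2048 Hz, a slow ~4.5 s gait cycle with 10% cadence
#' jitter, 50 Hz line interference, and a 30 Hz biphasic stimulation artifact
#' (1 ms per phase) present during the ON block only.
#'
#' @param duration_s seconds per block (default 180).
#' @param fs sampling rate, samples/s (default 2048).
#' @param blocks block labels to generate, in order (default all three).
#' @param cycle_period_s nominal gait cycle duration in s (default 4.5).
#' @param cadence_jitter_frac multiplicative SD of per-cycle period jitter
#'   (default 0.10); individual periods are clamped to
#'   `cycle_period_s * (1 +/- 4 * cadence_jitter_frac)`.
#' @param muscles data frame as returned by [default_muscle_set()].
#' @param stim_freq_hz stimulation frequency, Hz (default 30).
#' @param stim_pulse_width_ms width of each pulse phase, ms (default 1).
#' @param stim_amplitude artifact peak amplitude relative to a unit EMG burst
#'   (default 10; transcutaneous stimulation artifacts typically dwarf the
#'   microvolt-scale EMG by an order of magnitude or more).
#' @param line_freq_hz power-line frequency, Hz (default 50).
#' @param line_amplitude line sinusoid amplitude (default 0.2).
#' @param motion_artifact_rate_per_min expected motion transients per minute
#'   (default 2).
#' @param motion_artifact_amplitude transient peak amplitude (default 1).
#' @param background_noise_sd SD of additive white background noise
#'   (default 0.1).
#' @param effect_map named list/vector: per-channel fractional amplitude
#'   change applied to the OFF-POST block, e.g. `c(ReFe_L = 0.10)`.
#' @param rng_seed integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 180, fs = 2048,
                              blocks = c("OFF-PRE", "ON", "OFF-POST"),
                              cycle_period_s = 4.5,
                              cadence_jitter_frac = 0.10,
                              muscles = default_muscle_set(),
                              stim_freq_hz = 30, stim_pulse_width_ms = 1,
                              stim_amplitude = 10,
                              line_freq_hz = 50, line_amplitude = 0.2,
                              motion_artifact_rate_per_min = 2,
                              motion_artifact_amplitude = 1,
                              background_noise_sd = 0.1,
                              effect_map = list(),
                              rng_seed = 1L) {
  cfg <- structure(
    list(duration_s = duration_s, fs = fs, blocks = blocks,
         cycle_period_s = cycle_period_s,
         cadence_jitter_frac = cadence_jitter_frac,
         muscles = as.data.frame(muscles),
         stim_freq_hz = stim_freq_hz,
         stim_pulse_width_ms = stim_pulse_width_ms,
         stim_amplitude = stim_amplitude,
         line_freq_hz = line_freq_hz, line_amplitude = line_amplitude,
         motion_artifact_rate_per_min = motion_artifact_rate_per_min,
         motion_artifact_amplitude = motion_artifact_amplitude,
         background_noise_sd = background_noise_sd,
         effect_map = as.list(effect_map), rng_seed = as.integer(rng_seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `simulation_config`.
#' @return `cfg` invisibly; classed `emgait_validation` error naming the
#'   offending field otherwise.
#' @export
validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) abort(sprintf("field '%s': %s", field, why), "emgait_validation")
  }
  chk(is_number(cfg$cycle_period_s) && cfg$cycle_period_s > 0,
      "cycle_period_s", "must be > 0")
  chk(is_number(cfg$duration_s) && cfg$duration_s > 2 * cfg$cycle_period_s,
      "duration_s", "must exceed 2 x cycle_period_s")
  chk(is_number(cfg$fs) && cfg$fs / 2 > 500,
      "fs", "Nyquist must exceed the 500 Hz analysis band edge")
  chk(all(cfg$blocks %in% c("OFF-PRE", "ON", "OFF-POST")) &&
        !anyDuplicated(cfg$blocks) && length(cfg$blocks) >= 1,
      "blocks", "must be distinct labels among OFF-PRE/ON/OFF-POST")
  chk(is_number(cfg$cadence_jitter_frac) && cfg$cadence_jitter_frac >= 0,
      "cadence_jitter_frac", "must be >= 0")
  amp_fields <- c("stim_amplitude", "line_amplitude",
                  "motion_artifact_amplitude", "background_noise_sd")
  for (f in amp_fields)
    chk(is_number(cfg[[f]]) && cfg[[f]] >= 0, f, "must be >= 0")
  chk(is_number(cfg$stim_freq_hz) && cfg$stim_freq_hz > 0 &&
        cfg$stim_freq_hz < cfg$fs / 2, "stim_freq_hz", "must be in (0, fs/2)")
  m <- cfg$muscles
  chk(nrow(m) >= 1 && all(c("label", "burst_onset_frac",
                            "burst_duration_frac", "burst_amplitude") %in% names(m)),
      "muscles", "must have label/burst_onset_frac/burst_duration_frac/burst_amplitude")
  chk(all(m$burst_amplitude >= 0), "muscles", "burst_amplitude must be >= 0")
  chk(all(m$burst_onset_frac >= 0 & m$burst_onset_frac < 1),
      "muscles", "burst_onset_frac must be in [0, 1)")
  chk(all(m$burst_duration_frac > 0 & m$burst_duration_frac <= 1),
      "muscles", "burst_duration_frac must be in (0, 1]")
  if (length(cfg$effect_map))
    chk(all(names(cfg$effect_map) %in% m$label), "effect_map",
        "names must be channel labels")
  invisible(cfg)
}

# Raised-cosine (Hann) burst profile added in place.
# events: cycle-start times (s); periods: per-cycle durations (s).
add_bursts <- function(env, fs, events, periods, onset_frac, dur_frac, amp) {
  n <- length(env)
  for (k in seq_along(events)) {
    t0 <- events[k] + onset_frac * periods[k]
    w <- dur_frac * periods[k]
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(n, ceiling((t0 + w) * fs) + 1L)
    if (i0 > n || i1 < 1L) next
    idx <- max(1L, i0):i1
    u <- ((idx - 1) / fs - t0) / w
    inside <- u >= 0 & u <= 1
    env[idx[inside]] <- env[idx[inside]] +
      amp * 0.5 * (1 - cos(2 * pi * u[inside]))
  }
  env
}

# Unit-RMS EMG carrier: white noise band-limited to 20-450 Hz.
emg_carrier <- function(n, fs) {
  w <- rnorm(n)
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  x <- zero_phase_filter(bf$b, bf$a, w, pad = min(n - 1L, round(fs / 5)))
  x / sd(x)
}

# Biphasic rectangular pulse train at stim_freq_hz over n samples.
stim_train <- function(n, fs, freq_hz, pulse_width_ms, amplitude) {
  out <- numeric(n)
  spp <- max(1L, round(fs * pulse_width_ms / 1000))  # samples per phase
  onsets <- floor(seq(0, (n - 1) / fs, by = 1 / freq_hz) * fs) + 1L
  for (o in onsets) {
    pos <- o:min(n, o + spp - 1L)
    neg <- (o + spp):min(n, o + 2L * spp - 1L)
    out[pos] <- out[pos] + amplitude
    if (neg[1] <= n) out[neg] <- out[neg] - amplitude
  }
  out
}

# Damped 5 Hz sinusoid transients at random times (rate per minute).
motion_transients <- function(n, fs, rate_per_min, amplitude) {
  out <- numeric(n)
  dur_s <- n / fs
  k <- rpois(1, rate_per_min * dur_s / 60)
  if (k == 0) return(out)
  times <- sort(runif(k, 0, dur_s))
  signs <- sample(c(-1, 1), k, replace = TRUE)
  len <- round(fs)  # 1 s support
  tt <- (0:(len - 1)) / fs
  shape <- sin(2 * pi * 5 * tt) * exp(-tt / 0.2)
  for (j in seq_len(k)) {
    i0 <- floor(times[j] * fs) + 1L
    idx <- i0:min(n, i0 + len - 1L)
    out[idx] <- out[idx] + amplitude * signs[j] * shape[seq_along(idx)]
  }
  out
}

#' Generate a synthetic gait-EMG recording with ground truth
#'
#' Produces the annotated blocks named in `config$blocks` (default OFF-PRE,
#' ON, OFF-POST). Within each block, gait cycles start at time 0 and recur
#' every `cycle_period_s` with multiplicative jitter; each muscle contributes
#' one raised-cosine activation burst per cycle which amplitude-modulates a
#' band-limited (20-450 Hz) noise carrier. Line interference, background
#' noise, sparse motion transients, and (during ON only) a biphasic
#' stimulation pulse train are added. OFF-POST channel amplitudes listed in
#' `config$effect_map` are scaled by `1 + fraction`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `recording` (an [emg_recording()]) and
#'   `ground_truth` (class `emg_ground_truth`: `event_times_s` — list of true
#'   cycle-start times per block, seconds from recording start;
#'   `injected_effects`; `artifact_times_s` — stimulation pulse times in the
#'   ON block).
#' @export
generate_recording <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  with_seed(cfg$rng_seed, {
    n_blk <- round(cfg$duration_s * cfg$fs)
    labels <- cfg$muscles$label
    n_ch <- length(labels)

    # per-block ground-truth cycle events (drawn first: stable draw order)
    events <- periods <- vector("list", length(cfg$blocks))
    names(events) <- names(periods) <- cfg$blocks
    for (b in seq_along(cfg$blocks)) {
      ev <- 0; per <- numeric()
      repeat {
        z <- rnorm(1) * cfg$cadence_jitter_frac
        z <- max(-4 * cfg$cadence_jitter_frac,
                 min(4 * cfg$cadence_jitter_frac, z))
        p <- cfg$cycle_period_s * (1 + z)
        nxt <- ev[length(ev)] + p
        per <- c(per, p)
        if (nxt >= cfg$duration_s) break
        ev <- c(ev, nxt)
      }
      events[[b]] <- ev
      periods[[b]] <- per
    }

    sig <- matrix(0, nrow = n_ch, ncol = n_blk * length(cfg$blocks))
    tt <- (0:(n_blk - 1)) / cfg$fs
    stim_times <- numeric(0)

    for (b in seq_along(cfg$blocks)) {
      blk <- cfg$blocks[b]
      cols <- (b - 1L) * n_blk + seq_len(n_blk)
      stim <- NULL
      if (blk == "ON" && cfg$stim_amplitude > 0) {
        stim <- stim_train(n_blk, cfg$fs, cfg$stim_freq_hz,
                           cfg$stim_pulse_width_ms, cfg$stim_amplitude)
        stim_times <- (b - 1) * cfg$duration_s +
          seq(0, (n_blk - 1) / cfg$fs, by = 1 / cfg$stim_freq_hz)
      }
      for (ci in seq_len(n_ch)) {
        env <- add_bursts(numeric(n_blk), cfg$fs, events[[b]], periods[[b]],
                          cfg$muscles$burst_onset_frac[ci],
                          cfg$muscles$burst_duration_frac[ci],
                          cfg$muscles$burst_amplitude[ci])
        x <- if (any(env > 0)) env * emg_carrier(n_blk, cfg$fs) else env
        phase <- runif(1, 0, 2 * pi)  # drawn unconditionally: stable draw order
        if (cfg$line_amplitude > 0)
          x <- x + cfg$line_amplitude * sin(2 * pi * cfg$line_freq_hz * tt + phase)
        if (cfg$background_noise_sd > 0)
          x <- x + cfg$background_noise_sd * rnorm(n_blk)
        if (cfg$motion_artifact_rate_per_min > 0 &&
            cfg$motion_artifact_amplitude > 0)
          x <- x + motion_transients(n_blk, cfg$fs,
                                     cfg$motion_artifact_rate_per_min,
                                     cfg$motion_artifact_amplitude)
        if (!is.null(stim)) x <- x + stim
        if (blk == "OFF-POST" && !is.null(cfg$effect_map[[labels[ci]]]))
          x <- x * (1 + cfg$effect_map[[labels[ci]]])
        sig[ci, cols] <- x
      }
    }

    blocks <- data.frame(
      label = cfg$blocks,
      start_sample = (seq_along(cfg$blocks) - 1L) * n_blk + 1L,
      end_sample = seq_along(cfg$blocks) * n_blk)
    channels <- data.frame(label = labels,
                           muscle = cfg$muscles$muscle %||% labels,
                           side = cfg$muscles$side %||% "")
    rec <- emg_recording(sig, cfg$fs, channels, blocks)
    ev_abs <- lapply(seq_along(cfg$blocks), function(b)
      events[[b]] + (b - 1) * cfg$duration_s)
    names(ev_abs) <- cfg$blocks
    gt <- structure(list(event_times_s = ev_abs,
                         injected_effects = cfg$effect_map,
                         artifact_times_s = stim_times),
                    class = "emg_ground_truth")
    list(recording = rec, ground_truth = gt)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale one channel within one block
#'
#' Multiplies the samples of `channel` inside `block` by `1 + fraction`,
#' leaving every other sample untouched. Used to inject known pre/post
#' amplitude effects for recovery testing.
#'
#' @param rec an [emg_recording()].
#' @param channel channel label.
#' @param block block label.
#' @param fraction fractional change; `0.10` scales by 1.10.
#' @return the modified recording.
#' @export
inject_effect <- function(rec, channel, block, fraction) {
  i <- channel_index(rec, channel)
  idx <- block_samples(rec, block)
  rec$signal[i, idx] <- rec$signal[i, idx] * (1 + fraction)
  rec
}
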