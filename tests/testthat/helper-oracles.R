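# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, direct enumeration, raw
# periodograms.

# quick small simulation config shared by several tests
quick_config <- function(...) {
  args <- list(duration_s = 30, cycle_period_s = 4.5,
               muscles = default_muscle_set()[c(1, 3), ],  # TiAn_L + ReFe_L
               rng_seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# noise-free variant (bursts only)
clean_config <- function(...) {
  quick_config(stim_amplitude = 0, line_amplitude = 0,
               motion_artifact_rate_per_min = 0, background_noise_sd = 0, ...)
}

# single-channel recording wrapper for filter tests
one_channel_rec <- function(x, fs = 2048, block = "OFF-PRE") {
  emg_recording(matrix(x, nrow = 1), fs,
                channels = data.frame(label = "ch1", muscle = "m", side = "L"),
                blocks = data.frame(label = block, start_sample = 1L,
                                    end_sample = length(x)))
}

# raw periodogram in dB: power at the FFT bin nearest f_hz
pgram_db <- function(x, fs, f_hz) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  10 * log10(p[which.min(abs(freqs - f_hz))] + 1e-300)
}

# total power in f_hz +/- half_bw (periodogram bins)
band_power <- function(x, fs, f_hz, half_bw) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(p[freqs >= f_hz - half_bw & freqs <= f_hz + half_bw])
}

# local noise floor: median periodogram power (dB) in a band around f_hz,
# excluding the +/- excl window
local_floor_db <- function(x, fs, f_hz, span = 10, excl = 2) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- abs(freqs - f_hz) <= span & abs(freqs - f_hz) > excl
  10 * log10(median(p[sel]) + 1e-300)
}

# brute-force running median (odd window, median end rule)
brute_runmed <- function(x, k) {
  n <- length(x); h <- (k - 1) %/% 2
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    if (i > h && i <= n - h) out[i] <- median(x[lo:hi])
  }
  out
}

# brute-force autocorrelation argmax over a lag window
brute_acf_argmax <- function(x, lags) {
  xc <- x - mean(x)
  r <- vapply(lags, function(L)
    sum(xc[1:(length(x) - L)] * xc[(L + 1):length(x)]), numeric(1))
  lags[which.max(r)]
}

# exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(m+n, m) group assignments of the pooled ranks (tie-free data)
enum_rank_sum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  total <- ncol(combos)
  p <- 2 * min(sum(u_all <= u_obs), sum(u_all >= u_obs)) / total
  min(1, p)
}

# synthetic noiseless periodic envelope: raised-cosine bumps with peaks at
# `peaks` (samples), bump full width `w`, on a small baseline
bump_train <- function(n, peaks, w, amp = 1, baseline = 0.05) {
  env <- rep(baseline, n)
  for (p in peaks) {
    idx <- max(1, ceiling(p - w / 2)):min(n, floor(p + w / 2))
    u <- (idx - (p - w / 2)) / w
    env[idx] <- env[idx] + amp * 0.5 * (1 - cos(2 * pi * u))
  }
  env
}
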