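fs <- 2048
tt <- (0:(8 * fs - 1)) / fs
sine <- function(f, a = 1) a * sin(2 * pi * f * tt)
mid <- function(x) {                 # steady-state amplitude, edges discarded
  n <- length(x)
  max(abs(x[round(n / 4):round(3 * n / 4)]))
}

test_that("band-pass matches the analog Butterworth magnitude law", {
  # closed-form one-pass |H| = 1/sqrt(1 + (f/fc)^2n); zero-phase applies it twice
  r100 <- bandpass(one_channel_rec(sine(100)))
  expect_lt(abs(mid(r100$signal[1, ]) - 1), 0.05)
  r5 <- bandpass(one_channel_rec(sine(5)))
  expect_lt(mid(r5$signal[1, ]), 0.1)
  rz <- bandpass(one_channel_rec(numeric(fs)))
  expect_true(all(rz$signal == 0))
  expect_match(tail(r100$processing_log, 1), "bandpass")
  expect_error(bandpass(one_channel_rec(sine(100)), low_hz = 600, high_hz = 500),
               class = "emgait_parameter")
  expect_error(bandpass(one_channel_rec(sine(100)), high_hz = 1200),
               class = "emgait_parameter")
})

test_that("notch rejects its line and passes neighbours per its transfer function", {
  r50 <- notch(one_channel_rec(sine(50)))
  # steady state (central half): the designed |H(50)| is exactly 0
  core <- seq(round(2 * fs), round(6 * fs))
  expect_lt(compute_rms(r50$signal[1, core]) / compute_rms(sine(50)), 0.01)
  r100 <- notch(one_channel_rec(sine(100)))
  expect_lt(abs(mid(r100$signal[1, ]) - 1), 0.05)
  rz <- notch(one_channel_rec(numeric(fs)))
  expect_true(all(rz$signal == 0))
  expect_error(notch(one_channel_rec(sine(50)), f0_hz = 1500),
               class = "emgait_parameter")
})

test_that("comb design places unit-circle zeros at harmonics over stable poles", {
  comb <- design_harmonic_comb(stimulation_spec(), fs)
  expect_equal(comb$harmonics_hz, 30 * (1:34))
  expect_equal(filter_magnitude(comb, c(30, 60, 90, 300)),
               rep(0, 4), tolerance = 1e-10)
  expect_gte(filter_magnitude(comb, 45), 0.95)
  # a notch as wide as r = 0.985 permits must still clear 0.95 at 45 Hz
  wide <- design_harmonic_comb(stimulation_spec(pole_radius = 0.985), fs)
  expect_gte(filter_magnitude(wide, 45), 0.95)
  # gain ~1 midway between harmonics
  mids <- 30 * (1:20) + 15
  expect_true(all(abs(filter_magnitude(comb, mids) - 1) <= 0.05))
  # stability: every pole strictly inside the unit circle at radius r
  pole_mod <- unlist(lapply(comb$sections, function(s)
    Mod(polyroot(rev(s$a)))))
  expect_equal(max(pole_mod), 0.9985, tolerance = 1e-8)
  expect_error(design_harmonic_comb(stimulation_spec(max_harmonic = 40), fs),
               class = "emgait_design")
})

test_that("comb removal attenuates stimulation bands in ON only, preserving envelopes", {
  # artifact attenuation measured on an artifact-dominated fixture: with EMG
  # present the +/- 0.5 Hz band ratio measures artifact-to-EMG ratio instead
  # of the filter
  art_cfg <- quick_config(line_amplitude = 0,
                          motion_artifact_rate_per_min = 0,
                          background_noise_sd = 0)
  art_cfg$muscles$burst_amplitude <- 0
  ga <- generate_recording(art_cfg)
  rec_a <- bandpass(ga$recording)
  out_a <- remove_stim_artifact(rec_a, stimulation_spec())
  core <- seq(round(3 * fs), length(block_samples(rec_a, "ON")) - round(3 * fs))
  for (f in c(30, 60, 90)) {
    # steady-state suppression: block interior, clear of the onset/offset
    # transients any narrow-band filter must produce
    drop_db <- 10 * log10(
      band_power(channel_signal(rec_a, "TiAn_L", "ON")[core], fs, f, 0.5) /
      band_power(channel_signal(out_a, "TiAn_L", "ON")[core], fs, f, 0.5))
    expect_gt(drop_db, 30)
  }

  cfg <- quick_config(line_amplitude = 0, motion_artifact_rate_per_min = 0)
  g <- generate_recording(cfg)
  rec <- bandpass(g$recording)
  out <- remove_stim_artifact(rec, stimulation_spec())
  on_pre <- channel_signal(rec, "TiAn_L", "ON")
  on_post <- channel_signal(out, "TiAn_L", "ON")
  # OFF blocks bit-identical (comb applied to ON only)
  expect_identical(channel_signal(out, "TiAn_L", "OFF-PRE"),
                   channel_signal(rec, "TiAn_L", "OFF-PRE"))
  # inter-harmonic signal-band power preserved (35-55 Hz minus 50 +/- 1)
  pwr <- function(x) band_power(x, fs, 45, 10) - band_power(x, fs, 50, 1)
  expect_gt(pwr(on_post) / pwr(on_pre), 0.9)
  # comb run over an artifact-free recording leaves envelope shape intact
  cfg0 <- quick_config(stim_amplitude = 0, line_amplitude = 0,
                       motion_artifact_rate_per_min = 0)
  rec0 <- bandpass(generate_recording(cfg0)$recording)
  comb0 <- remove_stim_artifact(rec0, stimulation_spec(apply_to = "OFF-PRE"))
  e_pre <- envelope(one_channel_rec(channel_signal(rec0, "TiAn_L", "OFF-PRE")))
  e_post <- envelope(one_channel_rec(
    channel_signal(comb0, "TiAn_L", "OFF-PRE")))
  expect_gt(cor(e_pre$signal[1, ], e_post$signal[1, ]), 0.99)
})

test_that("median smoothing matches a brute-force running median", {
  const <- one_channel_rec(rep(3.3, 1000))
  expect_equal(median_smooth(const, 0.05)$signal[1, ], rep(3.3, 1000))
  spike <- numeric(1000); spike[500] <- 100
  expect_true(all(median_smooth(one_channel_rec(spike), 0.05)$signal == 0))
  ramp <- seq(0, 1, length.out = 500)
  k <- 103  # 0.05 s at 2048 Hz, forced odd
  got <- median_smooth(one_channel_rec(ramp), 0.05)$signal[1, ]
  expect_equal(got, brute_runmed(ramp, k))
  expect_error(median_smooth(one_channel_rec(ramp), 0.0001),
               class = "emgait_parameter")
})

test_that("envelope settles to closed-form values", {
  rc <- envelope(one_channel_rec(rep(2.5, 8 * fs)))
  n <- ncol(rc$signal)
  expect_true(all(abs(rc$signal[1, round(n/4):round(3*n/4)] - 2.5) < 0.025))
  r80 <- envelope(one_channel_rec(sine(80, a = 2)))
  # mean of |A sin| = 2A/pi
  expect_equal(median(r80$signal[1, round(n/4):round(3*n/4)]), 2 * 2 / pi,
               tolerance = 0.05)
  expect_true(all(envelope(one_channel_rec(numeric(fs)))$signal == 0))
  expect_error(envelope(one_channel_rec(sine(10)),
                        envelope_spec(cutoff_hz = 3000)),
               class = "emgait_parameter")
})

test_that("cadence adjustment raises the envelope cutoff, never lowers it", {
  x <- sine(80)
  slow <- envelope(one_channel_rec(x), envelope_spec(cadence_hz = 0.2))
  expect_match(tail(slow$processing_log, 1), "lowpass 1 ")
  fast <- envelope(one_channel_rec(x), envelope_spec(cadence_hz = 2))
  expect_match(tail(fast$processing_log, 1), "lowpass 2 ")
})

test_that("linear stages are homogeneous and zero-phase", {
  g <- generate_recording(clean_config())
  x <- channel_signal(g$recording, "TiAn_L", "OFF-PRE")
  rec1 <- one_channel_rec(x)
  rec3 <- one_channel_rec(3 * x)
  for (stage in list(bandpass,
                     function(r) notch(r),
                     function(r) median_smooth(r, 0.05),
                     function(r) envelope(r))) {
    expect_equal(stage(rec3)$signal, 3 * stage(rec1)$signal,
                 tolerance = 1e-9)
  }
  # zero-phase: the burst's cross-correlation peak stays at lag 0
  y <- bandpass(rec1)$signal[1, ]
  cc <- ccf(y, x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("the preprocessing chain is reproducible and logs every stage", {
  g <- generate_recording(quick_config())
  p1 <- preprocess(g$recording)
  p2 <- preprocess(g$recording)
  expect_identical(p1$filtered$signal, p2$filtered$signal)
  expect_identical(p1$envelope$signal, p2$envelope$signal)
  expect_equal(grep("bandpass|notch|comb", p1$filtered$processing_log),
               1:3)  # narrative order preserved
  expect_true(any(grepl("rectify", p1$envelope$processing_log)))
  expect_false(any(!is.finite(p1$filtered$signal)))
  expect_false(any(!is.finite(p1$envelope$signal)))
})
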