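# All envelope fixtures here are built at 64 Hz, the rate segment_gait()
# decimates to internally.

efs <- 64

test_that("template period matches the brute-force autocorrelation oracle", {
  p_true <- 288  # 4.5 s at 64 Hz
  peaks <- seq(150, 12 * p_true, by = p_true)
  env <- bump_train(12 * p_true, peaks, w = 72)
  tm <- derive_template(env, efs, 4.5)
  oracle <- brute_acf_argmax(env, floor(0.5 * p_true):ceiling(1.5 * p_true))
  expect_lte(abs(tm$period - oracle), 1)
  expect_lte(abs(tm$period - p_true), 1)
  # peak-anchored: the template starts at its maximum
  expect_equal(which.max(tm$template), 1L)
})

test_that("degenerate envelopes raise periodicity/precondition errors", {
  expect_error(derive_template(rep(1, 2000), efs, 4.5),
               class = "emgait_periodicity")
  env2 <- bump_train(2 * 288, c(150, 438), w = 72)
  expect_error(derive_template(env2, efs, 4.5),
               class = "emgait_precondition")
})

test_that("noiseless periodic envelopes are segmented to within one sample", {
  p <- 288
  peaks <- seq(300, 15 * p, by = p)
  env <- bump_train(15 * p + 200, peaks, w = 72)
  tm <- derive_template(env, efs, 4.5)
  cs <- select_cycles(segment_cycles_dtw(env, tm, efs))
  ev_samples <- cs$event_times_s * efs + 1
  # every selected cycle start is exact; partial edge matches are the only
  # rejections
  sel_ev <- ev_samples[cs$selected]
  expect_true(all(vapply(sel_ev, function(e)
    min(abs(peaks - e)), numeric(1)) <= 1))
  # every interior true peak is recovered to within one sample
  interior <- peaks[-c(1, length(peaks))]
  expect_true(all(vapply(interior, function(p0)
    min(abs(sel_ev - p0)), numeric(1)) <= 1))
  expect_error(segment_cycles_dtw(env[1:400], tm, efs),
               class = "emgait_precondition")
})

test_that("segmentation is shift-equivariant", {
  p <- 288
  peaks <- seq(300, 10 * p, by = p)
  env <- bump_train(10 * p + 300, peaks, w = 72)
  tm <- derive_template(env, efs, 4.5)
  delay <- 37
  env_d <- c(rep(env[1], delay), env)[seq_along(env)]
  e1 <- segment_cycles_dtw(env, tm, efs)$event_times_s
  e2 <- segment_cycles_dtw(env_d, tm, efs)$event_times_s
  common <- min(length(e1), length(e2))
  # compare events detected in both (the shift can push one off the edge)
  o1 <- e1[e1 > delay / efs][1:(common - 1)]
  o2 <- e2[e2 > 2 * delay / efs][1:(common - 1)]
  expect_equal(o2 - o1, rep(delay / efs, common - 1), tolerance = 1.5 / efs)
})

test_that("cycle selection keeps clean cycles and rejects corrupted ones", {
  p <- 288
  peaks <- seq(150, 13 * p, by = p)
  env <- bump_train(13 * p, peaks, w = 72)
  tm <- derive_template(env, efs, 4.5)
  cs <- segment_cycles_dtw(env, tm, efs)
  cs_all <- select_cycles(cs)
  expect_true(all(cs_all$selected))
  expect_false(cs_all$under_count)
  expect_gte(sum(cs_all$selected), 10)

  # corrupt one mid cycle with pure noise -> rejected as low correlation
  k <- 5
  b <- cs$boundaries
  set.seed(7)
  cs_noise <- cs
  cs_noise$envelope[b$start[k]:b$end[k]] <- runif(b$end[k] - b$start[k] + 1)
  sel <- select_cycles(cs_noise)
  expect_false(sel$selected[k])
  expect_equal(sel$selection_reason[k], "low_correlation")
  expect_true(all(sel$selected[-k]))
})

test_that("normalisation divides by the mean of per-cycle peaks", {
  p <- 100
  env <- c(bump_train(p, 50, w = 40, amp = 1, baseline = 0),
           bump_train(p, 50, w = 40, amp = 3, baseline = 0))
  cs <- gait_cycle_set("ch", "OFF-PRE", efs,
                       data.frame(start = c(1, p + 1), end = c(p, 2 * p)),
                       envelope = env, template = env[1:p])
  out <- normalize_envelopes(cs)
  expect_equal(dim(out$normalized_envelopes), c(2L, 101L))
  # peaks 1 and 3 -> mean 2 -> normalised peaks 0.5 and 1.5
  expect_equal(apply(out$normalized_envelopes, 1, max), c(0.5, 1.5),
               tolerance = 1e-6)
  # scale invariance
  cs4 <- cs; cs4$envelope <- 4 * cs4$envelope
  out4 <- normalize_envelopes(cs4)
  expect_equal(out4$normalized_envelopes, out$normalized_envelopes,
               tolerance = 1e-12)
  # degenerate all-zero envelope
  cs0 <- cs; cs0$envelope <- 0 * cs0$envelope
  expect_error(normalize_envelopes(cs0), class = "emgait_degenerate")
})

test_that("event scoring implements greedy one-to-one matching with count conservation", {
  truth <- c(0, 1, 2, 3)
  q <- evaluate_segmentation(truth, truth)
  expect_equal(q$f1, 1); expect_equal(q$rmse_ms, 0)

  expect_equal(evaluate_segmentation(numeric(0), truth)$f1, 0)

  q50 <- evaluate_segmentation(truth + 0.05, truth)
  expect_equal(q50$f1, 1)
  expect_equal(q50$rmse_ms, 50)

  expect_error(evaluate_segmentation(truth, numeric(0)),
               class = "emgait_precondition")

  # one-to-one: two predictions near one event -> one TP, one FP
  q2 <- evaluate_segmentation(c(0.99, 1.01), truth)
  expect_equal(q2$tp, 1L); expect_equal(q2$fp, 1L); expect_equal(q2$fn, 3L)
  expect_equal(q2$tp + q2$fp, 2L)
  expect_equal(q2$tp + q2$fn, length(truth))
  expect_lte(q2$rmse_ms, q2$tol_ms)
})

test_that("segment_gait recovers ground-truth events on a simulated block", {
  cfg <- quick_config(duration_s = 60)
  g <- generate_recording(cfg)
  prep <- preprocess(g$recording)
  seg <- segment_gait(prep, "TiAn_L", blocks = "OFF-PRE")
  cs <- seg[["OFF-PRE"]]
  q <- evaluate_segmentation(cs$event_times_s,
                             g$ground_truth$event_times_s[["OFF-PRE"]])
  expect_gte(q$f1, 0.85)
  expect_lte(q$rmse_ms, 100)
  # boundaries mapped into the recording's sample clock stay inside it
  b <- cycle_boundaries_samples(cs)
  expect_true(all(b$start >= 1 & b$end <= ncol(g$recording$signal)))
  expect_true(all(b$end > b$start))
})
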