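# Seeded segmentation benchmark against simulator ground truth.

#' Benchmark DTW gait-cycle segmentation on synthetic walking trials
#'
#' For each seed, generates one walking block with the simulator's default
#' noise levels, runs the full preprocessing chain and DTW segmentation on
#' the reference channel, and scores the detected cycle-start times against
#' the simulator's ground truth. Only the reference channel is generated:
#' for the first channel of the default montage this yields sample-identical
#' data to a full-montage simulation under the same seed, at a fraction of
#' the cost.
#'
#' @param seeds integer vector of simulation seeds (one trial per seed).
#' @param duration_s trial length in seconds (default 180).
#' @param cycle_period_s nominal gait-cycle period (default 4.5 s).
#' @param cadence_jitter_frac cadence jitter SD (default 0.10).
#' @param channel reference channel label (default `"TiAn_L"`).
#' @param tol_ms event-matching tolerance in ms (default 150).
#' @param ... further overrides passed to [simulation_config()].
#' @return data frame with one row per trial: `seed`, `n_true`, `n_pred`,
#'   `n_selected`, `f1`, `rmse_ms`.
#' @export
segmentation_benchmark <- function(seeds, duration_s = 180,
                                   cycle_period_s = 4.5,
                                   cadence_jitter_frac = 0.10,
                                   channel = "TiAn_L", tol_ms = 150, ...) {
  muscles <- default_muscle_set()
  muscles <- muscles[match(channel, muscles$label), , drop = FALSE]
  if (anyNA(muscles$label))
    abort(sprintf("unknown channel '%s'", channel), "emgait_lookup")
  rows <- lapply(seeds, function(s) {
    cfg <- simulation_config(duration_s = duration_s, blocks = "OFF-PRE",
                             cycle_period_s = cycle_period_s,
                             cadence_jitter_frac = cadence_jitter_frac,
                             muscles = muscles, rng_seed = s, ...)
    g <- generate_recording(cfg)
    prep <- preprocess(g$recording)
    seg <- segment_gait(prep, channel, blocks = "OFF-PRE",
                        expected_period_s = cycle_period_s)
    cs <- seg[["OFF-PRE"]]
    q <- evaluate_segmentation(cs$event_times_s,
                               g$ground_truth$event_times_s[["OFF-PRE"]],
                               tol_ms = tol_ms)
    data.frame(seed = s,
               n_true = length(g$ground_truth$event_times_s[["OFF-PRE"]]),
               n_pred = length(cs$event_times_s),
               n_selected = sum(cs$selected),
               f1 = q$f1, rmse_ms = q$rmse_ms)
  })
  do.call(rbind, rows)
}
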