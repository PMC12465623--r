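# End-to-end driver: (simulate | read) -> preprocess -> segment on the
# reference channel -> propagate boundaries -> per-cycle metrics ->
# OFF-PRE vs OFF-POST comparison -> summary table. Deterministic given the
# configuration; a manifest records the configuration and artifact
# checksums when results are written to disk.

PIPELINE_SCHEMA <- "emgait-pipeline/1"

pipeline_defaults <- function() {
  list(
    schema = PIPELINE_SCHEMA,
    input = NULL,                      # path prefix for read_recording()
    simulate = NULL,                   # simulation_config overrides (list)
    preprocessing = list(low_hz = 20, high_hz = 500, bp_order = 2,
                         notch_hz = 50,
                         stim_freq_hz = 30, pole_radius = 0.9985,
                         comb_blocks = "ON",
                         median_window_s = 0.1,
                         env_cutoff_hz = 1, env_order = 2,
                         cadence_hz = NULL),
    segmentation = list(reference_channel = "TiAn_L",
                        expected_period_s = 4.5, seg_fs = 64,
                        band_frac = 0.25, min_corr = 0.7,
                        duration_band = 0.3, min_cycles = 10),
    stats = list(alpha = 0.05, adjust = "none", center = "mean"),
    out_dir = NULL,
    rng_seed = 1L)
}

#' Pipeline configuration
#'
#' Builds and validates the single configuration document driving
#' [run_pipeline()]. Unknown keys (at the top level or within a section) are
#' rejected; the document serialises to/from JSON with a versioned schema
#' tag.
#'
#' @param ... named overrides of the defaults; nested sections
#'   (`preprocessing`, `segmentation`, `stats`, `simulate`) are supplied as
#'   lists and merged key-wise.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    abort(sprintf("unknown configuration key(s): %s",
                  paste(bad, collapse = ", ")), "emgait_validation")
  for (k in names(over)) {
    if (k %in% c("preprocessing", "segmentation", "stats") &&
        is.list(over[[k]])) {
      bad <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(bad))
        abort(sprintf("unknown key(s) in '%s': %s", k,
                      paste(bad, collapse = ", ")), "emgait_validation")
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  if (!identical(cfg$schema, PIPELINE_SCHEMA))
    abort(sprintf("unsupported schema tag '%s'", cfg$schema),
          "emgait_validation")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @param cfg a `pipeline_config`.
#' @return `read_pipeline_config`: the parsed configuration;
#'   `write_pipeline_config`: `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> segment -> metrics -> compare -> report on a
#' recording that is either read from `config$input` or simulated from
#' `config$simulate` (a list of [simulation_config()] overrides; the
#' pipeline's `rng_seed` is used unless the overrides carry their own).
#' Identical configuration and input produce identical results. If
#' `config$out_dir` is set, all artifacts (recording, metrics, comparison,
#' summary, manifest with checksums) are written there.
#'
#' @param config a [pipeline_config()].
#' @return results bundle (class `emg_results`): `recording`,
#'   `ground_truth` (simulated inputs only), `preprocessed`, `segmentation`,
#'   `segmentation_quality` (when ground truth is available), `metrics`,
#'   `comparison`, `summary`, `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  gt <- NULL
  if (!is.null(config$input)) {
    rec <- read_recording(config$input)
  } else {
    sim_over <- config$simulate %||% list()
    if (is.null(sim_over$rng_seed)) sim_over$rng_seed <- config$rng_seed
    sim <- do.call(simulation_config, sim_over)
    g <- generate_recording(sim)
    rec <- g$recording
    gt <- g$ground_truth
  }

  pp <- config$preprocessing
  prep <- preprocess(
    rec, low_hz = pp$low_hz, high_hz = pp$high_hz, bp_order = pp$bp_order,
    notch_hz = pp$notch_hz,
    stim = stimulation_spec(stim_freq_hz = pp$stim_freq_hz,
                            pole_radius = pp$pole_radius,
                            apply_to = pp$comb_blocks),
    env = envelope_spec(cutoff_hz = pp$env_cutoff_hz, order = pp$env_order,
                        cadence_hz = pp$cadence_hz,
                        median_window_s = pp$median_window_s))

  sg <- config$segmentation
  test_blocks <- intersect(c("OFF-PRE", "OFF-POST"), rec$blocks$label)
  seg <- segment_gait(prep, channel = sg$reference_channel,
                      blocks = test_blocks,
                      expected_period_s = sg$expected_period_s,
                      seg_fs = sg$seg_fs, band_frac = sg$band_frac,
                      min_corr = sg$min_corr,
                      duration_band = sg$duration_band,
                      min_cycles = sg$min_cycles)

  quality <- NULL
  if (!is.null(gt)) {
    quality <- lapply(test_blocks, function(blk)
      evaluate_segmentation(seg[[blk]]$event_times_s,
                            gt$event_times_s[[blk]]))
    names(quality) <- test_blocks
  }

  metrics <- metrics_for_cycles(prep$filtered, seg)
  st <- config$stats
  comparison <- compare_blocks(metrics, alpha = st$alpha,
                               adjust = st$adjust, center = st$center)
  summary_tbl <- summary_table(comparison)

  bundle <- structure(
    list(recording = rec, ground_truth = gt, preprocessed = prep,
         segmentation = seg, segmentation_quality = quality,
         metrics = metrics, comparison = comparison, summary = summary_tbl,
         config = config),
    class = "emg_results")
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' Write a results bundle and its manifest
#'
#' Writes the recording (binary + sidecar), ground truth (if any), metrics,
#' comparison rows and summary table to `dir`, plus `manifest.json`
#' recording the configuration, seed and MD5 checksum of every artifact so
#' a run can be verified and regenerated.
#'
#' @param bundle an `emg_results` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_recording(bundle$recording, p("recording"))
  if (!is.null(bundle$ground_truth))
    write_ground_truth(bundle$ground_truth, p("ground_truth.json"))
  write_metrics(bundle$metrics, p("metrics.csv"))
  write_comparison(bundle$comparison, p("comparison.csv"))
  write.csv(bundle$summary, p("summary.csv"), row.names = FALSE)
  cfg_path <- p("config.json")
  write_pipeline_config(bundle$config, cfg_path)
  files <- setdiff(list.files(dir, full.names = TRUE),
                   p("manifest.json"))
  manifest <- list(schema = PIPELINE_SCHEMA,
                   rng_seed = bundle$config$rng_seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   artifacts = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' @export
print.emg_results <- function(x, ...) {
  cat("<emg_results>\n")
  print(x$recording)
  if (!is.null(x$segmentation_quality))
    for (blk in names(x$segmentation_quality)) {
      cat(sprintf("  %s: ", blk)); print(x$segmentation_quality[[blk]])
    }
  cat(sprintf("  %d metric rows, %d comparison rows\n",
              nrow(x$metrics), nrow(x$comparison)))
  invisible(x)
}
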