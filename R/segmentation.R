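# Gait-cycle segmentation from EMG envelopes.
#
# A cycle template is bootstrapped from the envelope's own periodicity
# (autocorrelation period estimate + pointwise median over coarse cycles,
# phase-anchored at the burst onset), then matched along the envelope by
# subsequence dynamic time warping under a Sakoe-Chiba band. Per-cycle start
# times are refined by normalised cross-correlation of the duration-rescaled
# template with parabolic sub-sample interpolation.

new_gait_cycle_set <- function(channel, block, fs, envelope, template,
                               boundaries, event_times_s,
                               t0_s = 0, fs_signal = fs,
                               block_start_sample = 1L, decim = 1L) {
  structure(list(
    channel = channel, block = block, fs = fs, envelope = envelope,
    template = template, boundaries = boundaries,
    event_times_s = event_times_s,
    t0_s = t0_s, fs_signal = fs_signal,
    block_start_sample = block_start_sample, decim = decim,
    selected = rep(TRUE, nrow(boundaries)),
    selection_reason = rep(NA_character_, nrow(boundaries)),
    under_count = FALSE, normalized_envelopes = NULL),
    class = "gait_cycle_set")
}

#' Construct a gait-cycle set from known boundaries
#'
#' Builds a `gait_cycle_set` directly from cycle boundaries, e.g. when
#' boundaries come from an external event source (foot switches) rather
#' than from [segment_cycles_dtw()]. All cycles start out selected.
#'
#' @param channel,block labels.
#' @param fs sampling rate the boundaries refer to.
#' @param boundaries data frame with 1-based inclusive `start`, `end`.
#' @param envelope,template optional envelope vector / template (needed for
#'   [select_cycles()] and [normalize_envelopes()]).
#' @param event_times_s cycle-start times in seconds; defaults to the
#'   boundary starts.
#' @param fs_signal,block_start_sample,decim mapping to the recording's
#'   clock (see [cycle_boundaries_samples()]).
#' @return a `gait_cycle_set`.
#' @export
gait_cycle_set <- function(channel, block, fs, boundaries, envelope = NULL,
                           template = NULL, event_times_s = NULL,
                           fs_signal = fs, block_start_sample = 1L,
                           decim = 1L) {
  boundaries <- as.data.frame(boundaries)
  if (nrow(boundaries) && (any(boundaries$end < boundaries$start) ||
                           is.unsorted(boundaries$start, strictly = TRUE)))
    abort("boundaries must be strictly ordered with end >= start",
          "emgait_validation")
  if (is.null(event_times_s))
    event_times_s <- (boundaries$start - 1) / fs
  new_gait_cycle_set(channel, block, fs, envelope, template, boundaries,
                     event_times_s, t0_s = (block_start_sample - 1) / fs_signal,
                     fs_signal = fs_signal,
                     block_start_sample = block_start_sample, decim = decim)
}

#' @export
print.gait_cycle_set <- function(x, ...) {
  cat(sprintf("<gait_cycle_set> %s / %s: %d cycles (%d selected%s)\n",
              x$channel %||% "?", x$block %||% "?", nrow(x$boundaries),
              sum(x$selected),
              if (x$under_count) ", UNDER-COUNT flag" else ""))
  invisible(x)
}

# circular indexing helper: 1-based index into a vector of length p
circ <- function(i, p) ((i - 1L) %% p) + 1L

#' Derive a gait-cycle template from an envelope
#'
#' Estimates the cycle period as the envelope autocorrelation peak nearest
#' the expected period (searched in `[0.5, 2] x expected`), then builds the
#' template as the pointwise median over coarse cycles extracted as
#' period-length windows centred on the envelope's per-cycle peaks (peak
#' alignment, rather than a fixed-phase fold, keeps the profile sharp when
#' cadence jitter makes cycle phase drift). The profile is finally rotated
#' so it starts at its peak: the burst centre is the one landmark invariant
#' to symmetric (zero-phase) envelope smoothing, so cycles are delimited
#' peak-to-peak of the reference muscle — the heel-strike convention when
#' the reference activity peaks at initial contact.
#'
#' @param envelope numeric envelope vector (one channel, one block).
#' @param fs sampling rate of `envelope` in Hz.
#' @param expected_period_s expected gait-cycle duration in seconds.
#' @return object of class `emg_template` with fields `template` (length =
#'   estimated period in samples), `period` (samples), `fs`.
#' @export
derive_template <- function(envelope, fs, expected_period_s) {
  n <- length(envelope)
  p_exp <- expected_period_s * fs
  if (n < 3 * p_exp)
    abort("envelope must span at least 3 expected periods", "emgait_precondition")
  if (sd(envelope) < 1e-12 * (abs(mean(envelope)) + 1))
    abort("no periodic structure: envelope is constant", "emgait_periodicity")

  lag_max <- min(n - 1L, ceiling(2 * p_exp))
  ac <- as.numeric(acf(envelope, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)[-1]  # lags 1..lag_max
  lo <- max(2L, floor(0.5 * p_exp)); hi <- min(lag_max - 1L, ceiling(2 * p_exp))
  if (hi <= lo)
    abort("no periodic structure: search window empty", "emgait_periodicity")
  win <- lo:hi
  is_max <- ac[win] > ac[win - 1L] & ac[win] >= ac[win + 1L] & ac[win] > 0
  cand <- win[is_max]
  if (length(cand))  # suppress weak noise maxima
    cand <- cand[ac[cand] >= 0.5 * max(ac[cand])]
  if (!length(cand))
    abort("no autocorrelation peak in [0.5, 2] x expected period",
          "emgait_periodicity")
  period <- cand[which.min(abs(cand - p_exp))]

  # coarse cycles: period-length windows centred on per-cycle envelope peaks
  min_sep <- max(1L, floor(0.6 * period))
  is_pk <- c(FALSE, envelope[2:(n - 1)] > envelope[1:(n - 2)] &
                    envelope[2:(n - 1)] >= envelope[3:n], FALSE)
  pks <- which(is_pk)
  pks <- pks[order(envelope[pks], decreasing = TRUE)]
  keep <- integer(0)
  for (p in pks)
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  half_w <- floor(period / 2)
  keep <- sort(keep[keep - half_w >= 1 & keep + half_w <= n])
  if (length(keep) < 2L)
    abort("no periodic structure: too few envelope peaks", "emgait_periodicity")
  wins <- vapply(keep, function(p)
    envelope[(p - half_w):(p + half_w)], numeric(2L * half_w + 1L))
  prof <- apply(wins, 1, median)[seq_len(period)]
  rng <- max(prof) - min(prof)
  if (rng <= 0)
    abort("no periodic structure: folded profile is flat", "emgait_periodicity")

  # anchor at the profile peak: the burst centre is invariant to symmetric
  # (zero-phase) smoothing, unlike edge landmarks, so cycles are defined
  # peak-to-peak (heel-strike convention for a terminal-swing/loading
  # reference muscle such as tibialis anterior)
  shift <- which.max(prof)
  template <- prof[circ(shift + 0:(length(prof) - 1L), length(prof))]

  structure(list(template = template, period = period, fs = fs),
            class = "emg_template")
}

#' Segment gait cycles by subsequence DTW template matching
#'
#' Aligns the template along the envelope with subsequence dynamic time
#' warping (free start/end, symmetric steps, per-path Sakoe-Chiba band of
#' half-width `band_frac x template length`). Local minima of the
#' path-length-normalised cost are accepted greedily in order of increasing
#' cost, non-overlapping matches only, until no candidate remains; matches
#' whose warped length falls outside `[0.7, 1.3] x` template length are
#' rejected. Cycle-start times are refined by cross-correlating the
#' duration-rescaled template around each match start (parabolic sub-sample
#' interpolation).
#'
#' @param envelope numeric envelope vector.
#' @param template an `emg_template` from [derive_template()] or a numeric
#'   vector.
#' @param fs sampling rate of `envelope` in Hz.
#' @param band_frac Sakoe-Chiba half-width as a fraction of template length.
#' @param len_range admissible warped-length range as fractions of template
#'   length.
#' @return a `gait_cycle_set` with fields `boundaries` (1-based inclusive
#'   start/end envelope samples), `event_times_s` (refined cycle-start
#'   times, seconds from envelope start), `selected`, `template`.
#' @export
segment_cycles_dtw <- function(envelope, template, fs, band_frac = 0.25,
                               len_range = c(0.7, 1.3)) {
  tm <- if (inherits(template, "emg_template")) template$template
        else as.numeric(template)
  m <- length(tm)
  n <- length(envelope)
  if (n < 2 * m)
    abort("envelope must be at least 2 template lengths", "emgait_precondition")

  band <- max(1L, as.integer(round(band_frac * m)))
  scan <- dtw_subsequence_scan(as.numeric(envelope), tm, band, which.max(tm))
  ncost <- scan$cost / pmax(scan$length, 1)

  finite <- is.finite(ncost)
  is_min <- c(FALSE, ncost[2:(n - 1)] <= ncost[1:(n - 2)] &
                     ncost[2:(n - 1)] <= ncost[3:n], FALSE) & finite
  cand <- which(is_min)
  span_len <- cand - scan$start[cand] + 1L
  keep <- scan$start[cand] > 0 &
    span_len >= len_range[1] * m & span_len <= len_range[2] * m
  cand <- cand[keep]

  # greedy non-overlapping acceptance by ascending normalised cost
  cand <- cand[order(ncost[cand])]
  overlap_tol <- round(0.1 * m)
  acc_s <- integer(0); acc_e <- integer(0)
  for (j in cand) {
    s <- scan$start[j]
    if (!length(acc_s) ||
        all(pmin(j, acc_e) - pmax(s, acc_s) < overlap_tol)) {
      acc_s <- c(acc_s, s); acc_e <- c(acc_e, j)
    }
  }
  if (!length(acc_s)) {
    return(new_gait_cycle_set(NA_character_, NA_character_, fs, envelope, tm,
                              data.frame(start = integer(0), end = integer(0)),
                              numeric(0)))
  }
  ord <- order(acc_s)
  acc_s <- acc_s[ord]; acc_e <- acc_e[ord]

  # sub-sample start refinement with the duration-rescaled template
  w <- max(2L, round(0.15 * m))
  s_ref <- numeric(length(acc_s))
  for (k in seq_along(acc_s)) {
    L <- acc_e[k] - acc_s[k] + 1L
    tr <- resample_to(tm, L)
    lags <- (-w):w
    lags <- lags[acc_s[k] + lags >= 1 & acc_s[k] + lags + L - 1L <= n]
    if (length(lags) < 3L) { s_ref[k] <- acc_s[k]; next }
    sc <- vapply(lags, function(l) {
      seg <- envelope[(acc_s[k] + l):(acc_s[k] + l + L - 1L)]
      if (sd(seg) == 0 || sd(tr) == 0) return(-1)
      cor(tr, seg)
    }, numeric(1))
    bi <- which.max(sc)
    delta <- 0
    if (bi > 1L && bi < length(lags)) {
      den <- sc[bi - 1L] - 2 * sc[bi] + sc[bi + 1L]
      if (den < 0) delta <- 0.5 * (sc[bi - 1L] - sc[bi + 1L]) / den
    }
    s_ref[k] <- acc_s[k] + lags[bi] + delta
  }

  # integer boundaries, ordered and non-overlapping
  starts <- pmax(1L, pmin(n, as.integer(round(s_ref))))
  ends <- pmax(starts, pmin(n, starts + (acc_e - acc_s)))
  if (length(starts) > 1L)
    ends[-length(ends)] <- pmin(ends[-length(ends)], starts[-1L] - 1L)
  ok <- ends >= starts
  new_gait_cycle_set(NA_character_, NA_character_, fs, envelope, tm,
                     data.frame(start = starts[ok], end = ends[ok]),
                     (s_ref[ok] - 1) / fs)
}

#' Automated representative-cycle selection
#'
#' Replaces visual inspection with a reproducible rule: a cycle is selected
#' iff the Pearson correlation of its length-normalised envelope with the
#' template is at least `min_corr` and its duration lies within
#' `median +/- duration_band x median` of all cycle durations. If fewer than
#' `min_cycles` survive, the `under_count` flag is raised and all surviving
#' cycles are returned.
#'
#' @param cycles a `gait_cycle_set`.
#' @param min_corr minimum template correlation (default 0.7).
#' @param duration_band admissible fractional deviation from the median
#'   duration (default 0.3).
#' @param min_cycles minimum acceptable number of selected cycles
#'   (default 10).
#' @return the updated `gait_cycle_set` (`selected`, `selection_reason`,
#'   `under_count`).
#' @export
select_cycles <- function(cycles, min_corr = 0.7, duration_band = 0.3,
                          min_cycles = 10) {
  b <- cycles$boundaries
  if (!nrow(b)) {
    cycles$under_count <- TRUE
    return(cycles)
  }
  m <- length(cycles$template)
  durs <- b$end - b$start + 1L
  med <- median(durs)
  sel <- logical(nrow(b)); reason <- rep(NA_character_, nrow(b))
  for (k in seq_len(nrow(b))) {
    seg <- cycles$envelope[b$start[k]:b$end[k]]
    cc <- if (sd(seg) == 0) 0 else cor(resample_to(seg, m), cycles$template)
    if (is.na(cc) || cc < min_corr) {
      reason[k] <- "low_correlation"
    } else if (abs(durs[k] - med) > duration_band * med) {
      reason[k] <- "duration_outlier"
    } else {
      sel[k] <- TRUE
    }
  }
  cycles$selected <- sel
  cycles$selection_reason <- reason
  cycles$under_count <- sum(sel) < min_cycles
  cycles
}

#' Peak-normalised, time-normalised cycle envelopes
#'
#' Resamples each selected cycle's envelope to `n_points` points (0-100% of
#' the gait cycle) and divides by the mean of the per-cycle peaks across the
#' selected cycles, so the mean of normalised peaks is 1 by construction.
#' Intended for visualisation/QA; amplitude metrics are computed from the
#' unnormalised wide-band signal.
#'
#' @param cycles a `gait_cycle_set` with at least one selected cycle.
#' @param n_points number of resampled points per cycle (default 101).
#' @return the `gait_cycle_set` with `normalized_envelopes` (selected cycles
#'   x `n_points` matrix) filled in.
#' @export
normalize_envelopes <- function(cycles, n_points = 101) {
  idx <- which(cycles$selected)
  if (!length(idx))
    abort("no selected cycles to normalise", "emgait_precondition")
  mat <- t(vapply(idx, function(k)
    resample_to(cycles$envelope[cycles$boundaries$start[k]:
                                cycles$boundaries$end[k]], n_points),
    numeric(n_points)))
  mean_peak <- mean(apply(mat, 1, max))
  if (mean_peak <= 0)
    abort("degenerate signal: mean cycle peak is zero", "emgait_degenerate")
  cycles$normalized_envelopes <- mat / mean_peak
  cycles
}

#' Score predicted gait events against ground truth
#'
#' Greedy one-to-one matching of predicted to true events by increasing
#' absolute timing error, within a tolerance. Precision, recall and F1 are
#' computed from the matched counts; `rmse_ms` is the root-mean-square
#' timing error over matched pairs (bounded by the tolerance by
#' construction).
#'
#' @param predicted_s,true_s sorted event times in seconds.
#' @param tol_ms matching tolerance in milliseconds (default 150).
#' @return object of class `segmentation_quality`: `f1`, `precision`,
#'   `recall`, `rmse_ms`, `tp`, `fp`, `fn`, `tol_ms`.
#' @export
evaluate_segmentation <- function(predicted_s, true_s, tol_ms = 150) {
  if (!length(true_s))
    abort("recall undefined: no true events", "emgait_precondition")
  tol_s <- tol_ms / 1000
  pairs <- NULL
  if (length(predicted_s)) {
    d <- abs(outer(predicted_s, true_s, "-"))
    idx <- which(d <= tol_s, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(d[idx]), , drop = FALSE]
      used_p <- logical(length(predicted_s)); used_t <- logical(length(true_s))
      keep <- logical(nrow(idx))
      for (r in seq_len(nrow(idx))) {
        p <- idx[r, 1]; t <- idx[r, 2]
        if (!used_p[p] && !used_t[t]) {
          used_p[p] <- used_t[t] <- TRUE; keep[r] <- TRUE
        }
      }
      pairs <- idx[keep, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- length(predicted_s) - tp
  fn <- length(true_s) - tp
  precision <- if (length(predicted_s)) tp / length(predicted_s) else 0
  recall <- tp / length(true_s)
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  rmse_ms <- if (tp == 0) NA_real_ else
    sqrt(mean((predicted_s[pairs[, 1]] - true_s[pairs[, 2]])^2)) * 1000
  structure(list(f1 = f1, precision = precision, recall = recall,
                 rmse_ms = rmse_ms, tp = tp, fp = fp, fn = fn,
                 tol_ms = tol_ms),
            class = "segmentation_quality")
}

#' @export
print.segmentation_quality <- function(x, ...) {
  cat(sprintf("<segmentation_quality> F1 = %.3f (P %.3f / R %.3f), RMSE = %s ms @ %g ms tol\n",
              x$f1, x$precision, x$recall,
              if (is.na(x$rmse_ms)) "NA" else sprintf("%.1f", x$rmse_ms),
              x$tol_ms))
  invisible(x)
}

#' Segment gait cycles of a preprocessed recording
#'
#' High-level driver: extracts the named channel's envelope per block,
#' decimates it to about `seg_fs` (the envelope carries no content above a
#' few Hz), derives a cycle template, runs DTW segmentation, applies
#' representative-cycle selection, and computes normalised envelopes. Event
#' times and cycle boundaries are mapped back to the recording's clock.
#'
#' @param x an `emg_preprocessed` (its `envelope` element is used) or an
#'   [emg_recording()] that already holds envelopes.
#' @param channel channel label to segment on (the reference channel).
#' @param blocks block labels to segment; default all blocks.
#' @param expected_period_s expected gait-cycle duration (default 4.5 s).
#' @param seg_fs target envelope sampling rate for segmentation, Hz.
#' @param band_frac,min_corr,duration_band,min_cycles passed to
#'   [segment_cycles_dtw()] and [select_cycles()].
#' @param template optional pre-derived template (`emg_template`).
#' @return named list of `gait_cycle_set` (one per block), class
#'   `gait_segmentation`. Each set's `event_times_s` are seconds from the
#'   start of the recording.
#' @export
segment_gait <- function(x, channel, blocks = NULL, expected_period_s = 4.5,
                         seg_fs = 64, band_frac = 0.25, min_corr = 0.7,
                         duration_band = 0.3, min_cycles = 10,
                         template = NULL) {
  rec <- if (inherits(x, "emg_preprocessed")) x$envelope else x
  if (is.null(blocks)) blocks <- rec$blocks$label
  dec <- max(1L, as.integer(floor(rec$fs / seg_fs)))
  fs_e <- rec$fs / dec
  out <- lapply(blocks, function(blk) {
    env_full <- channel_signal(rec, channel, blk)
    env_blk <- env_full[seq(1, length(env_full), by = dec)]
    tmpl <- template %||% derive_template(env_blk, fs_e, expected_period_s)
    cs <- segment_cycles_dtw(env_blk, tmpl, fs_e, band_frac)
    cs$channel <- channel
    cs$block <- blk
    cs$t0_s <- block_start_s(rec, blk)
    cs$fs_signal <- rec$fs
    cs$block_start_sample <- rec$blocks$start_sample[match(blk, rec$blocks$label)]
    cs$decim <- dec
    cs$event_times_s <- cs$t0_s + cs$event_times_s
    cs <- select_cycles(cs, min_corr, duration_band, min_cycles)
    if (any(cs$selected)) cs <- normalize_envelopes(cs)
    cs
  })
  names(out) <- blocks
  structure(out, class = "gait_segmentation")
}

#' Cycle boundaries in recording samples
#'
#' Maps a `gait_cycle_set`'s envelope-rate boundaries back to 1-based
#' inclusive sample indices of the original recording.
#'
#' @param cycles a `gait_cycle_set` produced by [segment_gait()].
#' @param selected_only keep only selected cycles (default TRUE).
#' @return data frame with `start`, `end` (recording samples) and
#'   `cycle_index`.
#' @export
cycle_boundaries_samples <- function(cycles, selected_only = TRUE) {
  b <- cycles$boundaries
  keep <- if (selected_only) which(cycles$selected) else seq_len(nrow(b))
  dec <- cycles$decim %||% 1L
  bss <- cycles$block_start_sample %||% 1L
  data.frame(
    cycle_index = keep,
    start = bss + (b$start[keep] - 1L) * dec,
    end = bss + b$end[keep] * dec - 1L)
}
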