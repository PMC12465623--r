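# OFF-PRE vs OFF-POST comparison: Wilcoxon rank-sum tests per muscle/side
# and metric, percent-change summaries in the style of a clinical results
# table. Sessions are never pooled; cycles within a block are treated as
# independent observations (a documented simplification of the protocol's
# within-subject design). No multiple-testing correction is applied by
# default; Holm adjustment is available behind a flag.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' Exact null distribution (full enumeration, as implemented in
#' `stats::wilcox.test`) when the pooled sample size is at most
#' `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_threshold pooled-size limit for the exact test (default 20).
#' @return the two-sided p-value.
#' @export
rank_sum_test <- function(a, b, exact_threshold = 20) {
  if (!length(a) || !length(b))
    abort("both samples must be non-empty", "emgait_precondition")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= exact_threshold
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Compare OFF-PRE vs OFF-POST cycle metrics
#'
#' One comparison row per channel x metric: block means, percent change
#' `100 * (mean_post - mean_pre) / mean_pre`, two-sided rank-sum p-value on
#' the cycle-level values, and a significance flag. The ON block is never
#' tested. Channels missing either block are skipped with a warning.
#'
#' @param metrics data frame from [metrics_for_cycles()].
#' @param session session label recorded in the output (default taken from
#'   the metrics).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default, uncorrected p-values) or `"holm"`.
#' @param center `"mean"` (default) or `"median"` block summary for the
#'   percent change.
#' @param pre,post block labels compared.
#' @return data frame of class `emg_comparison` with columns `session`,
#'   `channel`, `metric`, `n_pre`, `n_post`, `mean_pre`, `mean_post`,
#'   `percent_change`, `p_value`, `significant`, `alpha`.
#' @export
compare_blocks <- function(metrics, session = NULL, alpha = 0.05,
                           adjust = c("none", "holm"),
                           center = c("mean", "median"),
                           pre = "OFF-PRE", post = "OFF-POST") {
  adjust <- match.arg(adjust)
  center_fun <- switch(match.arg(center), mean = mean, median = median)
  if (is.null(session)) session <- unique(metrics$session)[1]
  metrics <- metrics[metrics$session == session, , drop = FALSE]
  rows <- list()
  for (ch in unique(metrics$channel)) {
    sub <- metrics[metrics$channel == ch, , drop = FALSE]
    x_pre <- sub[sub$block == pre, , drop = FALSE]
    x_post <- sub[sub$block == post, , drop = FALSE]
    if (!nrow(x_pre) || !nrow(x_post)) {
      warning(sprintf("channel '%s' lacks a %s or %s block; skipped",
                      ch, pre, post))
      next
    }
    for (metric in c("rms", "iemg")) {
      va <- x_pre[[metric]]; vb <- x_post[[metric]]
      m_pre <- center_fun(va); m_post <- center_fun(vb)
      rows[[length(rows) + 1L]] <- data.frame(
        session = session, channel = ch, metric = metric,
        n_pre = length(va), n_post = length(vb),
        mean_pre = m_pre, mean_post = m_post,
        percent_change = 100 * (m_post - m_pre) / m_pre,
        p_value = rank_sum_test(va, vb))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    abort("no channel has both compared blocks", "emgait_precondition")
  if (adjust == "holm") out$p_value <- p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < alpha
  out$alpha <- alpha
  rownames(out) <- NULL
  class(out) <- c("emg_comparison", class(out))
  out
}

# significance markers following the convention * p < 0.05, ** p < 0.001
sig_marker <- function(p, alpha) {
  ifelse(p < 0.001, "**", ifelse(p < alpha, "*", ""))
}

#' Percent-change summary table
#'
#' Wide table with one row per channel and one column per session x metric;
#' cells show the signed percent change annotated with significance markers
#' (`*` p < alpha, `**` p < 0.001). In `"paper"` mode only significant cells
#' are populated; `"full"` mode shows all.
#'
#' @param rows an `emg_comparison` from [compare_blocks()] (rows from
#'   several sessions may be concatenated).
#' @param mode `"full"` (default) or `"paper"`.
#' @param digits decimal places in the rendered cells (default 1).
#' @return data frame: first column `channel`, remaining columns
#'   `<session>_<metric>` character cells.
#' @export
summary_table <- function(rows, mode = c("full", "paper"), digits = 1) {
  mode <- match.arg(mode)
  if (!nrow(rows)) abort("no comparison rows", "emgait_precondition")
  cells <- sprintf(paste0("%+.", digits, "f%s"), rows$percent_change,
                   sig_marker(rows$p_value, rows$alpha))
  if (mode == "paper") cells[!rows$significant] <- ""
  key <- paste(rows$session, rows$metric, sep = "_")
  channels <- unique(rows$channel)
  out <- data.frame(channel = channels)
  for (k in unique(key)) {
    col <- rep("", length(channels))
    sel <- key == k
    col[match(rows$channel[sel], channels)] <- cells[sel]
    out[[k]] <- col
  }
  out
}

#' Write / read comparison rows as CSV
#'
#' Round-trip-safe serialisation of an `emg_comparison`.
#'
#' @param rows an `emg_comparison`.
#' @param path CSV file path.
#' @return `write_comparison`: `path` invisibly. `read_comparison`: the
#'   parsed `emg_comparison`.
#' @export
write_comparison <- function(rows, path) {
  write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("emg_comparison", class(out))
  out
}
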