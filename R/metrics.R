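#' Initial-peak response metrics for a responsive unit
#'
#' Works on the baseline-subtracted trial-averaged PSTH within the peak
#' search window (first 100 ms post-stimulus by default). The peak amplitude
#' is the maximum baseline-subtracted rate (ties broken toward the earliest
#' bin) and the peak latency is that bin's center. Onset latency is the left
#' edge of the first bin of the contiguous run of bins strictly exceeding
#' `z_thresh` baseline s.d. above baseline that contains the peak bin (the
#' threshold crossing happens within that bin, so its left edge is the
#' unbiased landmark, and isolated noise bins before the response do not
#' count as onset; see vignette). Duration runs from the onset bin's left
#' edge to the left edge of the first later bin strictly below
#' `fall_thresh_sd` baseline s.d. above baseline.
#'
#' @param psth A `unit_psth` (after [detect_responsive()]).
#' @param params [analysis_params()].
#' @return List of class `peak_metrics`: `onset_ms`, `peak_ms`,
#'   `peak_amp_hz`, `duration_ms`, `found` (FALSE when no bin crosses the
#'   onset threshold inside the search window, in which case the unit is
#'   excluded from peak summaries but retained for suppression/rebound).
#' @export
peak_metrics <- function(psth, params = psth$params) {
  stopifnot(inherits(psth, "unit_psth"))
  mu <- psth$baseline_mean_hz
  sdv <- psth$baseline_sd_hz
  rate <- psth$rate_hz - mu
  win <- bins_in_window(params$peak_search_ms, params)
  peak_bin <- win[which.max(rate[win])]
  peak_amp <- rate[peak_bin]
  thr_on <- params$z_thresh * sdv
  thr_off <- params$fall_thresh_sd * sdv
  if (peak_amp <= thr_on)
    return(structure(list(found = FALSE, onset_ms = NA_real_,
                          peak_ms = NA_real_, peak_amp_hz = NA_real_,
                          duration_ms = NA_real_), class = "peak_metrics"))
  ## onset: first bin of the contiguous supra-threshold run that contains the
  ## peak bin (isolated earlier noise bins do not count as response onset)
  onset_bin <- peak_bin
  while (onset_bin > win[1] && rate[onset_bin - 1L] > thr_on)
    onset_bin <- onset_bin - 1L
  onset_ms <- params$bin_left_ms[onset_bin]
  later <- seq(onset_bin + 1L, params$n_bins)
  ## with a silent (zero-s.d.) baseline the fall threshold degenerates to the
  ## baseline mean; terminate at the first bin at or below it
  fall <- if (sdv > 0) later[rate[later] < thr_off] else
    later[rate[later] <= thr_off]
  dur <- if (length(fall)) params$bin_left_ms[fall[1]] - onset_ms else
    params$bin_edges_ms[params$n_bins + 1] - onset_ms
  structure(list(found = TRUE, onset_ms = onset_ms,
                 peak_ms = params$bin_left_ms[peak_bin] + params$bin_ms / 2,
                 peak_amp_hz = peak_amp, duration_ms = dur),
            class = "peak_metrics")
}

## paired Wilcoxon signed rank with zero differences dropped; returns NA when
## no informative pairs remain (reported as "not significant")
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0 & !is.na(d)]
  if (length(d) < 1) return(NA_real_)
  suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided")$p.value)
}

## per-trial mean firing rate (Hz) over a set of bins
trial_rates <- function(counts, bins, params) {
  rowSums(counts[, bins, drop = FALSE]) / (length(bins) * params$bin_ms / 1000)
}

#' Test for post-peak suppression
#'
#' Compares, trial by trial, the mean firing rate in the suppression window
#' (110-170 ms post-stimulus) against the mean pre-stimulus baseline rate
#' with a paired Wilcoxon signed-rank test. A unit is suppressed when the
#' test is significant and the window rate lies below baseline.
#'
#' @param psth A `unit_psth` with its trial count matrix.
#' @param params [analysis_params()].
#' @return List of class `suppression_result`: `is_suppressed`,
#'   `supp_rate_hz`, `supp_pct_baseline` (100 x window/baseline, `NA` when the
#'   baseline rate is zero), `p_value`.
#' @export
suppression_test <- function(psth, params = psth$params) {
  stopifnot(inherits(psth, "unit_psth"))
  counts <- psth$counts
  w <- trial_rates(counts, bins_in_window(params$supp_window_ms, params), params)
  b <- trial_rates(counts, params$baseline_bins, params)
  p <- signed_rank_p(w, b)
  supp_rate <- mean(w)
  base_rate <- mean(b)
  list_out <- list(
    is_suppressed = !is.na(p) && p < params$alpha && supp_rate < base_rate,
    supp_rate_hz = supp_rate,
    supp_pct_baseline = if (base_rate > 0) 100 * supp_rate / base_rate else NA_real_,
    p_value = p)
  structure(list_out, class = "suppression_result")
}

#' Test for post-inhibitory rebound
#'
#' Locates the maximum of the trial-averaged PSTH within the rebound window
#' (190-400 ms), averages the rate from `rebound_halfwidth_ms` before to
#' after that bin (span truncated at the window edges), and compares the
#' per-trial rates over that span against per-trial baseline rates with a
#' paired Wilcoxon signed-rank test.
#'
#' @param psth A `unit_psth` with its trial count matrix.
#' @param params [analysis_params()].
#' @return List of class `rebound_result`: `has_rebound`, `rebound_amp_hz`
#'   (baseline-subtracted mean over the span), `rebound_latency_ms` (center
#'   of the maximum bin), `p_value`.
#' @export
rebound_test <- function(psth, params = psth$params) {
  stopifnot(inherits(psth, "unit_psth"))
  counts <- psth$counts
  win <- bins_in_window(params$rebound_window_ms, params)
  max_bin <- win[which.max(psth$rate_hz[win])]
  center <- params$bin_left_ms[max_bin] + params$bin_ms / 2
  span_ms <- c(max(params$rebound_window_ms[1],
                   params$bin_left_ms[max_bin] - params$rebound_halfwidth_ms),
               min(params$rebound_window_ms[2],
                   params$bin_left_ms[max_bin] + params$bin_ms +
                     params$rebound_halfwidth_ms))
  span <- bins_in_window(span_ms, params)
  w <- trial_rates(counts, span, params)
  b <- trial_rates(counts, params$baseline_bins, params)
  p <- signed_rank_p(w, b)
  amp <- mean(w) - mean(b)
  structure(list(has_rebound = !is.na(p) && p < params$alpha && amp > 0,
                 rebound_amp_hz = amp, rebound_latency_ms = center,
                 p_value = p),
            class = "rebound_result")
}
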