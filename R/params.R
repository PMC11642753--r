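#' Analysis parameters
#'
#' Bundles every constant of the stimulus-aligned analysis: bin width,
#' analysis and baseline windows, the z-score responsiveness threshold, the
#' peak / suppression / rebound search windows, and inclusion rules. Defaults
#' are the values used throughout the package.
#'
#' @param bin_ms Bin width of the PSTH, ms. Must divide all window extents.
#' @param window_s Peristimulus analysis window (start, end) in seconds,
#'   relative to stimulus onset.
#' @param baseline_s Baseline window (start, end) in seconds; must lie within
#'   `window_s` and end at or before 0.
#' @param z_thresh Responsiveness / onset threshold in baseline s.d. units.
#' @param fall_thresh_sd Threshold (in baseline s.d.) used to terminate the
#'   response when measuring duration.
#' @param peak_search_ms Window (ms after stimulus) searched for the initial
#'   peak and onset.
#' @param supp_window_ms Post-peak suppression window, ms.
#' @param rebound_window_ms Rebound search window, ms.
#' @param rebound_halfwidth_ms Half-width of the averaging span around the
#'   rebound maximum, ms.
#' @param min_active_units Minimum number of active units for a probe
#'   recording to enter the analysis.
#' @param alpha Significance level for all per-unit tests.
#' @param detect_sd Scale of the z-score used by the responsiveness
#'   criterion. `"sqrt"` (default) z-scores the square-root-transformed
#'   binned counts, whose counting-noise s.d. is known and rate-independent,
#'   giving a max-over-bins statistic with stable false-positive control and
#'   detection power that does not depend on a unit's baseline rate;
#'   `"single_trial"` uses the s.d. of single-trial baseline bin rates;
#'   `"psth"` uses the s.d. across baseline bins of the trial-averaged PSTH
#'   (the scale used for onset/duration landmarks). See the vignette.
#' @param laminar_halfwidth_ms Half-width of the window around the
#'   grand-average peak used for laminar amplitudes, ms.
#' @param silencing_window_ms Integration window for silencing-effect
#'   integrals, ms (half-open `(lo, hi]`).
#' @param silencing_baseline_subtract Subtract the pre-stimulus baseline rate
#'   before integrating firing over `silencing_window_ms`.
#' @param baseline_pool Estimate each unit's baseline statistics from the
#'   pre-stimulus epochs of every trial in the session (all protocol blocks)
#'   rather than the hand-stimulation trials alone. The baseline is
#'   stationary, so pooling sharpens the per-unit estimate severalfold and
#'   decouples it from the hand-trial fluctuations that enter the
#'   responsiveness statistic.
#'
#' @return An object of class `analysis_params` (a validated list). Derived
#'   fields: `n_bins`, `bin_edges_ms`, `baseline_bins`, `post_bins`.
#' @examples
#' p <- analysis_params()
#' p$n_bins            # 200
#' length(p$baseline_bins)  # 50
#' @export
analysis_params <- function(bin_ms = 5,
                            window_s = c(-0.5, 0.5),
                            baseline_s = c(-0.25, 0),
                            z_thresh = 2.5,
                            fall_thresh_sd = 1.0,
                            peak_search_ms = c(0, 100),
                            supp_window_ms = c(110, 170),
                            rebound_window_ms = c(190, 400),
                            rebound_halfwidth_ms = 20,
                            min_active_units = 15,
                            alpha = 0.05,
                            detect_sd = c("sqrt", "single_trial", "psth"),
                            laminar_halfwidth_ms = 10,
                            silencing_window_ms = c(15, 50),
                            silencing_baseline_subtract = TRUE,
                            baseline_pool = TRUE) {
  detect_sd <- match.arg(detect_sd)
  stopifnot(bin_ms > 0, length(window_s) == 2, diff(window_s) > 0,
            length(baseline_s) == 2, diff(baseline_s) > 0,
            baseline_s[1] >= window_s[1], baseline_s[2] <= 0,
            z_thresh > 0, fall_thresh_sd > 0,
            diff(peak_search_ms) > 0, diff(supp_window_ms) > 0,
            diff(rebound_window_ms) > 0, rebound_halfwidth_ms > 0,
            min_active_units >= 1, alpha > 0, alpha < 1)
  win_ms <- window_s * 1000
  for (w in list(win_ms, baseline_s * 1000, peak_search_ms,
                 supp_window_ms, rebound_window_ms)) {
    if (any(abs(w / bin_ms - round(w / bin_ms)) > 1e-9))
      stop("bin_ms must divide all window boundaries")
  }
  n_bins <- as.integer(round(diff(win_ms) / bin_ms))
  edges <- win_ms[1] + bin_ms * (0:n_bins)
  left <- edges[-length(edges)]
  p <- list(bin_ms = bin_ms, window_s = window_s, baseline_s = baseline_s,
            z_thresh = z_thresh, fall_thresh_sd = fall_thresh_sd,
            peak_search_ms = peak_search_ms, supp_window_ms = supp_window_ms,
            rebound_window_ms = rebound_window_ms,
            rebound_halfwidth_ms = rebound_halfwidth_ms,
            min_active_units = min_active_units, alpha = alpha,
            detect_sd = detect_sd,
            laminar_halfwidth_ms = laminar_halfwidth_ms,
            silencing_window_ms = silencing_window_ms,
            silencing_baseline_subtract = silencing_baseline_subtract,
            baseline_pool = baseline_pool,
            n_bins = n_bins, bin_edges_ms = edges, bin_left_ms = left,
            baseline_bins = which(left >= baseline_s[1] * 1000 &
                                    left < baseline_s[2] * 1000),
            post_bins = which(left >= 0))
  class(p) <- "analysis_params"
  p
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Stimulus-aligned analysis parameters\n")
  cat(sprintf("  %d bins of %g ms over [%g, %g] s; baseline [%g, %g] s\n",
              x$n_bins, x$bin_ms, x$window_s[1], x$window_s[2],
              x$baseline_s[1], x$baseline_s[2]))
  cat(sprintf("  z threshold %.2f (%s s.d.), fall threshold %.1f s.d.\n",
              x$z_thresh, x$detect_sd, x$fall_thresh_sd))
  cat(sprintf("  peak (%g, %g] ms, suppression [%g, %g) ms, rebound [%g, %g) ms\n",
              x$peak_search_ms[1], x$peak_search_ms[2],
              x$supp_window_ms[1], x$supp_window_ms[2],
              x$rebound_window_ms[1], x$rebound_window_ms[2]))
  invisible(x)
}

## bin index (1-based) covering time t_ms under the package bin convention:
## half-open [left, right), anchored at stimulus onset.
bin_index <- function(t_ms, params) {
  findInterval(t_ms, params$bin_edges_ms, rightmost.closed = FALSE)
}

## bins whose [left, right) interval lies inside the half-open window (lo, hi]
## used for integral-style measures (silencing), and [lo, hi) windows used for
## suppression/rebound. Both reduce to left-edge arithmetic for bin-aligned
## windows.
bins_in_window <- function(window_ms, params) {
  left <- params$bin_left_ms
  which(left >= window_ms[1] & left < window_ms[2])
}
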