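## Laminar depth profiles: units sorted into 20 bins of 5% normalised
## cortical depth (0 = pia, 1 = white-matter boundary).

#' Depth bin assignment
#'
#' Bin k (0-based) covers `[0.05 k, 0.05 (k + 1))`; the last bin is closed at
#' 1.0 so the 20 bins partition `[0, 1]`.
#'
#' @param depth_frac Normalised cortical depths in `[0, 1]`.
#' @param n_bins Number of depth bins.
#' @return Integer bin indices in `0:(n_bins - 1)`.
#' @export
bin_by_depth <- function(depth_frac, n_bins = 20) {
  if (any(is.na(depth_frac)) || any(depth_frac < 0 | depth_frac > 1))
    stop("depth_frac must lie in [0, 1]")
  pmin(floor(depth_frac * n_bins), n_bins - 1L)
}

#' Laminar amplitude profile
#'
#' Active units are sorted into depth bins; within each recording the
#' baseline-subtracted rate around the area's grand-average peak latency
#' (+/- `laminar_halfwidth_ms`) is averaged over the units of each bin, and
#' bins are then averaged across recordings (mean +/- s.e.m.). Bins with no
#' units anywhere are flagged empty, not zero-filled.
#'
#' @param psths List of `unit_psth` objects (all active units of one area).
#' @param units Metadata rows aligned with `psths` (needs `recording_id`,
#'   `depth_frac`).
#' @param params [analysis_params()].
#' @param center_ms Center of the amplitude window; defaults to the
#'   grand-average peak latency of the responsive units (computed from the
#'   same PSTHs when `NULL`).
#' @param n_bins Number of depth bins.
#' @return Data frame of class `laminar_profile`: `depth_bin` (0-based),
#'   `depth_mid`, `amplitude_hz`, `sem_hz`, `n_units`, `n_recordings`,
#'   `empty`. The window used is attached as attribute `window_ms`.
#' @export
laminar_amplitude <- function(psths, units, params = analysis_params(),
                              center_ms = NULL, n_bins = 20) {
  stopifnot(length(psths) == nrow(units))
  if (is.null(center_ms)) {
    resp <- vapply(psths, function(p) isTRUE(p$responsive), TRUE)
    if (!any(resp)) resp <- rep(TRUE, length(psths))
    ga <- grand_average(psths, units$recording_id, subset = resp)
    win <- bins_in_window(params$peak_search_ms, params)
    base <- mean(ga$mean[params$baseline_bins])
    center_ms <- ga$time_ms[win[which.max(ga$mean[win] - base)]]
  }
  window_ms <- c(center_ms - params$laminar_halfwidth_ms,
                 center_ms + params$laminar_halfwidth_ms)
  wbins <- which(params$bin_left_ms + params$bin_ms / 2 >= window_ms[1] &
                   params$bin_left_ms + params$bin_ms / 2 <= window_ms[2])
  amp <- vapply(psths, function(p) mean(p$rate_hz[wbins]) - p$baseline_mean_hz,
                numeric(1))
  dbin <- bin_by_depth(units$depth_frac, n_bins)
  per_rec <- stats::aggregate(amp,
                              by = list(recording_id = units$recording_id,
                                        depth_bin = dbin), FUN = mean)
  out <- do.call(rbind, lapply(0:(n_bins - 1), function(k) {
    v <- per_rec$x[per_rec$depth_bin == k]
    data.frame(depth_bin = k, depth_mid = (k + 0.5) / n_bins,
               amplitude_hz = if (length(v)) mean(v) else NA_real_,
               sem_hz = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n_units = sum(dbin == k), n_recordings = length(v),
               empty = length(v) == 0)
  }))
  attr(out, "window_ms") <- window_ms
  class(out) <- c("laminar_profile", "data.frame")
  out
}

#' Correlation between two laminar profiles
#'
#' Spearman's rho across depth bins that are non-empty in both profiles
#' (e.g. the initial-peak and rebound profiles of one area).
#'
#' @param profile1,profile2 [laminar_amplitude()] results on identical bins.
#' @return Spearman's rho.
#' @export
profile_correlation <- function(profile1, profile2) {
  stopifnot(inherits(profile1, "laminar_profile"),
            inherits(profile2, "laminar_profile"),
            nrow(profile1) == nrow(profile2))
  ok <- !profile1$empty & !profile2$empty
  if (sum(ok) < 4) stop("fewer than 4 shared non-empty depth bins")
  cor(profile1$amplitude_hz[ok], profile2$amplitude_hz[ok], method = "spearman")
}
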