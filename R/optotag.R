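## Opto-tagging of PV interneurons from cortical-laser trials with sham
## controls: PV units show short-latency, sustained firing during the 20-ms
## laser pulse, absent on sham (laser-off) alignments.

#' Opto-tagging criteria
#'
#' @param sub_bin_ms Sub-bin width for tagging, ms (finer than the 5-ms
#'   analysis bins because the pulse lasts only 20 ms).
#' @param latency_max_ms Maximum latency of the first significant rate
#'   elevation for a direct (opsin-driven) response, ms.
#' @param sustained_min Minimum fraction of pulse sub-bins with rate above
#'   baseline.
#' @param alpha Significance level of the laser-vs-sham signed-rank test.
#' @param pre_s Pre-pulse baseline used for the sub-binned PSTH, s.
#' @param pulse_ms Laser pulse duration, ms.
#' @param z_thresh Threshold (in single-trial baseline s.d.) for "significant
#'   rate elevation" of a sub-bin.
#' @return A list of class `tag_params`.
#' @export
tag_params <- function(sub_bin_ms = 1, latency_max_ms = 5, sustained_min = 0.5,
                       alpha = 0.05, pre_s = 0.25, pulse_ms = 20,
                       z_thresh = 2.5) {
  structure(list(sub_bin_ms = sub_bin_ms, latency_max_ms = latency_max_ms,
                 sustained_min = sustained_min, alpha = alpha, pre_s = pre_s,
                 pulse_ms = pulse_ms, z_thresh = z_thresh),
            class = "tag_params")
}

#' Classify units as PV / non-PV from laser and sham alignments
#'
#' A unit is tagged PV when (a) the first sub-bin whose rate exceeds
#' `z_thresh` single-trial baseline s.d. above the baseline mean lies within
#' `latency_max_ms` of laser onset, (b) the rate is elevated above the
#' baseline mean in at least `sustained_min` of the sub-bins spanning the
#' pulse, and (c) per-trial firing over the pulse window is higher on laser
#' than on sham trials (paired Wilcoxon signed rank, `p < alpha`). Only
#' laser/sham trials inform the tags.
#'
#' @param spikes Spike table (`unit_id`, `spike_time_s`) for the units to
#'   classify.
#' @param unit_ids Units to classify (defaults to all units in `spikes`;
#'   pass explicitly so silent units receive a row).
#' @param laser_events,sham_events Event time vectors (s). Sham events are
#'   triggered at the same interval with the laser off.
#' @param tag [tag_params()].
#' @return Data frame of class `tag_result`: `unit_id`, `is_pv`,
#'   `laser_latency_ms`, `laser_rate_hz`, `sham_rate_hz`, `sustained_frac`,
#'   `p_value`. With no laser events, every unit is returned untagged
#'   (`is_pv = NA`) so downstream analysis proceeds without PV parsing.
#' @export
classify_pv <- function(spikes, laser_events, sham_events,
                        unit_ids = unique(spikes$unit_id),
                        tag = tag_params()) {
  if (length(laser_events) == 0) {
    return(structure(data.frame(unit_id = unit_ids, is_pv = NA,
                                laser_latency_ms = NA_real_,
                                laser_rate_hz = NA_real_, sham_rate_hz = NA_real_,
                                sustained_frac = NA_real_, p_value = NA_real_),
                     class = c("tag_result", "data.frame")))
  }
  sub_params <- analysis_params(bin_ms = tag$sub_bin_ms,
                                window_s = c(-tag$pre_s, tag$pulse_ms / 1000),
                                baseline_s = c(-tag$pre_s, 0),
                                z_thresh = tag$z_thresh)
  n_pair <- min(length(laser_events), length(sham_events))
  pulse_bins <- bins_in_window(c(0, tag$pulse_ms), sub_params)
  bin_s <- tag$sub_bin_ms / 1000
  rows <- lapply(unit_ids, function(id) {
    st <- spikes$spike_time_s[spikes$unit_id == id]
    cl <- bin_unit(st, laser_events, sub_params)
    cs <- bin_unit(st, sham_events, sub_params)
    rate <- colMeans(cl) / bin_s
    mu <- mean(rate[sub_params$baseline_bins])
    sd1 <- sd(as.vector(cl[, sub_params$baseline_bins]) / bin_s)
    thr <- if (sd1 > 0) mu + tag$z_thresh * sd1 else mu
    sig <- which(rate[pulse_bins] > thr)
    latency <- if (length(sig)) sub_params$bin_left_ms[pulse_bins[sig[1]]] else NA_real_
    sustained <- mean(rate[pulse_bins] > mu)
    wl <- rowSums(cl[seq_len(n_pair), pulse_bins, drop = FALSE]) /
      (length(pulse_bins) * bin_s)
    ws <- rowSums(cs[seq_len(n_pair), pulse_bins, drop = FALSE]) /
      (length(pulse_bins) * bin_s)
    p <- signed_rank_p(wl, ws)
    is_pv <- !is.na(latency) && latency <= tag$latency_max_ms &&
      sustained >= tag$sustained_min &&
      !is.na(p) && p < tag$alpha && mean(wl) > mean(ws)
    data.frame(unit_id = id, is_pv = is_pv, laser_latency_ms = latency,
               laser_rate_hz = mean(wl), sham_rate_hz = mean(ws),
               sustained_frac = sustained, p_value = p,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("tag_result", "data.frame"))
}

#' PV versus non-PV partition of the evoked responses
#'
#' Per recording: the percentage of stimulus-responsive units that are PV,
#' the percentage of PV (and non-PV) units that are responsive, the PV share
#' of evoked spikes over the initial-peak time course (baseline-subtracted
#' spike counts, negative unit totals treated as zero), and paired PV vs
#' non-PV comparisons of onset latency, peak amplitude, suppression and
#' rebound incidence (Wilcoxon signed rank across recordings; recordings
#' lacking one class are excluded from that comparison).
#'
#' @param tags [classify_pv()] result.
#' @param metrics Per-unit metrics table (needs `unit_id`, `recording_id`,
#'   `responsive`, `onset_ms`, `amplitude_hz`, `is_suppressed`, `has_rebound`,
#'   `evoked_spikes`).
#' @return List of class `pv_partition`: `per_recording` data frame,
#'   `comparisons` data frame, `pv_spike_share_pct` (cohort mean of
#'   per-recording shares).
#' @export
partition_metrics <- function(tags, metrics) {
  m <- merge(metrics, tags[, c("unit_id", "is_pv")], by = "unit_id")
  m <- m[!is.na(m$is_pv), , drop = FALSE]
  if (!nrow(m)) stop("no tagged units shared between tags and metrics")
  per <- lapply(split(m, m$recording_id), function(d) {
    r <- d[d$responsive %in% TRUE, , drop = FALSE]
    ev <- pmax(r$evoked_spikes, 0)
    data.frame(
      recording_id = d$recording_id[1],
      n_units = nrow(d), n_pv = sum(d$is_pv),
      pct_resp_pv = if (nrow(r)) 100 * mean(r$is_pv) else NA_real_,
      pct_pv_responsive = 100 * mean(d$responsive[d$is_pv] %in% TRUE),
      pct_nonpv_responsive = 100 * mean(d$responsive[!d$is_pv] %in% TRUE),
      pv_spike_share_pct = if (sum(ev) > 0) 100 * sum(ev[r$is_pv]) / sum(ev)
                           else NA_real_,
      onset_pv = mean(r$onset_ms[r$is_pv], na.rm = TRUE),
      onset_nonpv = mean(r$onset_ms[!r$is_pv], na.rm = TRUE),
      amp_pv = mean(r$amplitude_hz[r$is_pv], na.rm = TRUE),
      amp_nonpv = mean(r$amplitude_hz[!r$is_pv], na.rm = TRUE),
      supp_pct_pv = 100 * mean(r$is_suppressed[r$is_pv] %in% TRUE),
      supp_pct_nonpv = 100 * mean(r$is_suppressed[!r$is_pv] %in% TRUE),
      reb_pct_pv = 100 * mean(r$has_rebound[r$is_pv] %in% TRUE),
      reb_pct_nonpv = 100 * mean(r$has_rebound[!r$is_pv] %in% TRUE),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  cmp <- function(a, b, label) {
    ok <- is.finite(per[[a]]) & is.finite(per[[b]])
    data.frame(comparison = label,
               pv_mean = mean(per[[a]][ok]), nonpv_mean = mean(per[[b]][ok]),
               p_value = if (sum(ok) >= 2)
                 paired_area_test(per[[a]][ok], per[[b]][ok])$p else NA_real_,
               n_recordings = sum(ok), stringsAsFactors = FALSE)
  }
  comparisons <- rbind(
    cmp("onset_pv", "onset_nonpv", "onset latency (ms)"),
    cmp("amp_pv", "amp_nonpv", "peak amplitude (Hz)"),
    cmp("supp_pct_pv", "supp_pct_nonpv", "units with suppression (%)"),
    cmp("reb_pct_pv", "reb_pct_nonpv", "units with rebound (%)"))
  structure(list(per_recording = per, comparisons = comparisons,
                 pv_spike_share_pct = mean(per$pv_spike_share_pct, na.rm = TRUE)),
            class = "pv_partition")
}
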