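#' Run the full evoked-response analysis on a cohort
#'
#' Orchestrates every stage on spike/unit/trial tables (synthetic or read
#' from disk): probe inclusion filtering, hand-stimulation PSTHs,
#' responsiveness detection, triphasic metric extraction, per-area summary
#' tables, laminar profiles, PV opto-tagging and partitioning, propagation
#' speeds, paired-pulse recovery and silencing effects. Stages whose
#' protocols are absent from the trial table are skipped (recorded in
#' `$exclusions`).
#'
#' @param cohort A `cohort` object ([simulate_cohort()] / [read_cohort()]),
#'   or a list with `spikes`, `units`, `trials`.
#' @param params [analysis_params()].
#' @param geometry Optional probe-geometry data frame (`recording_id`,
#'   `s1_m1_mm`); taken from the cohort manifest when present.
#' @param hand_to_s1_mm Hand-to-S1 pathway distance, mm.
#' @return An object of class `cohort_analysis`; see the vignette for a tour
#'   of its elements (`metrics`, `summary`, `grand`, `laminar`, `tags`,
#'   `pv_partition`, `speeds`, `paired_pulse`, `silencing`, `exclusions`).
#' @export
analyze_cohort <- function(cohort, params = analysis_params(),
                           geometry = NULL, hand_to_s1_mm = 44.3) {
  spikes <- cohort$spikes; units <- cohort$units; trials <- cohort$trials
  require_columns(units, c("recording_id", "unit_id", "area", "depth_frac"),
                  "units")
  require_columns(trials, c("recording_id", "event_time_s", "protocol"),
                  "trials")
  if (is.null(geometry) && !is.null(cohort$manifest))
    geometry <- cohort$manifest$probe_geometry
  exclusions <- character(0)

  probes <- filter_recordings(units, params)
  for (i in which(!probes$included))
    exclusions <- c(exclusions, sprintf(
      "probe %s/%s excluded: %d active units (< %d)",
      probes$recording_id[i], probes$area[i], probes$n_units[i],
      params$min_active_units))
  keep <- merge(units, probes[probes$included, c("recording_id", "area")],
                by = c("recording_id", "area"))
  keep <- keep[order(keep$recording_id, keep$unit_id), , drop = FALSE]

  hand <- trials[trials$protocol == "hand", , drop = FALSE]
  if (!nrow(hand)) {
    ## sham-only session: align to hand-off events so the PSTH stage (and a
    ## near-zero responsive count) is still reported
    hand <- trials[trials$protocol == "hand_off", , drop = FALSE]
    if (!nrow(hand))
      stop("no hand or hand_off trials in the trial table")
    exclusions <- c(exclusions,
                    "no hand trials: PSTHs aligned to hand_off (sham) events")
  }

  psths <- vector("list", nrow(keep))
  names(psths) <- keep$unit_id
  rows <- vector("list", nrow(keep))
  for (rid in unique(keep$recording_id)) {
    ev <- sort(hand$event_time_s[hand$recording_id == rid])
    idx <- which(keep$recording_id == rid)
    sp <- spikes[spikes$recording_id == rid &
                   spikes$unit_id %in% keep$unit_id[idx],
                 c("unit_id", "spike_time_s")]
    mats <- bin_spikes(sp, ev, params)
    bmats <- NULL
    if (isTRUE(params$baseline_pool)) {
      all_ev <- sort(trials$event_time_s[trials$recording_id == rid])
      if (length(all_ev) > length(ev)) bmats <- bin_spikes(sp, all_ev, params)
    }
    for (i in idx) {
      id <- keep$unit_id[i]
      m <- if (id %in% names(mats)) mats[[id]] else
        matrix(0L, length(ev), params$n_bins)
      bm <- if (!is.null(bmats) && id %in% names(bmats)) bmats[[id]] else NULL
      p <- detect_responsive(average_psth(m, params, baseline_counts = bm),
                             params)
      psths[[id]] <- p
      pk <- if (p$responsive) peak_metrics(p, params) else NULL
      su <- if (p$responsive) suppression_test(p, params) else NULL
      rb <- if (p$responsive) rebound_test(p, params) else NULL
      wpk <- bins_in_window(params$peak_search_ms, params)
      rows[[i]] <- data.frame(
        recording_id = rid, unit_id = id, area = keep$area[i],
        depth_frac = keep$depth_frac[i],
        is_single = if ("is_single" %in% names(keep)) keep$is_single[i] else NA,
        responsive = p$responsive, baseline_hz = p$baseline_mean_hz,
        max_z = p$max_z,
        peak_found = if (is.null(pk)) NA else pk$found,
        onset_ms = if (is.null(pk)) NA_real_ else pk$onset_ms,
        peak_ms = if (is.null(pk)) NA_real_ else pk$peak_ms,
        duration_ms = if (is.null(pk)) NA_real_ else pk$duration_ms,
        amplitude_hz = if (is.null(pk)) NA_real_ else pk$peak_amp_hz,
        evoked_spikes = sum(p$rate_hz[wpk] - p$baseline_mean_hz) *
          params$bin_ms / 1000,
        is_suppressed = if (is.null(su)) NA else su$is_suppressed,
        supp_rate_hz = if (is.null(su)) NA_real_ else su$supp_rate_hz,
        supp_pct_baseline = if (is.null(su)) NA_real_ else su$supp_pct_baseline,
        supp_p = if (is.null(su)) NA_real_ else su$p_value,
        has_rebound = if (is.null(rb)) NA else rb$has_rebound,
        rebound_amp_hz = if (is.null(rb)) NA_real_ else rb$rebound_amp_hz,
        rebound_latency_ms = if (is.null(rb)) NA_real_ else rb$rebound_latency_ms,
        rebound_p = if (is.null(rb)) NA_real_ else rb$p_value,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  resp_ids <- metrics$unit_id[metrics$responsive %in% TRUE]
  smry <- summarize_responses(metrics, params)

  grand <- lapply(c(S1 = "S1", M1 = "M1"), function(a) {
    sel <- metrics$area == a
    if (!any(sel & metrics$responsive %in% TRUE)) return(NULL)
    grand_average(psths[metrics$unit_id[sel]], metrics$recording_id[sel],
                  subset = metrics$responsive[sel] %in% TRUE)
  })

  laminar <- lapply(c(S1 = "S1", M1 = "M1"), function(a) {
    sel <- metrics$area == a
    if (!any(sel)) return(NULL)
    laminar_amplitude(psths[metrics$unit_id[sel]],
                      metrics[sel, c("recording_id", "depth_frac")], params)
  })

  ## opto-tagging: full-intensity cortical laser vs sham (hand-off) events
  laser <- trials[trials$protocol == "cortex_laser" &
                    (is.na(trials$intensity_frac) | trials$intensity_frac >= 1), ]
  sham <- trials[trials$protocol == "hand_off", , drop = FALSE]
  tags <- NULL; pv_part <- NULL
  if (nrow(laser) && nrow(sham)) {
    tag_list <- lapply(unique(keep$recording_id), function(rid) {
      classify_pv(spikes[spikes$recording_id == rid, c("unit_id", "spike_time_s")],
                  sort(laser$event_time_s[laser$recording_id == rid]),
                  sort(sham$event_time_s[sham$recording_id == rid]),
                  unit_ids = keep$unit_id[keep$recording_id == rid])
    })
    tags <- do.call(rbind, c(tag_list, list(make.row.names = FALSE)))
    s1m <- metrics[metrics$area == "S1", , drop = FALSE]
    if (nrow(s1m) && any(tags$is_pv %in% TRUE))
      pv_part <- partition_metrics(tags, s1m)
  } else {
    exclusions <- c(exclusions,
                    "no full-intensity cortex_laser (or sham) trials: units untagged")
  }

  ## propagation speeds from per-recording mean latencies of responsive units
  lat <- function(col) {
    ok <- metrics$responsive %in% TRUE & metrics$peak_found %in% TRUE
    per_area <- function(a) {
      sel <- ok & metrics$area == a
      if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
      tapply(metrics[[col]][sel], metrics$recording_id[sel], mean)
    }
    s1 <- per_area("S1"); m1 <- per_area("M1")
    recs <- union(names(s1), names(m1))
    data.frame(recording_id = recs,
               s1_ms = as.numeric(s1[recs]), m1_ms = as.numeric(m1[recs]),
               row.names = NULL)
  }
  speeds <- list(onset = propagation_speeds(lat("onset_ms"), geometry,
                                            hand_to_s1_mm),
                 peak = propagation_speeds(lat("peak_ms"), geometry,
                                           hand_to_s1_mm))
  for (sx in speeds) exclusions <- c(exclusions, if (length(sx$excluded))
    sprintf("recording %s excluded from S1->M1 speed: non-positive latency difference",
            sx$excluded))

  ## property correlations across per-recording means (responsive units)
  correlations <- lapply(c(S1 = "S1", M1 = "M1"), function(a) {
    r <- metrics[metrics$area == a & metrics$responsive %in% TRUE, ]
    if (!nrow(r)) return(NULL)
    per <- stats::aggregate(
      r[, c("baseline_hz", "onset_ms", "peak_ms", "duration_ms",
            "amplitude_hz", "rebound_amp_hz")],
      by = list(recording_id = r$recording_id), FUN = mean, na.rm = TRUE)
    if (nrow(per) < 4) return(NULL)
    correlate_properties(per[, -1], alpha = params$alpha)
  })

  pp <- list(S1 = NULL, M1 = NULL)
  if (any(trials$protocol == "paired_pulse")) {
    for (a in c("S1", "M1")) {
      ua <- keep[keep$area == a, , drop = FALSE]
      if (nrow(ua))
        pp[[a]] <- paired_pulse_analysis(spikes, trials, ua, resp_ids, params)
    }
  } else exclusions <- c(exclusions, "no paired_pulse trials: recovery analysis skipped")

  sil <- NULL
  if (any(trials$protocol == "hand_plus_cortex")) {
    sil <- silencing_effect(spikes, trials, keep, resp_ids, tags, params)
  } else exclusions <- c(exclusions, "no hand_plus_cortex trials: silencing analysis skipped")

  structure(list(params = params, probes = probes, metrics = metrics,
                 psths = psths, summary = smry, grand = grand,
                 laminar = laminar, tags = tags, pv_partition = pv_part,
                 speeds = speeds, paired_pulse = pp, silencing = sil,
                 correlations = correlations, exclusions = exclusions),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Cohort analysis: %d units on %d included probes; %d responsive\n",
              nrow(m), sum(x$probes$included), sum(m$responsive %in% TRUE)))
  for (a in c("S1", "M1")) {
    sel <- m$area == a
    if (!any(sel)) next
    cat(sprintf("  %s: %4.1f%% responsive, onset %.1f ms, amplitude %.1f Hz\n",
                a, 100 * mean(m$responsive[sel] %in% TRUE),
                mean(m$onset_ms[sel], na.rm = TRUE),
                mean(m$amplitude_hz[sel], na.rm = TRUE)))
  }
  if (length(x$exclusions)) cat("  exclusions:", length(x$exclusions), "logged\n")
  invisible(x)
}
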