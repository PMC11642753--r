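## Protocol-level analyses: pathway propagation speeds, paired-pulse
## recovery, and partial-silencing effect integrals.

#' Pathway propagation speeds
#'
#' Divides pathway distances by response latencies, per recording, and
#' averages the per-recording speeds (mean of ratios, not ratio of means).
#' The hand-to-S1 distance is a morphometric constant; the S1-to-M1 distance
#' is the per-recording Euclidean distance between the probes, and the
#' S1-to-M1 latency is the per-recording M1 - S1 latency difference.
#' Recordings with a non-positive latency difference are excluded from the
#' S1-to-M1 speed and listed in `excluded`.
#'
#' @param latencies Data frame: `recording_id`, `s1_ms`, `m1_ms`
#'   (per-recording mean latencies, onset- or peak-based).
#' @param geometry Data frame: `recording_id`, `s1_m1_mm`. May be `NULL` if
#'   only the hand-to-S1 speed is wanted.
#' @param hand_to_s1_mm Hand-to-S1 pathway distance, mm.
#' @return List of class `propagation_speeds`: `per_recording`,
#'   `hand_s1_m_per_s` (mean, sd), `s1_m1_m_per_s` (mean, sd), `excluded`.
#' @examples
#' propagation_speeds(data.frame(recording_id = "R01", s1_ms = 14.7,
#'                               m1_ms = 24.3))$hand_s1_m_per_s[["mean"]]
#' @export
propagation_speeds <- function(latencies, geometry = NULL,
                               hand_to_s1_mm = 44.3) {
  stopifnot(all(c("recording_id", "s1_ms") %in% names(latencies)))
  if (any(latencies$s1_ms <= 0, na.rm = TRUE))
    stop("latencies must be positive")
  per <- latencies
  per$hand_s1_m_per_s <- hand_to_s1_mm / per$s1_ms  # mm/ms = m/s
  per$s1_m1_m_per_s <- NA_real_
  excluded <- character(0)
  if (!is.null(geometry) && "m1_ms" %in% names(per)) {
    per <- merge(per, geometry[, c("recording_id", "s1_m1_mm")],
                 by = "recording_id", all.x = TRUE)
    dlat <- per$m1_ms - per$s1_ms
    ok <- !is.na(dlat) & dlat > 0 & !is.na(per$s1_m1_mm)
    per$s1_m1_m_per_s[ok] <- per$s1_m1_mm[ok] / dlat[ok]
    excluded <- per$recording_id[!is.na(dlat) & dlat <= 0]
  }
  msd <- function(x) {
    x <- x[is.finite(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  structure(list(per_recording = per,
                 hand_s1_m_per_s = msd(per$hand_s1_m_per_s),
                 s1_m1_m_per_s = msd(per$s1_m1_m_per_s),
                 excluded = excluded),
            class = "propagation_speeds")
}

## Friedman chi-square plus Dunn-Sidak post hoc comparisons against a
## reference condition (column 1). `mat` is recordings x conditions.
friedman_dunn_sidak <- function(mat, alpha = 0.05) {
  stopifnot(is.matrix(mat), nrow(mat) >= 4, ncol(mat) >= 2)
  fr <- friedman.test(mat)
  ranks <- t(apply(mat, 1, rank))
  k <- ncol(mat); n <- nrow(mat)
  se <- sqrt(k * (k + 1) / (6 * n))
  m <- k - 1
  post <- do.call(rbind, lapply(2:k, function(j) {
    z <- (mean(ranks[, j]) - mean(ranks[, 1])) / se
    p <- 2 * pnorm(-abs(z))
    data.frame(condition = colnames(mat)[j], z = z, p_raw = p,
               p_sidak = 1 - (1 - p)^m, stringsAsFactors = FALSE)
  }))
  post$significant <- post$p_sidak < alpha
  list(chisq = unname(fr$statistic), df = unname(fr$parameter),
       p = fr$p.value, posthoc = post)
}

#' Paired-pulse recovery analysis
#'
#' For each lag condition, builds the per-recording average PSTH over
#' stimulus-responsive units, extracts first- and second-pulse peak
#' amplitudes (maximum baseline-subtracted rate in a 100-ms window anchored
#' at each pulse), and forms per-recording second/first ratios. Conditions
#' (first pulse and each lag) are compared with a Friedman test and
#' Dunn-Sidak post hoc contrasts against the first pulse.
#'
#' @param spikes,trials,units Cohort tables (one area's units).
#' @param responsive_ids Character vector of stimulus-responsive unit ids
#'   (from the hand-stimulation analysis).
#' @param params [analysis_params()].
#' @param lags Lags analysed, ms.
#' @return List of class `paired_pulse_result`: `per_recording` (recording,
#'   lag, first/second amplitudes, ratio), `ratio_by_lag` (mean +/- s.d.),
#'   `friedman` (with Dunn-Sidak post hoc), `missing` (recording x lag
#'   combinations without trials, excluded and logged).
#' @export
paired_pulse_analysis <- function(spikes, trials, units, responsive_ids,
                                  params = analysis_params(),
                                  lags = c(150, 250, 350)) {
  pp <- trials[trials$protocol == "paired_pulse", , drop = FALSE]
  if (!nrow(pp)) stop("no paired_pulse trials present")
  recs <- unique(units$recording_id)
  rows <- list(); missing <- list()
  for (rid in recs) {
    uid <- intersect(units$unit_id[units$recording_id == rid], responsive_ids)
    if (!length(uid)) next
    sp <- spikes[spikes$recording_id == rid & spikes$unit_id %in% uid, ]
    for (lag in lags) {
      ev <- pp$event_time_s[pp$recording_id == rid & pp$lag_ms == lag]
      if (!length(ev)) {
        missing[[paste(rid, lag)]] <- data.frame(recording_id = rid, lag_ms = lag)
        next
      }
      mats <- bin_spikes(sp[, c("unit_id", "spike_time_s")], ev, params)
      mats <- c(mats, replicate(length(setdiff(uid, names(mats))),
                                matrix(0L, length(ev), params$n_bins),
                                simplify = FALSE))
      rates <- vapply(mats, function(m) colMeans(m) / (params$bin_ms / 1000),
                      numeric(params$n_bins))
      avg <- rowMeans(rates)
      mu <- mean(avg[params$baseline_bins])
      w1 <- bins_in_window(params$peak_search_ms, params)
      w2 <- bins_in_window(lag + params$peak_search_ms, params)
      a1 <- max(avg[w1] - mu)
      a2 <- max(avg[w2] - mu)
      rows[[paste(rid, lag)]] <- data.frame(
        recording_id = rid, lag_ms = lag, first_amp_hz = a1,
        second_amp_hz = a2, ratio = if (a1 > 0) a2 / a1 else NA_real_)
    }
  }
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ratio_by_lag <- do.call(rbind, lapply(lags, function(l) {
    v <- per$ratio[per$lag_ms == l & is.finite(per$ratio)]
    data.frame(lag_ms = l, ratio_mean = mean(v),
               ratio_sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  }))
  ## Friedman across conditions: first-pulse amplitude (averaged over lag
  ## blocks within recording) plus the second-pulse amplitude at each lag
  wide <- NULL; fried <- NULL
  cmplt <- stats::reshape(per[, c("recording_id", "lag_ms", "second_amp_hz")],
                          idvar = "recording_id", timevar = "lag_ms",
                          direction = "wide")
  first <- tapply(per$first_amp_hz, per$recording_id, mean)
  cmplt$first <- first[cmplt$recording_id]
  cols <- c("first", paste0("second_amp_hz.", lags))
  if (all(cols %in% names(cmplt))) {
    wide <- as.matrix(cmplt[complete.cases(cmplt[cols]), cols])
    colnames(wide) <- c("first", paste0("lag_", lags))
    if (nrow(wide) >= 4) fried <- friedman_dunn_sidak(wide, params$alpha)
  }
  structure(list(per_recording = per, ratio_by_lag = ratio_by_lag,
                 friedman = fried, amplitudes = wide,
                 missing = if (length(missing))
                   do.call(rbind, c(missing, list(make.row.names = FALSE)))
                 else NULL),
            class = "paired_pulse_result")
}

#' Partial-silencing effect on evoked responses
#'
#' For every hand-stimulation-responsive unit, integrates the (by default
#' baseline-subtracted) firing rate over the silencing window (15-50 ms
#' post-stimulus, half-open) under each condition: hand stimulation alone,
#' cortical laser alone, and simultaneous hand + cortex stimulation. Units
#' are grouped into populations (S1 all / S1 PV / S1 non-PV / M1 all); the
#' population value is the mean across units, the silencing ratio is
#' 100 x (hand+cortex)/hand, the within-recording comparison is a Wilcoxon
#' signed rank across units (hand vs hand+cortex), and p-values are BH
#' corrected across recording x population cells.
#'
#' @param spikes,trials,units Cohort tables.
#' @param responsive_ids Hand-stimulation-responsive unit ids.
#' @param tags Optional [classify_pv()] result for the PV/non-PV split.
#' @param params [analysis_params()].
#' @return Data frame of class `silencing_summary`: one row per recording x
#'   population with condition integrals (Hz x ms), `ratio_pct`, `p_value`,
#'   `bh_significant`. Rows with a zero hand-condition integral carry
#'   `ratio_pct = NA`.
#' @export
silencing_effect <- function(spikes, trials, units, responsive_ids,
                             tags = NULL, params = analysis_params()) {
  conds <- list(
    hand = trials[trials$protocol == "hand", , drop = FALSE],
    cortex = trials[trials$protocol == "cortex_laser" &
                      !is.na(trials$intensity_frac) &
                      trials$intensity_frac < 1, , drop = FALSE],
    hand_cortex = trials[trials$protocol == "hand_plus_cortex", , drop = FALSE])
  if (!nrow(conds$hand) || !nrow(conds$hand_cortex))
    stop("silencing analysis requires hand and hand_plus_cortex trials")
  ibins <- bins_in_window(params$silencing_window_ms, params)
  integ <- function(st, ev) {
    if (!length(ev)) return(NA_real_)
    m <- bin_unit(st, ev, params)
    rate <- colMeans(m) / (params$bin_ms / 1000)
    mu <- if (params$silencing_baseline_subtract)
      mean(rate[params$baseline_bins]) else 0
    sum(rate[ibins] - mu) * params$bin_ms
  }
  u <- units[units$unit_id %in% responsive_ids, , drop = FALSE]
  if (!is.null(tags)) u <- merge(u, tags[, c("unit_id", "is_pv")],
                                 by = "unit_id", all.x = TRUE)
  rows <- list()
  for (rid in unique(u$recording_id)) {
    ur <- u[u$recording_id == rid, , drop = FALSE]
    ints <- lapply(names(conds), function(cn) {
      ev <- conds[[cn]]$event_time_s[conds[[cn]]$recording_id == rid]
      vapply(ur$unit_id, function(id)
        integ(spikes$spike_time_s[spikes$unit_id == id], ev), numeric(1))
    })
    names(ints) <- names(conds)
    pops <- list(`S1 all` = ur$area == "S1",
                 `M1 all` = ur$area == "M1")
    if (!is.null(tags) && "is_pv" %in% names(ur)) {
      pops$`S1 PV` <- ur$area == "S1" & ur$is_pv %in% TRUE
      pops$`S1 non-PV` <- ur$area == "S1" & ur$is_pv %in% FALSE
    }
    for (pn in names(pops)) {
      sel <- pops[[pn]]
      if (!any(sel)) next
      h <- mean(ints$hand[sel]); hc <- mean(ints$hand_cortex[sel])
      rows[[paste(rid, pn)]] <- data.frame(
        recording_id = rid, population = pn, n_units = sum(sel),
        int_hand = h, int_cortex = mean(ints$cortex[sel]), int_hand_cortex = hc,
        ratio_pct = if (h > 0) 100 * hc / h else NA_real_,
        p_value = signed_rank_p(ints$hand[sel], ints$hand_cortex[sel]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  bh <- adjust_bh(out$p_value, params$alpha)
  out$p_adjusted <- bh$adjusted
  out$bh_significant <- bh$reject
  class(out) <- c("silencing_summary", "data.frame")
  out
}
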