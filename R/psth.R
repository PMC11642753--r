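#' Bin spikes into trial x bin count matrices
#'
#' Aligns spike times to stimulus events and counts spikes in half-open,
#' left-inclusive bins anchored at stimulus onset: bin b covers
#' `[b*bin_ms, (b+1)*bin_ms)` relative to the event, so a spike exactly at
#' the event time falls in the first post-stimulus bin.
#'
#' @param spikes Either a numeric vector of spike times (s) for one unit, or
#'   a data frame with `unit_id` and `spike_time_s` for many.
#' @param events Numeric vector of stimulus onset times (s), sorted.
#' @param params [analysis_params()].
#' @return For vector input, an integer matrix (trials x bins); for data
#'   frame input, a named list of such matrices (one per unit, in the order
#'   units first appear).
#' @export
bin_spikes <- function(spikes, events, params = analysis_params()) {
  stopifnot(length(events) >= 1)
  events <- as.numeric(events)
  if (is.unsorted(events)) stop("events must be sorted")
  if (length(events) > 1 && min(diff(events)) < diff(params$window_s) - 1e-9)
    stop("analysis windows of consecutive events overlap")
  if (is.data.frame(spikes)) {
    require_columns(spikes, c("unit_id", "spike_time_s"), "spike table")
    ids <- unique(spikes$unit_id)
    out <- lapply(ids, function(id)
      bin_unit(spikes$spike_time_s[spikes$unit_id == id], events, params))
    names(out) <- ids
    return(out)
  }
  bin_unit(as.numeric(spikes), events, params)
}

bin_unit <- function(times, events, params) {
  n_bins <- params$n_bins
  counts <- matrix(0L, nrow = length(events), ncol = n_bins)
  times <- sort(times)
  for (i in seq_along(events)) {
    ## small epsilon guards float error in times computed as event + offset,
    ## preserving the half-open left-inclusive convention at bin edges
    rel_ms <- (times - events[i]) * 1000 + 1e-7
    rel_ms <- rel_ms[rel_ms >= params$window_s[1] * 1000 &
                       rel_ms < params$window_s[2] * 1000]
    if (!length(rel_ms)) next
    b <- bin_index(rel_ms, params)
    tab <- tabulate(b, nbins = n_bins)
    counts[i, ] <- tab
  }
  counts
}

#' Average binned counts into a per-unit PSTH
#'
#' Produces the trial-averaged firing rate in Hz per bin, the across-trial
#' s.d. per bin, baseline statistics over the baseline window (mean and s.d.
#' across the baseline bins of the trial-averaged rate, plus the s.d. of
#' single-trial baseline bin rates used by the responsiveness criterion),
#' and the z-scored rate.
#'
#' @param counts Integer matrix of trial x bin spike counts.
#' @param params [analysis_params()].
#' @param baseline_counts Optional event x bin count matrix from which the
#'   baseline statistics are computed instead (e.g. the pre-stimulus epochs
#'   of every trial in the session, pooled across protocol blocks for a more
#'   precise baseline estimate); defaults to `counts` itself.
#' @return An object of class `unit_psth`.
#' @export
average_psth <- function(counts, params = analysis_params(),
                         baseline_counts = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) >= 1,
            ncol(counts) == params$n_bins)
  if (is.null(baseline_counts)) baseline_counts <- counts
  stopifnot(ncol(baseline_counts) == params$n_bins)
  bin_s <- params$bin_ms / 1000
  rate <- colMeans(counts) / bin_s
  rate_sd <- if (nrow(counts) > 1) apply(counts, 2, sd) / bin_s else rep(0, ncol(counts))
  bb <- params$baseline_bins
  base_rate <- colMeans(baseline_counts[, bb, drop = FALSE]) / bin_s
  base_mean <- mean(base_rate)
  base_sd <- sd(base_rate)
  if (is.na(base_sd)) base_sd <- 0
  single <- as.vector(baseline_counts[, bb, drop = FALSE]) / bin_s
  base_sd_single <- if (length(single) > 1) sd(single) else 0
  z <- if (base_sd > 0) (rate - base_mean) / base_sd else
    ifelse(rate > base_mean, Inf, ifelse(rate < base_mean, -Inf, 0))
  structure(list(counts = counts, trial_count = nrow(counts),
                 rate_hz = rate, rate_sd = rate_sd,
                 baseline_mean_hz = base_mean, baseline_sd_hz = base_sd,
                 baseline_sd_single_hz = base_sd_single,
                 z = z, params = params, responsive = NA),
            class = "unit_psth")
}

#' @export
print.unit_psth <- function(x, ...) {
  cat(sprintf("PSTH: %d trials x %d bins; baseline %.2f +/- %.2f Hz; peak rate %.1f Hz%s\n",
              x$trial_count, length(x$rate_hz), x$baseline_mean_hz,
              x$baseline_sd_hz, max(x$rate_hz),
              if (isTRUE(x$responsive)) "; responsive"
              else if (identical(x$responsive, FALSE)) "; not responsive" else ""))
  invisible(x)
}

#' Classify a unit as stimulus-responsive
#'
#' A unit is stimulus-responsive when the maximum of its z-scored PSTH over
#' the post-stimulus bins exceeds `z_thresh` (strictly). By default the
#' z-score is computed on the square-root-transformed binned counts, whose
#' counting-noise s.d. is known (1/2) and independent of the firing rate, so
#' that the max-over-bins statistic has stable false-positive control and
#' its detection power does not depend on a unit's baseline rate (see the
#' package vignette); alternative s.d. conventions are selectable via
#' `params$detect_sd`. If the baseline is completely silent, a unit with any
#' post-stimulus spike is responsive (its z is marked infinite); a silent
#' unit is not.
#'
#' @param psth A [average_psth()] result.
#' @param params [analysis_params()].
#' @return The `unit_psth` with `$responsive` (logical), `$z_detect` (the z
#'   vector used for detection) and `$max_z` filled in.
#' @export
detect_responsive <- function(psth, params = psth$params) {
  stopifnot(inherits(psth, "unit_psth"))
  rate <- psth$rate_hz
  mu <- psth$baseline_mean_hz
  post <- params$post_bins
  if (params$detect_sd == "sqrt") {
    ctot <- colSums(psth$counts)
    ## expected baseline count per bin at the trial count of this PSTH,
    ## taken from the (possibly pooled) baseline estimate
    cbase <- mu * (params$bin_ms / 1000) * psth$trial_count
    if (cbase > 0) {
      zd <- (sqrt(ctot) - sqrt(cbase)) / 0.5
      resp <- max(zd[post]) > params$z_thresh
    } else {
      zd <- ifelse(ctot > 0, Inf, 0)
      resp <- any(ctot[post] > 0)
    }
  } else {
    sd_scale <- switch(params$detect_sd,
                       single_trial = psth$baseline_sd_single_hz,
                       psth = psth$baseline_sd_hz)
    if (sd_scale > 0) {
      zd <- (rate - mu) / sd_scale
      resp <- max(zd[post]) > params$z_thresh
    } else {
      zd <- ifelse(rate > mu, Inf, ifelse(rate < mu, -Inf, 0))
      resp <- any(rate[post] > 0)
    }
  }
  psth$z_detect <- zd
  psth$max_z <- max(zd[post])
  psth$responsive <- resp
  psth
}

#' Apply the minimum-active-units inclusion rule
#'
#' Probe recordings (one area of one session) with fewer than
#' `min_active_units` active units are excluded from all downstream analyses.
#'
#' @param units Unit metadata data frame with `recording_id` and `area`.
#' @param params [analysis_params()].
#' @return Data frame with one row per probe (`recording_id`, `area`,
#'   `n_units`, `included`); excluded probes carry `included = FALSE`.
#' @export
filter_recordings <- function(units, params = analysis_params()) {
  if (nrow(units) == 0)
    return(data.frame(recording_id = character(0), area = character(0),
                      n_units = integer(0), included = logical(0)))
  tab <- as.data.frame(table(recording_id = units$recording_id,
                             area = units$area), stringsAsFactors = FALSE)
  names(tab)[3] <- "n_units"
  tab <- tab[tab$n_units > 0, , drop = FALSE]
  tab$included <- tab$n_units >= params$min_active_units
  rownames(tab) <- NULL
  tab[order(tab$recording_id, tab$area), , drop = FALSE]
}

#' Two-level (units -> recording -> cohort) grand average of PSTHs
#'
#' Unit PSTHs are first averaged within each recording, and the per-recording
#' averages are then averaged across recordings; the grand s.d. is taken
#' across recordings. With equal unit counts per recording this equals the
#' pooled single-level average.
#'
#' @param psths List of `unit_psth` objects (or numeric rate vectors).
#' @param recording Character vector assigning each element to a recording.
#' @param subset Optional logical vector selecting units (e.g. responsive
#'   only).
#' @return List with `per_recording` (matrix, recordings x bins), `mean`,
#'   `sd` (grand average across recordings), `n_recordings`, `n_units` and
#'   `time_ms` (bin centers).
#' @export
grand_average <- function(psths, recording, subset = NULL) {
  stopifnot(length(psths) == length(recording), length(psths) >= 1)
  rates <- lapply(psths, function(p) if (inherits(p, "unit_psth")) p$rate_hz else as.numeric(p))
  if (!is.null(subset)) {
    rates <- rates[subset]
    recording <- recording[subset]
  }
  if (!length(rates)) stop("no units selected for grand average")
  mat <- do.call(rbind, rates)
  recs <- unique(recording)
  per_rec <- t(vapply(recs, function(r)
    colMeans(mat[recording == r, , drop = FALSE]), numeric(ncol(mat))))
  gm <- colMeans(per_rec)
  gsd <- if (length(recs) > 1) apply(per_rec, 2, sd) else rep(0, ncol(mat))
  params <- if (inherits(psths[[1]], "unit_psth")) psths[[1]]$params else NULL
  time_ms <- if (!is.null(params)) params$bin_left_ms + params$bin_ms / 2 else
    seq_len(ncol(mat))
  list(per_recording = per_rec, mean = gm, sd = gsd,
       n_recordings = length(recs), n_units = nrow(mat), time_ms = time_ms)
}

## scalar analogue of grand_average: unit values -> per-recording means ->
## across-recording mean +/- s.d.
two_level_mean <- function(x, recording) {
  keep <- !is.na(x)
  x <- x[keep]; recording <- recording[keep]
  if (!length(x))
    return(list(mean = NA_real_, sd = NA_real_, per_recording = numeric(0),
                n = 0L))
  per <- tapply(x, recording, mean)
  list(mean = mean(per), sd = if (length(per) > 1) sd(per) else NA_real_,
       per_recording = per, n = length(per))
}
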