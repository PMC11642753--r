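## Area presets for the synthetic cohort generator.
##
## Distribution means equal the published per-area response statistics this
## generator emulates (grand averages across 13 paired recordings): low
## baseline rates, a short-latency peak (earlier and ~3x larger in S1),
## post-peak suppression to <10% of baseline in a minority of responsive
## units, and a rebound at ~280-290 ms. PV-interneuron structure (earlier,
## larger responses; higher responsive fraction) is parameterised by
## conditional multipliers that are renormalised so the PV/non-PV mixture
## reproduces the per-area means.

area_preset_fields <- function() c(
  "area", "baseline_mean_hz", "baseline_sd_hz",
  "responsive_prob", "suppressed_prob", "rebound_prob",
  "onset_mean_ms", "onset_sd_ms", "rise_mean_ms", "rise_sd_ms",
  "dur_mean_ms", "dur_sd_ms", "amp_mean_hz", "amp_sd_hz",
  "supp_frac_mean", "supp_frac_sd",
  "rebound_peak_mean_ms", "rebound_peak_sd_ms",
  "rebound_amp_mean_hz", "rebound_amp_sd_hz",
  "pv_frac", "pv_onset_shift_ms", "pv_amp_mult", "pv_resp_mult",
  "pv_supp_mult", "pv_rebound_mult",
  "depth_amp_peak", "depth_amp_sd", "single_frac",
  "silencing_pv", "silencing_nonpv", "plateau_hz",
  "paired_pulse_recovery")

#' Generator preset for one cortical area
#'
#' Returns the fully populated parameter set used to sample per-unit ground
#' truth for a synthetic recording in one area. The distribution means of the
#' `S1_default` and `M1_default` presets equal the per-area grand averages of
#' the evoked-response statistics the generator emulates (baseline rate
#' 1.2 / 0.6 Hz, onset 14.7 / 24.3 ms, peak 21.4 / 31.2 ms, duration
#' 27.0 / 22.4 ms, amplitude 83.0 / 25.8 Hz, responsive probability
#' 0.367 / 0.256, suppression probability 0.223 / 0.084 with depth 8.2% / 5.6%
#' of baseline, rebound probability 0.309 / 0.081 at 289.0 / 274.7 ms and
#' 31.4 / 20.2 Hz, for S1 / M1 respectively). The laminar amplitude weighting
#' peaks at middle depth for S1 (0.45) and upper depth for M1 (0.25).
#'
#' PV modifiers: PV units respond 5 ms earlier, with 2-fold amplitude, and
#' are about twice as likely to be stimulus-responsive; multipliers are
#' applied conditionally on the PV flag and renormalised so that the mixture
#' means stay at the per-area values above.
#'
#' @param name `"S1_default"` or `"M1_default"`.
#' @param ... Named overrides of any preset field (e.g. `onset_sd_ms = 0` for
#'   degenerate, noise-free ground truth).
#' @return An object of class `area_preset` (a named list).
#' @examples
#' make_preset("S1_default")$onset_mean_ms  # 14.7
#' make_preset("M1_default")$baseline_mean_hz  # 0.6
#' @export
make_preset <- function(name = c("S1_default", "M1_default"), ...) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("S1_default", "M1_default"))
    stop("unknown preset name: ", paste(name, collapse = ", "))
  p <- if (name == "S1_default") list(
    area = "S1",
    baseline_mean_hz = 1.2, baseline_sd_hz = 0.7,
    responsive_prob = 0.367, suppressed_prob = 0.223, rebound_prob = 0.309,
    onset_mean_ms = 14.7, onset_sd_ms = 2.5,
    rise_mean_ms = 6.7, rise_sd_ms = 1.0,
    dur_mean_ms = 27.0, dur_sd_ms = 4.0,
    amp_mean_hz = 83.0, amp_sd_hz = 43.1,
    supp_frac_mean = 0.082, supp_frac_sd = 0.063,
    rebound_peak_mean_ms = 289.0, rebound_peak_sd_ms = 31.9,
    rebound_amp_mean_hz = 31.4, rebound_amp_sd_hz = 13.6,
    pv_frac = 0.468, pv_onset_shift_ms = -5, pv_amp_mult = 2.0,
    pv_resp_mult = 2.058, pv_supp_mult = 1.69, pv_rebound_mult = 1.377,
    depth_amp_peak = 0.45, depth_amp_sd = 0.2, single_frac = 0.30,
    silencing_pv = 0.742, silencing_nonpv = 0.588, plateau_hz = 100,
    paired_pulse_recovery = c("150" = 0.5, "250" = 1.0, "350" = 1.0)
  ) else list(
    area = "M1",
    baseline_mean_hz = 0.6, baseline_sd_hz = 0.2,
    responsive_prob = 0.256, suppressed_prob = 0.084, rebound_prob = 0.081,
    onset_mean_ms = 24.3, onset_sd_ms = 4.3,
    rise_mean_ms = 6.9, rise_sd_ms = 1.0,
    dur_mean_ms = 22.4, dur_sd_ms = 3.2,
    amp_mean_hz = 25.8, amp_sd_hz = 8.9,
    supp_frac_mean = 0.056, supp_frac_sd = 0.075,
    rebound_peak_mean_ms = 274.7, rebound_peak_sd_ms = 36.2,
    rebound_amp_mean_hz = 20.2, rebound_amp_sd_hz = 5.3,
    pv_frac = 0.468, pv_onset_shift_ms = -5, pv_amp_mult = 2.0,
    pv_resp_mult = 2.058, pv_supp_mult = 1.69, pv_rebound_mult = 1.377,
    depth_amp_peak = 0.25, depth_amp_sd = 0.2, single_frac = 0.33,
    silencing_pv = 0.762, silencing_nonpv = 0.762, plateau_hz = 100,
    paired_pulse_recovery = c("150" = 0.5, "250" = 1.0, "350" = 1.0)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), area_preset_fields())
    if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_area_preset(p)
  class(p) <- "area_preset"
  p
}

validate_area_preset <- function(p) {
  probs <- c(p$responsive_prob, p$suppressed_prob, p$rebound_prob,
             p$pv_frac, p$single_frac)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p$baseline_mean_hz >= 0, p$amp_mean_hz >= 0,
            p$supp_frac_mean >= 0, p$supp_frac_mean <= 1,
            p$onset_mean_ms > 0, p$rise_mean_ms > 0,
            p$dur_mean_ms > p$rise_mean_ms,
            p$silencing_pv >= 0, p$silencing_nonpv >= 0,
            p$plateau_hz >= 0,
            all(p$paired_pulse_recovery >= 0))
  invisible(p)
}

#' @export
print.area_preset <- function(x, ...) {
  cat(sprintf("Area preset %s: baseline %.1f Hz, responsive %.1f%%,\n",
              x$area, x$baseline_mean_hz, 100 * x$responsive_prob))
  cat(sprintf("  peak: onset %.1f ms, amplitude %.1f Hz, duration %.1f ms\n",
              x$onset_mean_ms, x$amp_mean_hz, x$dur_mean_ms))
  cat(sprintf("  suppression %.1f%% of units to %.1f%% of baseline; rebound %.1f%% at %.0f ms\n",
              100 * x$suppressed_prob, 100 * x$supp_frac_mean,
              100 * x$rebound_prob, x$rebound_peak_mean_ms))
  invisible(x)
}

#' Stimulation protocol descriptor
#'
#' @param kind Protocol kind: `hand` (5-ms photostimulus to the palm),
#'   `hand_off` (hand off the light-delivery bar; baseline/sham), `paired_pulse`
#'   (two hand stimuli separated by `lag_ms`), `cortex_laser` (20-ms laser
#'   pulse over cortex driving PV interneurons) or `hand_plus_cortex`
#'   (simultaneous hand stimulus and low-intensity cortical silencing).
#' @param n_trials Trials per block (default 25; silencing conditions use 27).
#' @param inter_trial_s Inter-trial period, s.
#' @param pulse_ms Stimulus duration, ms (5 for hand, 20 for cortex laser).
#' @param lag_ms Second-pulse lag for `paired_pulse` (one of 150, 250, 350).
#' @param intensity_frac Laser intensity as a fraction of full (1 for
#'   opto-tagging, 0.25 for silencing).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(kind = c("hand", "hand_off", "paired_pulse",
                                   "cortex_laser", "hand_plus_cortex"),
                          n_trials = NULL, inter_trial_s = 1.0,
                          pulse_ms = NULL, lag_ms = NULL,
                          intensity_frac = 1.0) {
  kind <- match.arg(kind)
  if (is.null(n_trials))
    n_trials <- if (kind == "hand_plus_cortex") 27L else 25L
  if (is.null(pulse_ms))
    pulse_ms <- if (kind %in% c("cortex_laser", "hand_plus_cortex")) 20 else 5
  if (kind == "paired_pulse") {
    if (is.null(lag_ms) || !lag_ms %in% c(150, 250, 350))
      stop("paired_pulse requires lag_ms in {150, 250, 350}")
  } else if (!is.null(lag_ms)) {
    stop("lag_ms is only meaningful for paired_pulse protocols")
  }
  stopifnot(n_trials >= 1, inter_trial_s >= 1.0,
            intensity_frac > 0, intensity_frac <= 1)
  structure(list(kind = kind, n_trials = as.integer(n_trials),
                 inter_trial_s = inter_trial_s, pulse_ms = pulse_ms,
                 lag_ms = lag_ms, intensity_frac = intensity_frac),
            class = "stim_protocol")
}

## the default protocol battery recorded in every synthetic session
default_protocols <- function() list(
  hand        = stim_protocol("hand"),
  hand_off    = stim_protocol("hand_off"),
  paired_150  = stim_protocol("paired_pulse", lag_ms = 150),
  paired_250  = stim_protocol("paired_pulse", lag_ms = 250),
  paired_350  = stim_protocol("paired_pulse", lag_ms = 350),
  laser_tag   = stim_protocol("cortex_laser", intensity_frac = 1.0),
  laser_low   = stim_protocol("cortex_laser", n_trials = 27,
                              intensity_frac = 0.25),
  hand_cortex = stim_protocol("hand_plus_cortex", n_trials = 27,
                              intensity_frac = 0.25)
)
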