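#' Peristimulus firing-rate profile for one unit under one protocol
#'
#' Builds the ground-truth rate function r(t) (Hz, t in ms relative to
#' stimulus onset) from a unit's generative parameters. Responsive units on
#' hand-stimulation trials carry a piecewise-linear peak kernel rising from
#' `onset_ms` to a maximum of `baseline + peak_hz` at `peak_ms` and decaying
#' back to baseline by `onset_ms + dur_ms`. Suppressed units fall to
#' `supp_frac` x baseline during the suppression window; rebound units carry
#' a Gaussian bump (s.d. 40 ms, truncated to the rebound window) peaking at
#' `rebound_peak_ms`. Protocol variants: `hand_off` is baseline everywhere;
#' `paired_pulse` adds a second kernel scaled by the lag-dependent recovery
#' factor; `cortex_laser` drives PV units at a plateau during the 20-ms pulse
#' and scales suppression/rebound by the laser intensity; `hand_plus_cortex`
#' multiplies the hand kernel by the unit's silencing factor.
#'
#' @param unit A one-row data frame (or list) of unit ground truth, as
#'   produced by [simulate_cohort()]'s manifest.
#' @param protocol A [stim_protocol()].
#' @param recovery Named paired-pulse recovery map (lag ms -> amplitude
#'   multiplier for the second pulse).
#' @param supp_window_ms,rebound_window_ms Suppression and rebound windows of
#'   the generative model, ms.
#' @param rebound_sd_ms Width of the rebound bump, ms.
#' @return A vectorised function of peristimulus time in ms, with attributes
#'   `rmax` (finite upper bound on the rate, used by the thinning sampler)
#'   and `protocol`.
#' @examples
#' u <- list(baseline_hz = 1.2, responsive = FALSE, suppressed = FALSE,
#'           rebound = FALSE, is_pv = FALSE, plateau_hz = 0,
#'           silencing_factor = 1)
#' r <- rate_profile(u, stim_protocol("hand"))
#' r(c(-100, 50, 300))  # constant baseline
#' @export
rate_profile <- function(unit, protocol,
                         recovery = c("150" = 0.5, "250" = 1.0, "350" = 1.0),
                         supp_window_ms = c(110, 170),
                         rebound_window_ms = c(190, 400),
                         rebound_sd_ms = 40) {
  stopifnot(inherits(protocol, "stim_protocol"))
  u <- as.list(unit)
  base <- u$baseline_hz
  if (!is.finite(base) || base < 0) stop("baseline rate must be finite and >= 0")
  kind <- protocol$kind
  intensity <- protocol$intensity_frac

  has_kernel <- isTRUE(u$responsive) &&
    kind %in% c("hand", "paired_pulse", "hand_plus_cortex")
  kern_scale <- if (kind == "hand_plus_cortex") u$silencing_factor else 1
  if (has_kernel) {
    onset <- u$onset_ms; peak <- u$peak_ms; dur <- u$dur_ms; amp <- u$peak_hz
    stopifnot(onset < peak, peak < onset + dur, amp >= 0)
  }
  kern <- function(t) {
    up <- (t >= onset) & (t <= peak)
    down <- (t > peak) & (t < onset + dur)
    amp * (up * (t - onset) / (peak - onset) +
             down * (1 - (t - peak) / (onset + dur - peak)))
  }
  second_scale <- 0
  if (kind == "paired_pulse") {
    key <- as.character(protocol$lag_ms)
    if (!key %in% names(recovery)) stop("no recovery factor for lag ", key)
    second_scale <- recovery[[key]]
  }
  mod_scale <- if (kind == "cortex_laser") intensity else 1
  has_supp <- isTRUE(u$suppressed) && kind != "hand_off"
  sf <- if (has_supp) u$supp_frac else NA_real_
  if (has_supp && (!is.finite(sf) || sf < 0 || sf > 1))
    stop("supp_frac must lie in [0, 1]; refusing to clamp a negative rate")
  has_reb <- isTRUE(u$rebound) && kind != "hand_off"
  has_plateau <- kind == "cortex_laser" && isTRUE(u$is_pv) && u$plateau_hz > 0

  r <- function(t) {
    rate <- rep(base, length(t))
    if (has_supp) {
      inw <- t >= supp_window_ms[1] & t < supp_window_ms[2]
      rate[inw] <- rate[inw] - base * mod_scale * (1 - sf)
    }
    if (has_reb) {
      inw <- t >= rebound_window_ms[1] & t < rebound_window_ms[2]
      rate[inw] <- rate[inw] + mod_scale * u$rebound_hz *
        exp(-(t[inw] - u$rebound_peak_ms)^2 / (2 * rebound_sd_ms^2))
    }
    if (has_kernel) {
      rate <- rate + kern_scale * kern(t)
      if (second_scale > 0) rate <- rate + second_scale * kern(t - protocol$lag_ms)
    }
    if (has_plateau) {
      inp <- t >= 0 & t < protocol$pulse_ms
      rate[inp] <- rate[inp] + intensity * u$plateau_hz
    }
    rate
  }
  rmax <- base +
    (if (has_kernel) kern_scale * u$peak_hz + second_scale * u$peak_hz else 0) +
    (if (has_reb) mod_scale * u$rebound_hz else 0) +
    (if (has_plateau) intensity * u$plateau_hz else 0)
  probe <- r(seq(-500, 500, by = 0.5))
  if (any(probe < 0))
    stop("rate profile is negative; mis-specified unit parameters")
  structure(r, rmax = rmax, protocol = protocol)
}
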