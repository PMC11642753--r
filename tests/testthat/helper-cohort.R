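## Shared fixtures. The default 13-recording cohort (seed 1) and its full
## analysis are expensive (~20 s each), so they are built once and cached for
## every test file that needs them.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort))
    .fixture_cache$cohort <- simulate_cohort(seed = 1)
  .fixture_cache$cohort
}

default_analysis <- function() {
  if (is.null(.fixture_cache$analysis))
    .fixture_cache$analysis <- analyze_cohort(default_cohort())
  .fixture_cache$analysis
}

## minimal unit ground-truth stubs for rate-profile construction
baseline_unit <- function(baseline_hz = 1.2, ...) {
  u <- list(baseline_hz = baseline_hz, responsive = FALSE, suppressed = FALSE,
            rebound = FALSE, is_pv = FALSE, plateau_hz = 0,
            silencing_factor = 1)
  u[names(list(...))] <- list(...)
  u
}

responsive_unit <- function(baseline_hz = 1.2, onset_ms = 14.7,
                            peak_ms = 21.4, dur_ms = 27, peak_hz = 83, ...) {
  baseline_unit(baseline_hz, responsive = TRUE, onset_ms = onset_ms,
                peak_ms = peak_ms, dur_ms = dur_ms, peak_hz = peak_hz, ...)
}

## a unit_psth stub with prescribed rate vector and baseline statistics, for
## landmark-extraction tests that specify the PSTH directly
psth_stub <- function(rate_hz, baseline_mean, baseline_sd,
                      params = analysis_params(), counts = NULL) {
  structure(list(counts = counts, trial_count = if (is.null(counts)) 25L else nrow(counts),
                 rate_hz = rate_hz, rate_sd = rep(0, length(rate_hz)),
                 baseline_mean_hz = baseline_mean, baseline_sd_hz = baseline_sd,
                 baseline_sd_single_hz = baseline_sd, z = rate_hz,
                 params = params, responsive = TRUE),
            class = "unit_psth")
}

## closed-form time integral (in expected spikes over the peristimulus
## second) of a generative rate profile, used as the quadrature oracle
profile_integral_oracle <- function(unit, lo_s = -0.5, hi_s = 0.5,
                                    rebound_sd_ms = 40) {
  area <- unit$baseline_hz * (hi_s - lo_s)
  if (isTRUE(unit$responsive))
    area <- area + unit$peak_hz * unit$dur_ms / 2 / 1000
  if (isTRUE(unit$suppressed))
    area <- area - unit$baseline_hz * (1 - unit$supp_frac) * 0.060
  if (isTRUE(unit$rebound)) {
    s <- rebound_sd_ms
    gauss <- unit$rebound_hz * s * sqrt(2 * pi) *
      (pnorm((400 - unit$rebound_peak_ms) / s) -
         pnorm((190 - unit$rebound_peak_ms) / s))
    area <- area + gauss / 1000
  }
  area
}
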