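#' Configuration for one paired S1+M1 synthetic recording
#'
#' @param recording_id Identifier, e.g. `"R01"`.
#' @param s1,m1 [make_preset()] objects for the two probes.
#' @param n_units_per_area Active units per probe (>= 15, the analysis
#'   inclusion rule; default 40, a typical yield for a 64-channel probe).
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(recording_id, s1 = make_preset("S1_default"),
                             m1 = make_preset("M1_default"),
                             n_units_per_area = 40) {
  stopifnot(inherits(s1, "area_preset"), inherits(m1, "area_preset"),
            n_units_per_area >= 15)
  structure(list(recording_id = recording_id, s1 = s1, m1 = m1,
                 n_units_per_area = as.integer(n_units_per_area)),
            class = "recording_config")
}

## nominal stereotaxic probe targets (mm, AP / ML) for forelimb S1 and M1
.s1_target <- c(ap = 0.00, ml = 2.40)
.m1_target <- c(ap = 0.25, ml = 1.35)

## per-recording event schedule: one block per protocol, 1-s trial spacing,
## 2-s gaps between blocks, first event late enough that the full
## peristimulus window has non-negative absolute times
schedule_events <- function(protocols) {
  out <- list()
  t0 <- 0.5
  for (nm in names(protocols)) {
    pr <- protocols[[nm]]
    ev <- t0 + (seq_len(pr$n_trials) - 1) * pr$inter_trial_s
    out[[nm]] <- data.frame(
      block = nm, event_time_s = ev, protocol = pr$kind,
      lag_ms = if (is.null(pr$lag_ms)) NA_real_ else pr$lag_ms,
      hand_on = pr$kind %in% c("hand", "paired_pulse", "hand_plus_cortex"),
      intensity_frac = if (pr$kind %in% c("cortex_laser", "hand_plus_cortex"))
        pr$intensity_frac else NA_real_,
      stringsAsFactors = FALSE)
    t0 <- max(ev) + pr$inter_trial_s + 2
  }
  do.call(rbind, out)
}

#' Simulate a multi-recording synthetic cohort
#'
#' Generates paired S1+M1 recordings: per-unit ground truth sampled from the
#' area presets, spike trains sampled by thinning from the implied rate
#' profiles under every protocol block, per-recording probe coordinates, and
#' a manifest retaining all ground truth for parameter-recovery testing.
#' A master seed spawns independent per-recording / per-unit / per-block
#' streams, so regeneration is bit-identical and enlarging a cohort does not
#' perturb existing units.
#'
#' @param configs List of [recording_config()] objects, or `NULL` to build
#'   `n_recordings` default S1+M1 recordings.
#' @param seed Master integer seed.
#' @param n_recordings Number of paired recordings when `configs` is `NULL`
#'   (default 13, the cohort size the generator emulates).
#' @param n_units_per_area Units per probe for default configs.
#' @param s1,m1 Default area presets.
#' @param protocols Named list of [stim_protocol()] blocks recorded in each
#'   session (default: hand, hand-off, three paired-pulse lags, full-intensity
#'   cortical laser for opto-tagging, low-intensity laser, and simultaneous
#'   hand + cortex silencing).
#' @return An object of class `cohort`: list with `spikes` (recording_id,
#'   unit_id, spike_time_s), `units` (public metadata incl. the true PV
#'   label), `trials` (event table), and `manifest` (configs, full unit
#'   ground truth, probe geometry, seed).
#' @examples
#' co <- simulate_cohort(n_recordings = 1, n_units_per_area = 15, seed = 1,
#'                       protocols = list(hand = stim_protocol("hand")))
#' head(co$spikes)
#' @export
simulate_cohort <- function(configs = NULL, seed = 1, n_recordings = 13,
                            n_units_per_area = 40,
                            s1 = make_preset("S1_default"),
                            m1 = make_preset("M1_default"),
                            protocols = default_protocols()) {
  if (is.null(configs)) {
    configs <- lapply(seq_len(n_recordings), function(i)
      recording_config(sprintf("R%02d", i), s1 = s1, m1 = m1,
                       n_units_per_area = n_units_per_area))
  }
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, TRUE, "recording_config")))
  events <- schedule_events(protocols)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  truth <- list(); spikes <- list(); trials <- list(); geom <- list()
  for (ri in seq_along(configs)) {
    cfg <- configs[[ri]]
    rid <- cfg$recording_id
    ## probe geometry: S1 fixed at target, M1 displaced along the nominal
    ## S1->M1 axis by a distance ~ N(0.92, 0.12) mm
    set.seed(mix_seed(seed, ri, 7))
    d <- rtnorm(1, 0.92, 0.12, lower = 0.3)
    axis <- (.m1_target - .s1_target) / sqrt(sum((.m1_target - .s1_target)^2))
    m1_xy <- .s1_target + d * axis
    geom[[rid]] <- data.frame(recording_id = rid,
                              s1_ap = .s1_target["ap"], s1_ml = .s1_target["ml"],
                              m1_ap = m1_xy["ap"], m1_ml = m1_xy["ml"],
                              s1_m1_mm = d, row.names = NULL)
    for (ai in 1:2) {
      preset <- if (ai == 1) cfg$s1 else cfg$m1
      ## one truth stream per unit: enlarging a cohort never perturbs the
      ## ground truth (or spikes) of units that were already there
      gt <- do.call(rbind, lapply(seq_len(cfg$n_units_per_area), function(ui) {
        set.seed(mix_seed(seed, ri, ai, ui, 9))
        sample_unit_truth(preset, 1L, rid, first_index = ui)
      }))
      truth[[paste(rid, ai)]] <- gt
      for (ui in seq_len(nrow(gt))) {
        unit <- gt[ui, ]
        for (bi in seq_along(protocols)) {
          pr <- protocols[[bi]]
          r <- rate_profile(unit, pr, recovery = preset$paired_pulse_recovery)
          sp <- sample_spikes(r, pr, seed = mix_seed(seed, ri, ai, ui, bi))
          if (nrow(sp) == 0) next
          ev <- events$event_time_s[events$block == names(protocols)[bi]]
          spikes[[length(spikes) + 1L]] <- data.frame(
            recording_id = rid, unit_id = unit$unit_id,
            spike_time_s = ev[sp$trial] + sp$time_s)
        }
      }
    }
    trials[[rid]] <- cbind(recording_id = rid, events, row.names = NULL)
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  spikes <- do.call(rbind, c(spikes, list(make.row.names = FALSE)))
  spikes <- spikes[order(spikes$recording_id, spikes$unit_id,
                         spikes$spike_time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  trials <- do.call(rbind, c(trials, list(make.row.names = FALSE)))
  units <- truth[, c("recording_id", "unit_id", "area", "depth_frac",
                     "is_single", "is_pv")]
  names(units)[names(units) == "is_pv"] <- "is_pv_true"
  structure(list(
    spikes = spikes, units = units,
    trials = trials[, c("recording_id", "event_time_s", "protocol", "lag_ms",
                        "hand_on", "intensity_frac", "block")],
    manifest = list(seed = seed,
                    n_recordings = length(configs),
                    recordings = vapply(configs, `[[`, "", "recording_id"),
                    n_units_per_area = vapply(configs, `[[`, 1L, "n_units_per_area"),
                    presets = list(s1 = unclass(configs[[1]]$s1),
                                   m1 = unclass(configs[[1]]$m1)),
                    ground_truth = truth,
                    probe_geometry = do.call(rbind, c(geom, list(make.row.names = FALSE))))),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d recording(s), %d units, %d spikes, %d trials\n",
              length(unique(x$units$recording_id)), nrow(x$units),
              nrow(x$spikes), nrow(x$trials)))
  invisible(x)
}
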