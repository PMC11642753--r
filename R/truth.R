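## Per-unit ground-truth sampling for the synthetic cohort.

## deterministic seed derivation: a master seed spawns independent
## per-recording / per-unit / per-block streams, so enlarging a cohort never
## perturbs the spikes of units that were already there.
mix_seed <- function(...) {
  m <- 2147483647
  s <- 104729
  for (v in c(...)) s <- (s * 69069 + (as.numeric(v) %% m)) %% m
  as.integer(s)
}

## truncated-normal sampler; degenerates to the (clipped) mean when sd = 0
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (sd <= 0) return(pmin(pmax(mean, lower), upper))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

## log-normal parameterised by arithmetic mean and s.d.
rlnorm_ms <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- pmax(mean, 0)
  ok <- sd > 0 & mean > 0
  if (any(ok)) {
    cv2 <- (sd[ok] / mean[ok])^2
    sdlog <- sqrt(log(1 + cv2))
    out[ok] <- rlnorm(sum(ok), log(mean[ok]) - sdlog^2 / 2, sdlog)
  }
  out
}

## laminar amplitude weight: Gaussian bump in normalised depth, rescaled to
## mean 1 over depth ~ U(0, 1) so that the area's mean amplitude is preserved
depth_weight <- function(depth_frac, peak, sd) {
  if (!is.finite(sd)) return(rep(1, length(depth_frac)))
  w <- exp(-(depth_frac - peak)^2 / (2 * sd^2))
  norm <- sd * sqrt(2 * pi) * (pnorm((1 - peak) / sd) - pnorm(-peak / sd))
  w / norm
}

## PV-conditional parameters, renormalised so the PV/non-PV mixture mean
## equals the preset mean. `w_resp_pv` is the expected share of responsive
## units that are PV.
pv_mixture <- function(p) {
  f <- p$pv_frac
  p_np <- p$responsive_prob / (f * p$pv_resp_mult + (1 - f))
  p_pv <- min(1, p_np * p$pv_resp_mult)
  resp <- f * p_pv + (1 - f) * p_np
  w <- if (resp > 0) f * p_pv / resp else 0
  amp_np <- p$amp_mean_hz / (w * p$pv_amp_mult + (1 - w))
  onset_np <- p$onset_mean_ms - p$pv_onset_shift_ms * w
  supp_np <- p$suppressed_prob / (w * p$pv_supp_mult + (1 - w))
  reb_np <- p$rebound_prob / (w * p$pv_rebound_mult + (1 - w))
  list(p_resp_np = p_np, p_resp_pv = p_pv, w_resp_pv = w,
       amp_np = amp_np, amp_pv = amp_np * p$pv_amp_mult,
       onset_np = onset_np, onset_pv = onset_np + p$pv_onset_shift_ms,
       supp_np = supp_np, supp_pv = min(1, supp_np * p$pv_supp_mult),
       reb_np = reb_np, reb_pv = min(1, reb_np * p$pv_rebound_mult))
}

## draw ground truth for `n` units of one area; caller owns the RNG state.
## `first_index` offsets unit numbering so cohorts can be drawn unit-by-unit
## from independent streams.
sample_unit_truth <- function(preset, n, recording_id, first_index = 1L) {
  p <- preset
  mx <- pv_mixture(p)
  is_pv <- runif(n) < p$pv_frac
  is_single <- runif(n) < p$single_frac
  depth <- runif(n)
  dw <- depth_weight(depth, p$depth_amp_peak, p$depth_amp_sd)
  baseline <- rlnorm_ms(n, p$baseline_mean_hz, p$baseline_sd_hz)
  responsive <- runif(n) < ifelse(is_pv, mx$p_resp_pv, mx$p_resp_np)
  onset <- rtnorm(n, ifelse(is_pv, mx$onset_pv, mx$onset_np),
                  p$onset_sd_ms, lower = 1)
  rise <- rtnorm(n, p$rise_mean_ms, p$rise_sd_ms, lower = 2)
  dur <- pmax(rtnorm(n, p$dur_mean_ms, p$dur_sd_ms, lower = 5), rise + 3)
  amp <- rlnorm_ms(n, ifelse(is_pv, mx$amp_pv, mx$amp_np), p$amp_sd_hz *
                     (ifelse(is_pv, mx$amp_pv, mx$amp_np) / p$amp_mean_hz)) * dw
  suppressed <- responsive & (runif(n) < ifelse(is_pv, mx$supp_pv, mx$supp_np))
  supp_frac <- rtnorm(n, p$supp_frac_mean, p$supp_frac_sd, 0, 1)
  rebound <- responsive & (runif(n) < ifelse(is_pv, mx$reb_pv, mx$reb_np))
  reb_peak <- rtnorm(n, p$rebound_peak_mean_ms, p$rebound_peak_sd_ms, 200, 390)
  reb_amp <- rlnorm_ms(n, p$rebound_amp_mean_hz, p$rebound_amp_sd_hz) * dw
  data.frame(
    recording_id = recording_id,
    unit_id = sprintf("%s_%s_u%02d", recording_id, p$area,
                      first_index + seq_len(n) - 1L),
    area = p$area, depth_frac = depth, is_single = is_single, is_pv = is_pv,
    baseline_hz = baseline, responsive = responsive,
    onset_ms = ifelse(responsive, onset, NA_real_),
    peak_ms = ifelse(responsive, onset + rise, NA_real_),
    dur_ms = ifelse(responsive, dur, NA_real_),
    peak_hz = ifelse(responsive, amp, NA_real_),
    suppressed = suppressed,
    supp_frac = ifelse(suppressed, supp_frac, NA_real_),
    rebound = rebound,
    rebound_peak_ms = ifelse(rebound, reb_peak, NA_real_),
    rebound_hz = ifelse(rebound, reb_amp, NA_real_),
    silencing_factor = ifelse(is_pv, p$silencing_pv, p$silencing_nonpv),
    plateau_hz = ifelse(is_pv, p$plateau_hz, 0),
    stringsAsFactors = FALSE)
}
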