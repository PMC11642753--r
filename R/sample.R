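#' Sample spike times from a rate profile (inhomogeneous Poisson, thinning)
#'
#' Lewis-Shedler thinning: candidate events are drawn from a homogeneous
#' Poisson process at the profile's rate bound `rmax` and accepted with
#' probability r(t)/rmax, independently per trial. Identical
#' (rate, protocol, seed) triples give identical spikes.
#'
#' @param rate A rate function of peristimulus time in ms, Hz, with an `rmax`
#'   attribute (as returned by [rate_profile()]); any finite, non-negative
#'   vectorised function with an `rmax` bound is accepted.
#' @param protocol A [stim_protocol()]; supplies the trial count.
#' @param seed Integer seed for this unit/block stream.
#' @param window_s Peristimulus window simulated per trial, s.
#' @return A data frame with columns `trial` (1-based) and `time_s`
#'   (peristimulus, seconds), sorted within trial.
#' @examples
#' u <- list(baseline_hz = 2, responsive = FALSE, suppressed = FALSE,
#'           rebound = FALSE, is_pv = FALSE, plateau_hz = 0,
#'           silencing_factor = 1)
#' sp <- sample_spikes(rate_profile(u, stim_protocol("hand")),
#'                     stim_protocol("hand"), seed = 1)
#' nrow(sp) / 25  # about 2 spikes per 1-s trial
#' @export
sample_spikes <- function(rate, protocol, seed, window_s = c(-0.5, 0.5)) {
  stopifnot(inherits(protocol, "stim_protocol"), is.function(rate))
  rmax <- attr(rate, "rmax")
  if (is.null(rmax) || !is.finite(rmax) || rmax < 0)
    stop("rate function must carry a finite, non-negative rmax bound")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_trials <- protocol$n_trials
  span <- diff(window_s)
  if (rmax == 0)
    return(data.frame(trial = integer(0), time_s = numeric(0)))
  n_cand <- rpois(n_trials, rmax * span)
  trial <- rep.int(seq_len(n_trials), n_cand)
  t_s <- runif(sum(n_cand), window_s[1], window_s[2])
  keep <- runif(length(t_s)) * rmax < rate(t_s * 1000)
  out <- data.frame(trial = trial[keep], time_s = t_s[keep])
  out[order(out$trial, out$time_s), , drop = FALSE]
}
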