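test_that("propagation speeds are mean-of-ratios with printed-value arithmetic", {
  ## printed morphometry: 44.3 mm / 14.7 ms and 44.3 / 21.4
  one <- propagation_speeds(data.frame(recording_id = "R", s1_ms = 14.7))
  expect_equal(round(one$hand_s1_m_per_s[["mean"]], 1), 3.0)
  pk <- propagation_speeds(data.frame(recording_id = "R", s1_ms = 21.4))
  expect_equal(round(pk$hand_s1_m_per_s[["mean"]], 1), 2.1)
  ## 1 mm / 1 ms = 1 m/s
  unit <- propagation_speeds(data.frame(recording_id = "R", s1_ms = 1, m1_ms = 2),
                             geometry = data.frame(recording_id = "R", s1_m1_mm = 1))
  expect_equal(unit$s1_m1_m_per_s[["mean"]], 1)
  ## mean of ratios, not ratio of means
  lat <- data.frame(recording_id = c("A", "B", "C"), s1_ms = c(5, 10, 20))
  sp <- propagation_speeds(lat, hand_to_s1_mm = 1)
  expect_equal(sp$hand_s1_m_per_s[["mean"]], mean(c(0.2, 0.1, 0.05)))
  expect_false(isTRUE(all.equal(sp$hand_s1_m_per_s[["mean"]], 3 / 35)))
  ## homogeneity: doubling all distances doubles every speed
  sp2 <- propagation_speeds(lat, hand_to_s1_mm = 2)
  expect_equal(sp2$per_recording$hand_s1_m_per_s,
               2 * sp$per_recording$hand_s1_m_per_s)
  ## non-positive latency differences are excluded and logged
  bad <- propagation_speeds(
    data.frame(recording_id = c("A", "B"), s1_ms = c(10, 10), m1_ms = c(20, 8)),
    geometry = data.frame(recording_id = c("A", "B"), s1_m1_mm = c(1, 1)))
  expect_equal(bad$excluded, "B")
  expect_equal(bad$s1_m1_m_per_s[["mean"]], 0.1)
  expect_error(propagation_speeds(data.frame(recording_id = "R", s1_ms = -1)),
               "positive")
})

test_that("Friedman statistic agrees with the closed-form rank formula", {
  set.seed(70)
  mat <- cbind(first = c(10, 12, 11, 13), lag_150 = c(5, 6, 5.5, 6.5),
               lag_250 = c(9, 11, 10, 12), lag_350 = c(9.8, 12.2, 10.7, 12.7))
  fr <- triphasic:::friedman_dunn_sidak(mat)
  ## oracle: chi2 = 12 / (n k (k+1)) * sum Rj^2 - 3 n (k+1) on column rank sums
  ranks <- t(apply(mat, 1, rank))
  rj <- colSums(ranks)
  n <- nrow(mat); k <- ncol(mat)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  expect_equal(fr$chisq, chi2)
  expect_equal(fr$df, k - 1)
  ## post hoc: the suppressed-lag condition differs from the first pulse
  expect_true(fr$posthoc$significant[fr$posthoc$condition == "lag_150"])
  ## Sidak adjustment is monotone in the raw p
  expect_true(all(fr$posthoc$p_sidak >= fr$posthoc$p_raw))
})

## deterministic spike table: every trial of every condition carries the same
## peristimulus pattern, so condition ratios are exact
deterministic_silencing_tables <- function(scale_hand_cortex = 1) {
  trials <- rbind(
    data.frame(recording_id = "R01", event_time_s = 10 + 0:9, protocol = "hand",
               lag_ms = NA, hand_on = TRUE, intensity_frac = NA),
    data.frame(recording_id = "R01", event_time_s = 40 + 0:9,
               protocol = "cortex_laser", lag_ms = NA, hand_on = FALSE,
               intensity_frac = 0.25),
    data.frame(recording_id = "R01", event_time_s = 70 + 0:9,
               protocol = "hand_plus_cortex", lag_ms = NA, hand_on = TRUE,
               intensity_frac = 0.25))
  units <- data.frame(recording_id = "R01", unit_id = c("u1", "u2"),
                      area = c("S1", "M1"), depth_frac = c(0.4, 0.3),
                      is_single = TRUE)
  ## 3 spikes at +20,25,30 ms per hand trial; scaled count on hand+cortex
  mk <- function(ev, n_spk) {
    do.call(rbind, lapply(ev, function(e)
      data.frame(spike_time_s = e + 0.020 + 0.005 * seq_len(n_spk) - 0.005)))
  }
  spikes <- do.call(rbind, lapply(c("u1", "u2"), function(id) {
    h <- mk(trials$event_time_s[trials$protocol == "hand"], 4)
    hc <- mk(trials$event_time_s[trials$protocol == "hand_plus_cortex"],
             4 * scale_hand_cortex)
    cbind(recording_id = "R01", unit_id = id, rbind(h, hc))
  }))
  list(spikes = spikes, trials = trials, units = units)
}

test_that("identical hand and hand+cortex responses give a 100% silencing ratio", {
  tb <- deterministic_silencing_tables(1)
  s <- silencing_effect(tb$spikes, tb$trials, tb$units,
                        responsive_ids = c("u1", "u2"))
  expect_equal(s$ratio_pct, rep(100, nrow(s)))
  ## halving the paired-condition response gives 50%
  tb2 <- deterministic_silencing_tables(0.5)
  s2 <- silencing_effect(tb2$spikes, tb2$trials, tb2$units,
                         responsive_ids = c("u1", "u2"))
  expect_equal(s2$ratio_pct, rep(50, nrow(s2)))
})

test_that("silencing-factor recovery on the default cohort lands near the generative factors", {
  an <- default_analysis()
  sil <- an$silencing
  target <- c(`S1 PV` = 74.2, `S1 non-PV` = 58.8, `M1 all` = 76.2)
  for (pop in names(target)) {
    got <- mean(sil$ratio_pct[sil$population == pop], na.rm = TRUE)
    expect_lt(abs(got - target[[pop]]), 8)
  }
})

test_that("paired-pulse analysis with a flat recovery map gives unit ratios", {
  s1 <- make_preset("S1_default",
                    paired_pulse_recovery = c("150" = 1, "250" = 1, "350" = 1),
                    suppressed_prob = 0, rebound_prob = 0)
  co <- simulate_cohort(
    lapply(1:4, function(i) recording_config(sprintf("R%02d", i), s1 = s1,
                                             n_units_per_area = 20)),
    seed = 12,
    protocols = list(hand = stim_protocol("hand"),
                     p150 = stim_protocol("paired_pulse", lag_ms = 150),
                     p250 = stim_protocol("paired_pulse", lag_ms = 250),
                     p350 = stim_protocol("paired_pulse", lag_ms = 350)))
  an <- analyze_cohort(co)
  pp <- an$paired_pulse$S1
  expect_true(all(abs(pp$ratio_by_lag$ratio_mean - 1) < 0.15))
  expect_true(all(!is.na(pp$per_recording$ratio)))
})
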