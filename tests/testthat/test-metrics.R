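params <- analysis_params()

## rate vector with prescribed post-stimulus values (Hz), flat elsewhere
post_rates <- function(post, base = 1) {
  r <- rep(base, params$n_bins)
  r[100 + seq_along(post)] <- post
  r
}

test_that("peak metrics match hand-worked bin arithmetic", {
  ## baseline 1 +/- 2 Hz; post rates 1,1,9,30,9,2,1,...
  p <- psth_stub(post_rates(c(1, 1, 9, 30, 9, 2)), 1, 2, params)
  pk <- peak_metrics(p, params)
  expect_true(pk$found)
  expect_equal(pk$peak_amp_hz, 29)          # 30 - baseline
  expect_equal(pk$peak_ms, 17.5)            # center of 4th post bin
  expect_equal(pk$onset_ms, 10)             # left edge of first bin > 1 + 2.5*2
  expect_equal(pk$duration_ms, 15)          # falls below 1 + 1*2 at bin [25,30)
})

test_that("a single bin exactly at threshold is not an onset (strict inequality)", {
  p <- psth_stub(post_rates(c(1, 1, 6, 1)), 1, 2, params)  # 6 == 1 + 2.5*2
  pk <- peak_metrics(p, params)
  expect_false(pk$found)
  expect_true(is.na(pk$onset_ms))
})

test_that("isolated pre-response noise bins do not drag the onset early", {
  ## a lone 7-Hz noise bin at 0-5 ms, true response at 30-45 ms
  p <- psth_stub(post_rates(c(7, 1, 1, 1, 1, 1, 20, 30, 20, 1)), 1, 2, params)
  pk <- peak_metrics(p, params)
  expect_equal(pk$onset_ms, 30)
})

test_that("suppression requires consistent paired per-trial evidence", {
  ## identical window and baseline on every trial: not suppressed
  flat <- matrix(1L, 25, params$n_bins)
  p <- average_psth(flat, params)
  s <- suppression_test(p, params)
  expect_false(s$is_suppressed)
  ## ~8 Hz baseline, silent suppression window, 25 trials
  counts <- matrix(0L, 25, params$n_bins)
  counts[, params$baseline_bins[seq(1, 50, 2)]] <- 1L   # 25 baseline spikes/trial
  counts[, 101:110] <- 1L                               # a response, outside 110-170
  p2 <- average_psth(counts, params)
  s2 <- suppression_test(p2, params)
  expect_true(s2$is_suppressed)
  expect_equal(s2$supp_pct_baseline, 0)
  expect_lt(s2$p_value, 0.05)
  ## oracle: 25 equal positive differences, exact signed-rank p
  d <- rep(1, 25)
  expect_lt(suppressWarnings(wilcox.test(d)$p.value), 0.05)
})

test_that("rebound is located and tested against per-trial baselines", {
  flat <- average_psth(matrix(1L, 25, params$n_bins), params)
  expect_false(rebound_test(flat, params)$has_rebound)
  ## 4 spikes/trial in the bin covering 285-290 ms over an 8-Hz baseline
  counts <- matrix(0L, 25, params$n_bins)
  counts[, params$baseline_bins[c(10, 30)]] <- 1L
  bin290 <- which(params$bin_left_ms == 285)
  counts[, bin290] <- 4L
  rb <- rebound_test(average_psth(counts, params), params)
  expect_true(rb$has_rebound)
  expect_equal(rb$rebound_latency_ms, 287.5)
  expect_lt(rb$p_value, 0.05)
  expect_gt(rb$rebound_amp_hz, 0)
})

make_metrics <- function(onsets_s1, onsets_m1, recs = paste0("R", seq_along(onsets_s1))) {
  rbind(
    data.frame(recording_id = recs, unit_id = paste0(recs, "s"), area = "S1",
               responsive = TRUE, baseline_hz = 1, onset_ms = onsets_s1,
               peak_ms = onsets_s1 + 7, duration_ms = 25, amplitude_hz = 80,
               is_suppressed = FALSE, supp_rate_hz = NA, supp_pct_baseline = NA,
               has_rebound = FALSE, rebound_latency_ms = NA, rebound_amp_hz = NA),
    data.frame(recording_id = recs, unit_id = paste0(recs, "m"), area = "M1",
               responsive = TRUE, baseline_hz = 0.5, onset_ms = onsets_m1,
               peak_ms = onsets_m1 + 7, duration_ms = 20, amplitude_hz = 25,
               is_suppressed = FALSE, supp_rate_hz = NA, supp_pct_baseline = NA,
               has_rebound = FALSE, rebound_latency_ms = NA, rebound_amp_hz = NA))
}

test_that("summaries pool units to recordings, then recordings to the cohort", {
  m <- make_metrics(c(10, 20), c(10, 20))
  s <- summarize_responses(m, params)
  onset <- s[s$parameter == "Onset latency (ms)", ]
  expect_equal(onset$s1_mean, 15)
  expect_equal(onset$s1_sd, sd(c(10, 20)))
  expect_equal(onset$diff_mean, 0)
  ## identical areas across >= 6 recordings: difference 0, p = 1
  m6 <- make_metrics(10 + 1:6, 10 + 1:6)
  s6 <- summarize_responses(m6, params)
  on6 <- s6[s6$parameter == "Onset latency (ms)", ]
  expect_equal(on6$diff_mean, 0)
  expect_equal(on6$p_value, 1)
})

test_that("summaries are invariant to unit and recording order", {
  m <- make_metrics(c(12, 18, 15, 11, 19, 14), c(22, 28, 25, 21, 29, 24))
  s1 <- summarize_responses(m, params)
  set.seed(44)
  s2 <- summarize_responses(m[sample(nrow(m)), ], params)
  expect_equal(s1, s2)
})

test_that("Spearman correlations and their t-transform p-values are exact", {
  rec <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5), z = -(1:5), w = rep(1, 5))
  cc <- correlate_properties(rec)
  expect_equal(cc$rho["x", "z"], -1)
  expect_equal(cc$rho["x", "x"], 1)
  expect_equal(cc$rho["x", "y"], 0.8)   # 1 - 6*4/(5*24)
  tv <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(cc$p["x", "y"], 2 * pt(-tv, df = 3))
  expect_true(is.na(cc$rho["x", "w"]))  # constant vector flagged undefined
  expect_error(correlate_properties(rec[1:3, ]), "4 recordings")
})

test_that("Benjamini-Hochberg step-up matches the hand-worked rule", {
  r <- adjust_bh(c(0.01, 0.02, 0.03, 0.9))
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$adjusted[1:3], rep(0.04, 3))
  one <- adjust_bh(0.03)
  expect_true(one$reject)
  expect_equal(one$adjusted, 0.03)
  expect_false(any(adjust_bh(rep(1, 5))$reject))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("peak extraction recovers piecewise-linear kernel landmarks in the noise-free limit", {
  ## direct rate input: bin-average the kernel exactly
  u <- responsive_unit(onset_ms = 15, peak_ms = 22.5, dur_ms = 30, peak_hz = 80)
  r <- rate_profile(u, stim_protocol("hand"))
  centers <- params$bin_left_ms + params$bin_ms / 2
  rate <- vapply(seq_along(centers), function(b)
    integrate(function(t) r(t), params$bin_left_ms[b],
              params$bin_left_ms[b] + params$bin_ms)$value / params$bin_ms,
    numeric(1))
  p <- psth_stub(rate, 1.2, 0.5, params)
  pk <- peak_metrics(p, params)
  expect_equal(pk$onset_ms, 15)        # threshold crossed inside [15, 20)
  expect_equal(pk$peak_ms, 22.5)
  expect_equal(pk$peak_amp_hz, max(rate) - 1.2)
  ## duration: first whole bin below baseline + 0.5 Hz is [45, 50)
  expect_equal(pk$duration_ms, 45 - 15, tolerance = 1e-6)
  ## monotonicity: doubling the amplitude cannot decrease extracted amplitude
  u2 <- responsive_unit(onset_ms = 15, peak_ms = 22.5, dur_ms = 30, peak_hz = 160)
  r2 <- rate_profile(u2, stim_protocol("hand"))
  rate2 <- vapply(seq_along(centers), function(b)
    integrate(function(t) r2(t), params$bin_left_ms[b],
              params$bin_left_ms[b] + params$bin_ms)$value / params$bin_ms,
    numeric(1))
  pk2 <- peak_metrics(psth_stub(rate2, 1.2, 0.5, params), params)
  expect_gt(pk2$peak_amp_hz, pk$peak_amp_hz)
})
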