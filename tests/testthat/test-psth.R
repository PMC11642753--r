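params <- analysis_params()

test_that("binning follows the half-open, left-inclusive, onset-anchored convention", {
  ev <- 10
  expect_counts_at <- function(spike_s, bin) {
    m <- bin_spikes(spike_s, ev, params)
    expect_equal(sum(m), 1)
    expect_equal(which(m[1, ] == 1), bin)
  }
  expect_counts_at(10.002, 101)       # +2 ms -> first post-stimulus bin
  expect_counts_at(10.005, 102)       # exactly +5 ms -> bin 1, not bin 0
  expect_counts_at(10.000, 101)       # spike at the event time
  expect_counts_at(10 - 0.5, 1)       # window start included
  expect_counts_at(10.499, 200)
  m <- bin_spikes(10.5, ev, params)   # window end excluded
  expect_equal(sum(m), 0)
})

test_that("binned counts conserve the number of in-window spikes", {
  set.seed(40)
  ev <- c(5, 7, 9, 11)
  spikes <- runif(400, 0, 16)
  m <- bin_spikes(spikes, ev, params)
  in_window <- sum(vapply(ev, function(e)
    sum(spikes >= e - 0.5 & spikes < e + 0.5), numeric(1)))
  expect_equal(sum(m), in_window)
  expect_error(bin_spikes(spikes, c(5, 5.3), params), "overlap")
})

test_that("PSTH averaging has the right scale and baseline statistics", {
  ones <- matrix(1L, 10, params$n_bins)
  p <- average_psth(ones, params)
  expect_true(all(p$rate_hz == 200))
  expect_equal(p$baseline_mean_hz, 200)
  expect_equal(p$baseline_sd_hz, 0)
  z <- average_psth(matrix(0L, 5, params$n_bins), params)
  expect_true(all(z$rate_hz == 0))
  expect_equal(z$baseline_mean_hz, 0)
})

test_that("a generated unit's baseline is recovered within 3 s.e.", {
  u <- baseline_unit(1.2)
  pr <- stim_protocol("hand", n_trials = 400)
  sp <- sample_spikes(rate_profile(u, pr), pr, seed = 17)
  ev <- seq_len(400) * 1.0 + 10
  m <- bin_spikes(sp$time_s + ev[sp$trial], ev, params)
  p <- average_psth(m, params)
  se <- sqrt(1.2 / (400 * 0.25))
  expect_lt(abs(p$baseline_mean_hz - 1.2), 3 * se)
})

test_that("responsiveness detection matches hand-computed z-scores", {
  flat <- detect_responsive(average_psth(matrix(1L, 5, params$n_bins), params))
  expect_false(flat$responsive)
  ## alternating 0/2-count baseline, one 10-count post bin, one trial
  counts <- matrix(0L, 1, params$n_bins)
  counts[1, params$baseline_bins] <- rep(c(0L, 2L), 25)
  counts[1, 120] <- 10L
  p <- detect_responsive(average_psth(counts, params))
  expect_true(p$responsive)
  expect_equal(p$max_z, (sqrt(10) - 1) / 0.5)   # sqrt-stabilised z
  ## zero-baseline policies
  silent_post <- matrix(0L, 5, params$n_bins)
  silent_post[2, 150] <- 1L
  expect_true(detect_responsive(average_psth(silent_post, params))$responsive)
  expect_false(detect_responsive(average_psth(matrix(0L, 5, params$n_bins),
                                              params))$responsive)
})

test_that("z-scored PSTHs are invariant to adding a constant count everywhere", {
  set.seed(41)
  counts <- matrix(rpois(25 * params$n_bins, 0.5), 25, params$n_bins)
  p1 <- average_psth(counts, params)
  p2 <- average_psth(counts + 2L, params)
  expect_equal(p1$z, p2$z)
})

test_that("probes below the active-unit minimum are excluded", {
  units <- data.frame(
    recording_id = c(rep("A", 14), rep("B", 15)),
    area = "S1",
    unit_id = sprintf("u%02d", 1:29))
  f <- filter_recordings(units, params)
  expect_false(f$included[f$recording_id == "A"])
  expect_true(f$included[f$recording_id == "B"])
  empty <- filter_recordings(units[0, ], params)
  expect_equal(nrow(empty), 0)
})

test_that("grand averages are two-level (units -> recording -> cohort)", {
  p10 <- psth_stub(rep(10, params$n_bins), 10, 0, params)
  p20 <- psth_stub(rep(20, params$n_bins), 20, 0, params)
  p40 <- psth_stub(rep(40, params$n_bins), 40, 0, params)
  one <- grand_average(list(p10), "A")
  expect_equal(unname(one$mean), p10$rate_hz)
  two <- grand_average(list(p10, p20), c("A", "B"))
  expect_equal(unique(two$mean), 15)
  expect_equal(unique(two$sd), sd(c(10, 20)))
  ## unbalanced designs: mean of recording means, not pooled-unit mean
  unb <- grand_average(list(p10, p10, p40), c("A", "A", "B"))
  expect_equal(unique(unb$mean), 25)      # (10 + 40) / 2, not 20
  ## equal unit counts: two-level equals pooled single-level
  bal <- grand_average(list(p10, p20, p20, p40), c("A", "A", "B", "B"))
  expect_equal(unique(bal$mean), mean(c(10, 20, 20, 40)))
})
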