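test_that("non-responsive units have a flat baseline profile on every hand protocol", {
  u <- baseline_unit(1.2)
  tt <- seq(-500, 500, by = 1)
  for (pr in list(stim_protocol("hand"), stim_protocol("hand_off"))) {
    r <- rate_profile(u, pr)
    expect_true(all(r(tt) == 1.2))
  }
  ## responsive unit on hand_off trials is also baseline everywhere
  r_off <- rate_profile(responsive_unit(), stim_protocol("hand_off"))
  expect_true(all(r_off(tt) == 1.2))
})

test_that("suppression multiplies baseline inside 110-170 ms", {
  u <- responsive_unit(baseline_hz = 1.2, suppressed = TRUE, supp_frac = 0.082)
  r <- rate_profile(u, stim_protocol("hand"))
  expect_equal(r(140), 0.0984)
  expect_equal(r(109.99), 1.2)
  expect_equal(r(170), 1.2)
})

test_that("the peak kernel is piecewise linear between onset, peak and offset", {
  u <- responsive_unit(onset_ms = 14.7, peak_ms = 21.4, dur_ms = 27,
                       peak_hz = 83, baseline_hz = 1.2)
  r <- rate_profile(u, stim_protocol("hand"))
  expect_equal(r(14.7), 1.2)
  expect_equal(r(21.4), 1.2 + 83)
  expect_equal(r((14.7 + 21.4) / 2), 1.2 + 41.5)
  expect_equal(r(14.7 + 27), 1.2)
  expect_equal(r(10), 1.2)
  expect_gte(min(r(seq(-500, 500, 0.25))), 0)
})

test_that("profile integral matches the closed-form component sum (quadrature oracle)", {
  u <- responsive_unit(baseline_hz = 1.5, onset_ms = 14.7, peak_ms = 21.4,
                       dur_ms = 27, peak_hz = 83, suppressed = TRUE,
                       supp_frac = 0.082, rebound = TRUE,
                       rebound_peak_ms = 289, rebound_hz = 31.4)
  r <- rate_profile(u, stim_protocol("hand"))
  quad <- integrate(function(t_s) r(t_s * 1000), -0.5, 0.5,
                    subdivisions = 2000, rel.tol = 1e-9)$value
  expect_equal(quad, profile_integral_oracle(u), tolerance = 1e-6)
})

test_that("paired-pulse profiles add a recovery-scaled second kernel", {
  u <- responsive_unit()
  r <- rate_profile(u, stim_protocol("paired_pulse", lag_ms = 150),
                    recovery = c("150" = 0.5, "250" = 1, "350" = 1))
  expect_equal(r(21.4), 1.2 + 83)             # first pulse untouched
  expect_equal(r(150 + 21.4), 1.2 + 0.5 * 83) # second scaled by 0.5
  r250 <- rate_profile(u, stim_protocol("paired_pulse", lag_ms = 250))
  expect_equal(r250(250 + 21.4), 1.2 + 83)
  expect_error(rate_profile(u, stim_protocol("paired_pulse", lag_ms = 150),
                            recovery = c("250" = 1)), "recovery")
})

test_that("cortex-laser profiles drive PV units at an intensity-scaled plateau", {
  pv <- baseline_unit(2, is_pv = TRUE, plateau_hz = 100)
  r <- rate_profile(pv, stim_protocol("cortex_laser", intensity_frac = 1))
  expect_equal(r(10), 102)
  expect_equal(r(25), 2)      # pulse over
  expect_equal(r(-10), 2)
  r_low <- rate_profile(pv, stim_protocol("cortex_laser", n_trials = 27,
                                          intensity_frac = 0.25))
  expect_equal(r_low(10), 2 + 25)
  nonpv <- baseline_unit(2)
  expect_equal(rate_profile(nonpv, stim_protocol("cortex_laser"))(10), 2)
  ## suppression scales with intensity on laser trials
  spv <- baseline_unit(2, suppressed = TRUE, supp_frac = 0.1)
  expect_equal(rate_profile(spv, stim_protocol("cortex_laser",
                                               intensity_frac = 0.5))(140),
               2 - 2 * 0.5 * 0.9)
})

test_that("hand-plus-cortex profiles scale the hand kernel by the silencing factor", {
  u <- responsive_unit(silencing_factor = 0.588)
  r <- rate_profile(u, stim_protocol("hand_plus_cortex"))
  expect_equal(r(21.4), 1.2 + 0.588 * 83)
  expect_equal(r(-100), 1.2)
})

test_that("mis-specified configurations raise instead of clamping negative rates", {
  bad <- responsive_unit(suppressed = TRUE, supp_frac = -0.5)
  expect_error(rate_profile(bad, stim_protocol("hand")), "clamp|\\[0, 1\\]")
  expect_error(rate_profile(baseline_unit(-1), stim_protocol("hand")), "baseline")
})

test_that("increasing peak amplitude strictly increases the peak-window rate mass", {
  amps <- c(20, 50, 83, 150)
  masses <- vapply(amps, function(a) {
    r <- rate_profile(responsive_unit(peak_hz = a), stim_protocol("hand"))
    integrate(function(t_s) r(t_s * 1000), 0, 0.1)$value
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
})
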