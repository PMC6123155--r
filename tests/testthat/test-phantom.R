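phantom_fixture <- function(lag = 0, duration = 60, frame_rate = 20,
                            n_couch = 8, dwell = 5) {
  t <- seq(0, duration, by = 0.04)
  internal <- resp_trace(t, 50 - 50 * cos(2 * pi * t / 4))
  surrogate <- resp_trace(t, 50 - 50 * cos(2 * pi * (t + lag) / 4))
  geom <- phantom_geometry(n_couch_positions = n_couch)
  sched <- acquisition_schedule(n_couch, dwell, frame_rate, start = 1)
  list(internal = internal, surrogate = surrogate, geom = geom,
       frames = simulate_acquisition(internal, geom, sched))
}

test_that("acquisition records the linear surrogate-to-anatomy coupling", {
  geom <- phantom_geometry(diaphragm_base_position = 10)
  sched <- acquisition_schedule(3, 4, frame_rate = 2, start = 0)
  flat <- resp_trace(seq(0, 15, by = 0.1), rep(0, 151))
  fr <- simulate_acquisition(flat, geom, sched)
  # constant trace at the EOE level: everything at the base position
  expect_true(all(fr$true_position == 10))
  # frame count = positions x dwell x rate
  expect_equal(nrow(fr), 3 * round(4 * 2))
  # full amplitude maps to base + excursion
  tri <- resp_trace(seq(0, 15, by = 0.1),
                    50 - 50 * cos(2 * pi * seq(0, 15, by = 0.1) / 4))
  fr2 <- simulate_acquisition(tri, geom, sched)
  expect_equal(max(fr2$true_position), 10 + geom$diaphragm_excursion,
               tolerance = 0.05)
  expect_error(simulate_acquisition(flat, geom,
                                    acquisition_schedule(5, 4, 2, start = 0)),
               "span")
})

test_that("a perfect surrogate reconstructs the nominal per-phase anatomy", {
  fx <- phantom_fixture()
  ex <- detect_extrema(fx$internal, window = 1.5)
  res <- reconstruct_phases(fx$frames, fx$internal, ex, fx$geom)
  pp <- res$per_phase
  # nominal amplitude fractions of the ten levels, quantized to 2 mm
  expect_equal(pp$apex_position, c(20, 16, 12, 8, 4, 0, 4, 8, 12, 16))
  expect_equal(pp$relative_displacement[6], 0)
  expect_true(all(pp$apex_position %% fx$geom$slice_thickness == 0))
  expect_equal(pp$lung_volume,
               fx$geom$lung_volume_at_eoe +
                 fx$geom$volume_per_mm * pp$apex_position)
  # identical surrogates: zero mismatch everywhere
  m <- compare_sortings(res, res)
  expect_true(all(m$per_phase$volume_diff_pct == 0))
  expect_true(all(m$per_phase$position_diff == 0))
  expect_equal(m$volume_diff_pct_range, c(0, 0))
})

test_that("a lag of T/10 shifts the phase curves by one index within one slice", {
  fx <- phantom_fixture(lag = 0.4)     # surrogate leads by T/10
  exi <- detect_extrema(fx$internal, window = 1.5)
  exs <- detect_extrema(fx$surrogate, window = 1.5)
  ra <- reconstruct_phases(fx$frames, fx$internal, exi, fx$geom)
  rb <- reconstruct_phases(fx$frames, fx$surrogate, exs, fx$geom)
  shift1 <- function(x, k) x[((seq_along(x) - 1 + k) %% length(x)) + 1]
  pa <- ra$per_phase$apex_position
  pb <- rb$per_phase$apex_position
  resid <- vapply(-1:1, function(k) max(abs(pb - shift1(pa, k))), numeric(1))
  # the one-index circular shift (in the lag direction) is the best match,
  # strictly better than no shift, and residuals stay within one slice
  expect_lt(resid[1], resid[2])
  expect_lte(resid[1], fx$geom$slice_thickness)
  # full-phase-set ranges agree between the two sortings (lag-only case)
  expect_equal(range(pa), range(pb))
  expect_equal(range(ra$per_phase$lung_volume),
               range(rb$per_phase$lung_volume))
  # lag sensitivity: mismatch reaches at least one slice thickness
  m <- compare_sortings(rb, ra)
  expect_gte(max(abs(m$per_phase$position_diff)), fx$geom$slice_thickness)
})

test_that("an exhale-warped surrogate concentrates mismatch on exhale phases", {
  p <- breathing_params(mean_period = 4, period_sd = 0, depth_sd = 0,
                        noise_sd = 0, duration = 60, seed = 3,
                        plateau_exponent = 1)
  internal <- generate_internal_motion(p)
  warped <- distort_to_surrogate(internal,
                                 surrogate_distortion(exhale_steepness = 2),
                                 seed = 1)
  geom <- phantom_geometry(n_couch_positions = 8)
  sched <- acquisition_schedule(8, 5, 20, start = 1)
  frames <- simulate_acquisition(internal, geom, sched)
  ra <- reconstruct_phases(frames, internal, NULL, geom)
  rb <- reconstruct_phases(frames, warped, NULL, geom)
  m <- compare_sortings(rb, ra)
  d <- abs(m$per_phase$position_diff)
  expect_gt(sum(d[2:5]), 0)                  # exhale phases disagree
  expect_gte(sum(d[2:5]), sum(d[7:10]))      # more than the inhale phases
})

test_that("missing limb coverage raises a data-sufficiency error naming the cell", {
  fx <- phantom_fixture()
  # a dwell far shorter than the period leaves cells uncovered
  short_sched <- acquisition_schedule(3, 0.6, 5, start = 1)
  frames <- simulate_acquisition(fx$internal, fx$geom, short_sched)
  ex <- detect_extrema(fx$internal, window = 1.5)
  expect_error(reconstruct_phases(frames, fx$internal, ex, fx$geom),
               "couch.*phase|data sufficiency")
})
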