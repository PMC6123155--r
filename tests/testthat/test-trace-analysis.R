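test_that("global renormalization is the expected affine map and idempotent", {
  tr <- resp_trace(c(0, 1, 2), c(2, 4, 6))
  expect_equal(normalize_global(tr)$amplitude, c(0, 50, 100))
  tr2 <- resp_trace(c(0, 1, 2), c(-1, 0, 3))
  expect_equal(normalize_global(tr2)$amplitude, c(0, 25, 100))
  once <- normalize_global(tr)
  expect_equal(normalize_global(once)$amplitude, once$amplitude)
  # order preserved
  p <- breathing_params(noise_sd = 3, duration = 20, seed = 8)
  raw <- generate_internal_motion(p)
  expect_equal(order(normalize_global(raw)$amplitude), order(raw$amplitude))
  expect_error(normalize_global(resp_trace(1:3, c(5, 5, 5))), "constant")
})

test_that("extrema detection matches the sinusoid's known peak times", {
  tr <- make_sinusoid(duration = 20, period = 4, rate = 25)
  ex <- detect_extrema(tr, window = 1.5)
  dt <- 0.04
  expect_true(all(abs(ex$eoi_times - c(1, 5, 9, 13, 17)) <= dt))
  expect_true(all(abs(ex$eoe_times - c(3, 7, 11, 15, 19)) <= dt))
  # two-pass automatic window lands on the same extrema
  ex_auto <- detect_extrema(tr)
  expect_equal(ex_auto$eoi_times, ex$eoi_times)
  # noise does not change the count (fixed seed)
  set.seed(42)
  noisy <- resp_trace(tr$time, tr$amplitude + rnorm(length(tr$time), 0, 2))
  exn <- detect_extrema(noisy, window = 1.5)
  expect_equal(length(exn$eoi_times), 5)
  expect_equal(length(exn$eoe_times), 5)
  expect_error(detect_extrema(resp_trace(1:100 / 25, rep(1, 100)),
                              window = 1.5), "no extrema")
})

test_that("extrema alternate and counts are invariant under a small lag", {
  tr <- make_sinusoid(duration = 24, period = 4)
  lag <- make_sinusoid(duration = 24, period = 4, phase = 0.3)
  ex1 <- detect_extrema(tr, window = 1.5)
  ex2 <- detect_extrema(lag, window = 1.5)
  expect_equal(length(ex1$eoi_times), length(ex2$eoi_times))
  all_t <- sort(c(ex1$eoi_times, ex1$eoe_times))
  types <- ifelse(all_t %in% ex1$eoi_times, "EOI", "EOE")
  expect_true(all(types[-1] != types[-length(types)]))
})

test_that("manual override replaces the nearest detected extremum", {
  tr <- make_sinusoid(duration = 20, period = 4)
  ex <- detect_extrema(tr, window = 1.5)
  ov <- data.frame(time = 5.2, label = "EOI")
  ex2 <- detect_extrema(tr, window = 1.5, override = ov)
  expect_equal(length(ex2$eoi_times), length(ex$eoi_times))
  expect_true(any(abs(ex2$eoi_times - 5.2) < 0.03))
  expect_false(any(abs(ex2$eoi_times - 5.0) < 0.03))
})

test_that("cycle segmentation reports EOI-to-EOI periods and 0-100 depths", {
  tr <- normalize_global(make_sinusoid(duration = 20, period = 4))
  ex <- detect_extrema(tr, window = 1.5)
  cyc <- segment_cycles(tr, ex)
  periods <- attr(cyc, "eoi_periods")
  expect_length(periods, 4)
  expect_true(all(abs(periods - 4) <= 0.04))
  expect_true(all(abs(cyc$depth_d - 100) < 1))
  # an odd long cycle is timed correctly
  t <- seq(0, 26, by = 0.04)
  ph <- ifelse(t < 8, 2 * pi * t / 4,
               ifelse(t < 14, 2 * pi * 8 / 4 + 2 * pi * (t - 8) / 6,
                      2 * pi * 8 / 4 + 2 * pi * 6 / 6 + 2 * pi * (t - 14) / 4))
  odd <- resp_trace(t, 50 - 50 * cos(ph))
  exo <- detect_extrema(odd, window = 1.4)
  cyc_o <- segment_cycles(odd, exo)
  # the 6 s EOE-to-EOE cycle is timed correctly; its EOI-to-EOI periods
  # straddle it as two 5 s gaps
  expect_true(any(abs(cyc_o$period_eoe - 6) <= 0.08))
  expect_equal(sum(abs(diff(exo$eoi_times) - 5) <= 0.08), 2)
  expect_error(segment_cycles(tr, list(eoi_times = 1, eoe_times = c(0, 2),
                                       eoi_indices = 26L,
                                       eoe_indices = c(1L, 51L))),
               "at least 2 EOI")
})

test_that("paired cycle statistics behave under identity, lag and gain", {
  p <- breathing_params(mean_period = 4, period_sd = 0.3, depth_sd = 8,
                        noise_sd = 0, duration = 60, seed = 21)
  tr <- normalize_global(generate_internal_motion(p))
  ex <- detect_extrema(tr)
  cyc <- segment_cycles(tr, ex)
  st <- paired_cycle_stats(cyc, cyc)
  expect_equal(st$period_diff_range, c(0, 0))
  expect_equal(st$depth_diff_range, c(0, 0))
  # lag preserves periods
  raw <- generate_internal_motion(p)
  lagged <- normalize_global(
    distort_to_surrogate(raw, surrogate_distortion(lag = 0.2), seed = 1))
  cyc_l <- segment_cycles(lagged, detect_extrema(lagged))
  st_l <- paired_cycle_stats(cyc, cyc_l)
  expect_true(all(abs(st_l$period_diff_range) <= 2 / 25))
  # amplitude gain before global normalization cancels: documented behavior
  gained <- raw
  gained$amplitude <- 0.9 * gained$amplitude
  attr(gained, "model") <- attr(raw, "model")
  cyc_g <- segment_cycles(normalize_global(gained),
                          detect_extrema(normalize_global(gained)))
  st_g <- paired_cycle_stats(cyc, cyc_g)
  expect_true(all(abs(st_g$depth_diff_range) < 1e-6))
})

test_that("whole-trace correlation has its closed-form values and invariances", {
  tr <- make_sinusoid(duration = 40)
  expect_equal(trace_correlation(tr, tr), 1.0, tolerance = 1e-12)
  neg <- resp_trace(tr$time, -tr$amplitude)
  expect_equal(trace_correlation(tr, neg), -1.0, tolerance = 1e-12)
  # lagged unit sinusoids over whole periods: r = cos(phi)
  phi <- 0.345
  lag <- make_sinusoid(duration = 40, phase = phi * 4 / (2 * pi))
  expect_equal(trace_correlation(tr, lag), cos(phi), tolerance = 1e-3)
  # symmetry and positive-affine invariance
  expect_equal(trace_correlation(lag, tr), trace_correlation(tr, lag))
  aff <- resp_trace(lag$time, 3.2 * lag$amplitude + 17)
  expect_equal(trace_correlation(tr, aff), trace_correlation(tr, lag),
               tolerance = 1e-12)
  expect_error(trace_correlation(tr, resp_trace(tr$time,
                                                rep(1, length(tr$time)))),
               "variance")
})
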