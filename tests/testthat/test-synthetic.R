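test_that("degenerate deterministic generator produces exactly periodic cycles", {
  p <- breathing_params(mean_period = 4, period_sd = 0, depth_sd = 0,
                        noise_sd = 0, baseline_drift_rate = 0,
                        duration = 20, seed = 3)
  tr <- generate_internal_motion(p)
  truth <- attr(tr, "truth")
  dt <- 1 / p$sampling_rate
  expect_true(all(abs(diff(truth$eoi_times) - 4) <= dt))
  # mean_period = 4 s over 20 s: 5 EOI marks (within one boundary cycle)
  expect_true(abs(length(truth$eoi_times) - 5) <= 1)
  # detected extrema agree with ground truth
  ex <- detect_extrema(normalize_global(tr), window = 1.5)
  expect_equal(length(ex$eoi_times), length(truth$eoi_times))
  expect_true(max(abs(ex$eoi_times - truth$eoi_times)) <= dt)
})

test_that("same seed reproduces bit-identical traces", {
  p <- breathing_params(noise_sd = 2, duration = 20, seed = 11)
  expect_identical(generate_internal_motion(p)$amplitude,
                   generate_internal_motion(p)$amplitude)
  pair1 <- generate_pair(p, surrogate_distortion(lag = 0.2, extra_noise_sd = 2))
  pair2 <- generate_pair(p, surrogate_distortion(lag = 0.2, extra_noise_sd = 2))
  expect_identical(pair1$surrogate_a$amplitude, pair2$surrogate_a$amplitude)
  expect_identical(pair1$surrogate_b$amplitude, pair2$surrogate_b$amplitude)
})

test_that("parameter invariants are enforced", {
  expect_error(breathing_params(mean_period = -1), "mean_period")
  expect_error(breathing_params(sampling_rate = 1), "sampling_rate")
  expect_error(breathing_params(duration = 5, mean_period = 4), "duration")
  expect_error(surrogate_distortion(exhale_steepness = 0.5), "exhale")
  expect_error(surrogate_distortion(inhale_steepness = 0), "inhale")
  expect_error(scan_timeline(0, 10, matrix(c(5, 4), 1)), "off time")
  expect_error(scan_timeline(0, 10, matrix(c(2, 6, 5, 9), 2, byrow = TRUE)),
               "non-overlapping")
})

test_that("identity distortion is an exact fixed point, even with noise", {
  p <- breathing_params(noise_sd = 2, duration = 30, seed = 5)
  tr <- generate_internal_motion(p)
  out <- distort_to_surrogate(tr, surrogate_distortion(), seed = 1)
  expect_equal(out$amplitude, tr$amplitude, tolerance = 1e-12)
  expect_equal(out$time, tr$time)
  # a trace without its generating model cannot be distorted
  bare <- resp_trace(tr$time, tr$amplitude)
  expect_error(distort_to_surrogate(bare, surrogate_distortion()), "model")
})

test_that("lag shifts every EOI earlier by the stated amount", {
  p <- breathing_params(mean_period = 4, period_sd = 0, depth_sd = 0,
                        noise_sd = 0, duration = 40, seed = 2)
  tr <- generate_internal_motion(p)
  out <- distort_to_surrogate(tr, surrogate_distortion(lag = 0.2), seed = 1)
  ex_in <- detect_extrema(normalize_global(tr), window = 1.5)
  ex_out <- detect_extrema(normalize_global(out), window = 1.5)
  n <- min(length(ex_in$eoi_times), length(ex_out$eoi_times))
  dt <- 1 / p$sampling_rate
  expect_true(all(abs((ex_in$eoi_times[1:n] - ex_out$eoi_times[1:n]) - 0.2)
                  <= dt))
})

test_that("lags compose additively", {
  p <- breathing_params(mean_period = 4, duration = 30, seed = 9)
  tr <- generate_internal_motion(p)
  one <- distort_to_surrogate(
    distort_to_surrogate(tr, surrogate_distortion(lag = 0.1), seed = 1),
    surrogate_distortion(lag = 0.15), seed = 1)
  both <- distort_to_surrogate(tr, surrogate_distortion(lag = 0.25), seed = 1)
  expect_equal(one$amplitude, both$amplitude, tolerance = 1e-9)
})

test_that("exhale steepening shortens the EOI-to-half-depth fall in every cycle", {
  p <- breathing_params(mean_period = 4, period_sd = 0.2, depth_sd = 5,
                        noise_sd = 0, duration = 40, seed = 13)
  tr <- generate_internal_motion(p)
  out <- distort_to_surrogate(tr, surrogate_distortion(exhale_steepness = 2),
                              seed = 1)
  truth <- attr(tr, "truth")
  # brute-force 50%-of-depth crossing search on each interior cycle
  half_fall <- function(trace, eoi, eoe_next) {
    i0 <- which.min(abs(trace$time - eoi))
    i1 <- which.min(abs(trace$time - eoe_next))
    seg <- i0:i1
    lvl <- trace$amplitude[i1] + 0.5 * (trace$amplitude[i0] - trace$amplitude[i1])
    cross <- seg[which(trace$amplitude[seg] <= lvl)[1]]
    trace$time[cross] - eoi
  }
  eoes <- truth$eoe_times
  for (k in seq_along(truth$eoi_times)) {
    eoi <- truth$eoi_times[k]
    nxt <- eoes[eoes > eoi]
    if (length(nxt) == 0) next
    if (nxt[1] > max(tr$time) - 0.1) next
    expect_lt(half_fall(out, eoi, nxt[1]), half_fall(tr, eoi, nxt[1]))
  }
})

test_that("warps preserve extrema count and ordering", {
  p <- breathing_params(mean_period = 4, period_sd = 0.3, noise_sd = 0,
                        duration = 40, seed = 17)
  tr <- generate_internal_motion(p)
  ex0 <- detect_extrema(normalize_global(tr), window = 1.5)
  for (d in list(surrogate_distortion(exhale_steepness = 2),
                 surrogate_distortion(inhale_steepness = 0.7),
                 surrogate_distortion(exhale_steepness = 1.5,
                                      inhale_steepness = 1.5,
                                      response_exponent = 1.3))) {
    out <- distort_to_surrogate(tr, d, seed = 1)
    ex <- detect_extrema(normalize_global(out), window = 1.5)
    expect_equal(length(ex$eoi_times), length(ex0$eoi_times))
    expect_equal(length(ex$eoe_times), length(ex0$eoe_times))
  }
})

test_that("generate_pair shares trigger, motion and beam timeline", {
  p <- breathing_params(duration = 30, noise_sd = 0, seed = 4)
  tl <- scan_timeline(0, 30, matrix(c(5, 12, 18, 24), 2, byrow = TRUE))
  # identity distortions at equal rates: the two surrogates coincide
  pair <- generate_pair(p, timeline = tl, rate_a = 25, rate_b = 25)
  expect_equal(pair$surrogate_a$amplitude, pair$surrogate_b$amplitude)
  expect_equal(pair$surrogate_a$time, pair$surrogate_b$time)
  seg_a <- beam_segments(pair$surrogate_a)
  seg_b <- beam_segments(pair$surrogate_b)
  expect_equal(nrow(seg_a), 2)
  expect_equal(seg_a, seg_b)
  # injected lag on b is recovered with b as the leading (first) argument
  pair2 <- generate_pair(p, distortion_b = surrogate_distortion(lag = 0.2),
                         rate_a = 25, rate_b = 40)
  sh <- eoi_latency_shift(pair2$surrogate_b, pair2$surrogate_a)
  expect_lt(abs(sh$mean_lag - 0.2), 1 / 25)
})
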