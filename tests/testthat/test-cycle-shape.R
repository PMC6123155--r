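sin_shape_fixture <- function() {
  tr <- normalize_global(make_sinusoid(duration = 24, period = 4, rate = 25))
  ex <- detect_extrema(tr, window = 1.5)
  list(tr = tr, ex = ex, cycles = extract_aligned_cycles(tr, ex))
}

test_that("aligned cycles are pinned at EOI = 100 with EOE endpoints at 0", {
  fx <- sin_shape_fixture()
  expect_length(fx$cycles, 5)
  for (cyc in fx$cycles) {
    at0 <- cyc$amplitude[which.min(abs(cyc$rel_time))]
    expect_equal(at0, 100, tolerance = 0.2)
    expect_lt(abs(cyc$amplitude[1]), 0.5)
    expect_lt(abs(cyc$amplitude[nrow(cyc)]), 0.5)
  }
  # all cycles of a pure sinusoid coincide
  g <- seq(-1.8, 1.8, by = 0.04)
  curves <- vapply(fx$cycles, function(c)
    approx(c$rel_time, c$amplitude, xout = g)$y, numeric(length(g)))
  expect_lt(max(apply(curves, 1, function(r) diff(range(r))), na.rm = TRUE),
            0.5)
})

test_that("drifting baselines map the lower flanking EOE to 0", {
  t <- seq(0, 12, by = 0.04)
  a <- 50 - 50 * cos(2 * pi * t / 4) + 3 * t     # interior EOEs at 4, 8
  tr <- resp_trace(t, a)
  ex <- detect_extrema(tr, window = 1.5, min_prominence = 5)
  cycles <- extract_aligned_cycles(tr, ex)
  expect_length(cycles, 1)
  cyc <- cycles[[1]]
  expect_equal(min(cyc$amplitude[c(1, nrow(cyc))]), 0, tolerance = 1e-9)
  expect_gt(max(cyc$amplitude[c(1, nrow(cyc))]), 5)
})

test_that("average shape equals any single cycle for identical cycles and masks sparse points", {
  fx <- sin_shape_fixture()
  shp <- average_shape(fx$cycles, grid_step = 0.04)
  expect_equal(shp$mean_amplitude[shp$rel_time == 0], 100, tolerance = 0.2)
  one <- fx$cycles[[2]]
  inside <- shp$rel_time >= min(one$rel_time) & shp$rel_time <= max(one$rel_time)
  ref <- approx(one$rel_time, one$amplitude, xout = shp$rel_time[inside])$y
  ok <- !is.na(shp$mean_amplitude[inside])
  expect_lt(max(abs(shp$mean_amplitude[inside][ok] - ref[ok])), 0.5)
  # masking: points covered by fewer than min_contributing cycles are NA
  short <- fx$cycles
  short[[1]] <- short[[1]][short[[1]]$rel_time > -0.5, ]   # truncate one cycle
  shp2 <- average_shape(short, grid_step = 0.04,
                        min_contributing = length(short))
  expect_true(any(is.na(shp2$mean_amplitude)))
  expect_error(average_shape(fx$cycles[1], grid_step = 0.04), "2 cycles")
  # symmetric +/- eps perturbations average back to the base curve
  base <- fx$cycles[[2]]
  up <- base; up$amplitude <- up$amplitude + 2
  dn <- base; dn$amplitude <- dn$amplitude - 2
  shp3 <- average_shape(list(up, dn), grid_step = 0.04, min_contributing = 2)
  inside <- !is.na(shp3$mean_amplitude)
  ref3 <- approx(base$rel_time, base$amplitude,
                 xout = shp3$rel_time[inside])$y
  expect_lt(max(abs(shp3$mean_amplitude[inside] - ref3), na.rm = TRUE), 1e-6)
})

test_that("shape is invariant under positive affine maps of the raw trace", {
  p <- breathing_params(duration = 40, noise_sd = 0, seed = 12)
  raw <- generate_internal_motion(p)
  aff <- resp_trace(raw$time, 2.5 * raw$amplitude - 40)
  ex <- detect_extrema(normalize_global(raw))
  s1 <- trace_average_shape(raw, extrema = ex)
  s2 <- trace_average_shape(aff, extrema = ex)
  ok <- !is.na(s1$mean_amplitude) & !is.na(s2$mean_amplitude)
  expect_lt(max(abs(s1$mean_amplitude[ok] - s2$mean_amplitude[ok])), 1e-6)
})

test_that("limb comparison flags warped limbs and matches identical shapes", {
  fx <- sin_shape_fixture()
  shp <- average_shape(fx$cycles, grid_step = 0.04)
  same <- compare_limbs(shp, shp)
  expect_equal(same$exhale_verdict, "matched")
  expect_equal(same$inhale_verdict, "matched")
  expect_equal(same$exhale_score, 0)
  expect_equal(same$inhale_score, 0)

  p <- breathing_params(duration = 60, noise_sd = 0, seed = 23)
  tr <- generate_internal_motion(p)
  warped <- distort_to_surrogate(tr, surrogate_distortion(exhale_steepness = 2),
                                 seed = 1)
  shp_a <- trace_average_shape(tr)
  shp_b <- trace_average_shape(warped)
  cmp <- compare_limbs(shp_a, shp_b)
  expect_equal(cmp$exhale_verdict, "B_steeper")
  expect_equal(cmp$inhale_verdict, "matched")
  # infinite threshold: always matched
  cmp_inf <- compare_limbs(shp_a, shp_b, threshold = Inf)
  expect_equal(cmp_inf$exhale_verdict, "matched")
  expect_equal(cmp_inf$inhale_verdict, "matched")
})

test_that("noise-only pairs stay within the default verdict threshold", {
  scores <- calibrate_limb_threshold(n_seeds = 6, noise_sd = 2)
  expect_true(all(abs(scores$exhale_score) < 3))
  expect_true(all(abs(scores$inhale_score) < 3))
})
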