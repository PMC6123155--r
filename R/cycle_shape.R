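#' Extract EOI-aligned, per-cycle-renormalized breathing cycles
#'
#' Each cycle runs between two sequential EOE points.  Its amplitude is
#' renormalized so that the EOI maps to 100 and the LOWER of the two flanking
#' EOE levels maps to 0 (under baseline drift the other endpoint then sits
#' above 0, preserving the cycle's geometry), and time is re-origined at the
#' EOI: negative relative time is the inhalation limb, positive the
#' exhalation limb.
#'
#' Shape averaging is sensitive to where each cycle's EOI is placed: on a
#' noisy trace the sample argmax wanders over the peak dwell region, and by
#' more on whichever flank is flatter, so automatically detected extrema
#' smear and slightly shift the averaged curve.  Supply corrected extrema
#' where alignment accuracy matters -- the `override` argument of
#' [detect_extrema()], or [true_extrema()] on synthetic traces -- exactly as
#' the manual adjustment step of the clinical workflow.
#'
#' @param trace A [resp_trace()].
#' @param extrema A [detect_extrema()] result (or [true_extrema()]) for it.
#' @return List of `aligned_cycle` data.frames (`rel_time`, `amplitude`);
#'   cycles whose EOI is not an interior maximum of the span are skipped
#'   with a warning.
#' @export
extract_aligned_cycles <- function(trace, extrema) {
  stopifnot_trace(trace)
  t <- trace$time
  a <- trace$amplitude
  cycles <- list()
  n_eoe <- length(extrema$eoe_times)
  if (n_eoe < 2)
    stop("extract_aligned_cycles: need at least one complete EOE-EOE cycle",
         call. = FALSE)
  for (k in seq_len(n_eoe - 1)) {
    i0 <- extrema$eoe_indices[k]
    i1 <- extrema$eoe_indices[k + 1]
    inside <- which(extrema$eoi_indices > i0 & extrema$eoi_indices < i1)
    if (length(inside) != 1) next
    ie <- extrema$eoi_indices[inside]
    seg <- i0:i1
    # 10% headroom: reject only grossly misplaced EOIs, not noise overshoot
    tol <- 0.1 * (max(a[seg]) - min(a[seg]))
    if (a[ie] < max(a[seg]) - tol || ie == i0 || ie == i1) {
      warning(sprintf(
        "extract_aligned_cycles: EOI at t=%.2f not a strict interior maximum; cycle skipped",
        t[ie]), call. = FALSE)
      next
    }
    base <- min(a[i0], a[i1])
    depth <- a[ie] - base
    if (depth <= 0) next
    cyc <- data.frame(rel_time = t[seg] - t[ie],
                      amplitude = 100 * (a[seg] - base) / depth)
    class(cyc) <- c("aligned_cycle", class(cyc))
    cycles[[length(cycles) + 1]] <- cyc
  }
  cycles
}

#' Average breathing-cycle shape
#'
#' Interpolates each aligned cycle onto a common relative-time grid anchored
#' at the EOI (rel_time = 0 is a grid point) and takes the pointwise mean
#' wherever at least `min_contributing` cycles cover the grid point; other
#' points are masked (`NA`).  Because every cycle is renormalized to 100 at
#' its EOI, the averaged curve has value 100 at rel_time 0.
#'
#' @param cycles List of aligned cycles from [extract_aligned_cycles()].
#' @param grid_step Grid spacing in seconds; default 0.04.
#' @param min_contributing Minimum cycles per grid point; default
#'   `max(2, ceiling(0.2 * n_cycles))`.
#' @return An object of class `average_cycle_shape`: data.frame with
#'   `rel_time`, `mean_amplitude`, `n_contributing`.
#' @export
average_shape <- function(cycles, grid_step = 0.04, min_contributing = NULL) {
  if (length(cycles) < 2)
    stop("average_shape: need at least 2 cycles", call. = FALSE)
  if (is.null(min_contributing))
    min_contributing <- max(2, ceiling(0.2 * length(cycles)))
  lo <- min(vapply(cycles, function(c) min(c$rel_time), numeric(1)))
  hi <- max(vapply(cycles, function(c) max(c$rel_time), numeric(1)))
  grid <- seq(-grid_step * ceiling(-lo / grid_step),
              grid_step * ceiling(hi / grid_step), by = grid_step)
  vals <- vapply(cycles, function(c) {
    v <- rep(NA_real_, length(grid))
    inside <- grid >= min(c$rel_time) & grid <= max(c$rel_time)
    v[inside] <- stats::approx(c$rel_time, c$amplitude,
                               xout = grid[inside])$y
    v
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n_contrib <- rowSums(!is.na(vals))
  mean_amp <- rowMeans(vals, na.rm = TRUE)
  mean_amp[n_contrib < min_contributing] <- NA_real_
  out <- data.frame(rel_time = grid, mean_amplitude = mean_amp,
                    n_contributing = n_contrib)
  class(out) <- c("average_cycle_shape", class(out))
  out
}

#' Compare inhalation / exhalation limb steepness of two average shapes
#'
#' Scores each limb as the mean of `shape_b - shape_a` over the grid points
#' where both shapes are defined on that limb (exhalation: rel_time > 0;
#' inhalation: rel_time < 0).  Because both shapes are pinned to 100 at the
#' EOI and descend to 0 at their EOE ends, the steeper curve lies BELOW the
#' gentler one on either limb, so a positive score means trace A is steeper
#' on that limb.  Verdicts: `A_steeper` if score > threshold, `B_steeper` if
#' score < -threshold, else `matched`; a limb with no overlap is
#' `undetermined`.
#'
#' The numeric threshold (default 3.0 on the 0-100 scale) stands in for the
#' visual three-group classification used in practice; see
#' [calibrate_limb_threshold()].
#'
#' @param shape_a,shape_b [average_shape()] results.
#' @param threshold Verdict threshold in 0-100 amplitude units.
#' @return An object of class `limb_comparison`: `exhale_verdict`,
#'   `inhale_verdict`, `exhale_score`, `inhale_score`, `threshold`.
#' @export
compare_limbs <- function(shape_a, shape_b, threshold = 3.0) {
  bi <- stats::approx(shape_b$rel_time, shape_b$mean_amplitude,
                      xout = shape_a$rel_time)$y
  diff_ab <- bi - shape_a$mean_amplitude
  score_limb <- function(mask) {
    v <- diff_ab[mask & !is.na(diff_ab) & !is.na(shape_a$mean_amplitude)]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }
  ex_score <- score_limb(shape_a$rel_time > 0)
  in_score <- score_limb(shape_a$rel_time < 0)
  verdict <- function(score) {
    if (is.na(score)) "undetermined"
    else if (score > threshold) "A_steeper"
    else if (score < -threshold) "B_steeper"
    else "matched"
  }
  structure(list(exhale_verdict = verdict(ex_score),
                 inhale_verdict = verdict(in_score),
                 exhale_score = ex_score, inhale_score = in_score,
                 threshold = threshold),
            class = "limb_comparison")
}

#' @export
print.limb_comparison <- function(x, ...) {
  cat(sprintf("<limb_comparison> exhale: %s (score %.2f), inhale: %s (score %.2f), threshold %.1f\n",
              x$exhale_verdict, x$exhale_score, x$inhale_verdict,
              x$inhale_score, x$threshold))
  invisible(x)
}

#' Average-shape pipeline for one trace
#'
#' Convenience wrapper: normalize, locate extrema, extract aligned cycles
#' and average them.  When the trace carries ground-truth marks (synthetic
#' traces) those are used for alignment by default, mirroring the manually
#' adjusted extrema of the clinical workflow; otherwise extrema are
#' detected automatically.
#'
#' @param trace A [resp_trace()].
#' @param grid_step Passed to [average_shape()].
#' @param extrema Optional extrema set; default [true_extrema()] when
#'   available, else [detect_extrema()].
#' @param ... Passed to [detect_extrema()].
#' @return An [average_shape()] result.
#' @export
trace_average_shape <- function(trace, grid_step = 0.04, extrema = NULL,
                                ...) {
  nt <- normalize_global(trace)
  if (is.null(extrema)) {
    extrema <- if (!is.null(trace_truth(trace))) true_extrema(nt)
               else detect_extrema(nt, ...)
  }
  average_shape(extract_aligned_cycles(nt, extrema), grid_step = grid_step)
}

#' Calibrate the limb-comparison threshold on noise-only pairs
#'
#' Simulates undistorted surrogate pairs differing only by sensor noise and
#' returns the empirical distribution of limb scores, so a threshold can be
#' chosen that classifies noise-only pairs as `matched` at a desired rate.
#'
#' @param n_seeds Number of simulated pairs.
#' @param noise_sd Sensor noise SD (0-100 units of the raw amplitude scale).
#' @param params Base [breathing_params()].
#' @return data.frame with one row per seed: `exhale_score`, `inhale_score`.
#' @export
calibrate_limb_threshold <- function(n_seeds = 20, noise_sd = 2,
                                     params = breathing_params()) {
  res <- lapply(seq_len(n_seeds), function(s) {
    p <- params
    p$seed <- derive_seed(p$seed, 100L + s)
    pair <- generate_pair(p,
                          surrogate_distortion(extra_noise_sd = noise_sd),
                          surrogate_distortion(extra_noise_sd = noise_sd))
    cmp <- compare_limbs(trace_average_shape(pair$surrogate_a),
                         trace_average_shape(pair$surrogate_b))
    data.frame(exhale_score = cmp$exhale_score,
               inhale_score = cmp$inhale_score)
  })
  do.call(rbind, res)
}
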