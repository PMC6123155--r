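#' Digital motion-phantom geometry
#'
#' A minimal linear anatomy model: the diaphragm apex moves along the
#' superior-inferior axis proportionally to the normalized internal
#' respiratory amplitude, and whole-lung volume is linear in apex position.
#' Reconstructed positions are quantized to the axial slice thickness.
#'
#' @param diaphragm_base_position Apex position at EOE, mm.
#' @param diaphragm_excursion Peak-to-peak apex motion, mm (> 0).
#' @param lung_volume_at_eoe mL.
#' @param volume_per_mm mL of lung volume per mm of apex displacement (> 0).
#' @param slice_thickness Axial slice thickness, mm (> 0); default 2.
#' @param n_couch_positions Number of couch stations.
#' @param couch_span Total scan extent, mm (bookkeeping only).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(diaphragm_base_position = 0,
                             diaphragm_excursion = 20,
                             lung_volume_at_eoe = 3000,
                             volume_per_mm = 50,
                             slice_thickness = 2,
                             n_couch_positions = 40,
                             couch_span = 300) {
  g <- list(diaphragm_base_position = diaphragm_base_position,
            diaphragm_excursion = diaphragm_excursion,
            lung_volume_at_eoe = lung_volume_at_eoe,
            volume_per_mm = volume_per_mm,
            slice_thickness = slice_thickness,
            n_couch_positions = as.integer(n_couch_positions),
            couch_span = couch_span)
  if (!(g$diaphragm_excursion > 0))
    stop("phantom_geometry: diaphragm_excursion must be > 0", call. = FALSE)
  if (!(g$slice_thickness > 0))
    stop("phantom_geometry: slice_thickness must be > 0", call. = FALSE)
  if (!(g$volume_per_mm > 0))
    stop("phantom_geometry: volume_per_mm must be > 0", call. = FALSE)
  class(g) <- "phantom_geometry"
  g
}

#' Cine acquisition schedule
#'
#' Step-and-shoot schedule: the scanner dwells at each couch position for
#' `dwell_duration` seconds (which must cover at least one maximal breathing
#' period - the data sufficiency condition), acquiring frames at
#' `frame_rate` Hz.  The default frame period of 0.5 s matches a typical CT
#' source rotation time.
#'
#' @param n_positions Number of couch positions.
#' @param dwell_duration Seconds per position.
#' @param frame_rate Frames per second; default 2 (0.5 s per frame).
#' @param start Time of the first dwell, seconds.
#' @return An object of class `acquisition_schedule` with per-position
#'   `dwell_start` and shared `dwell_duration`, `frame_rate`.
#' @export
acquisition_schedule <- function(n_positions, dwell_duration, frame_rate = 2,
                                 start = 0) {
  if (dwell_duration <= 0 || frame_rate <= 0)
    stop("acquisition_schedule: dwell_duration and frame_rate must be > 0",
         call. = FALSE)
  structure(list(
    n_positions = as.integer(n_positions),
    dwell_start = start + (seq_len(n_positions) - 1) * dwell_duration,
    dwell_duration = dwell_duration,
    frame_rate = frame_rate
  ), class = "acquisition_schedule")
}

#' Simulate a cine 4D CT acquisition over the phantom
#'
#' For every couch position and frame time, records the true diaphragm apex
#' position `base + excursion * g(t)`, where `g(t)` is the internal trace's
#' amplitude normalized to `[0, 1]` over its span (a constant trace maps to
#' 0, i.e. everything rests at the EOE position).
#'
#' @param internal Internal-motion [resp_trace()] covering the schedule.
#' @param geometry A [phantom_geometry()].
#' @param schedule An [acquisition_schedule()].
#' @return data.frame of class `phantom_frames`: `couch`, `time`,
#'   `true_position`.
#' @export
simulate_acquisition <- function(internal, geometry, schedule) {
  stopifnot_trace(internal, "internal")
  n_frames <- round(schedule$dwell_duration * schedule$frame_rate)
  last_t <- max(schedule$dwell_start) + (n_frames - 1) / schedule$frame_rate
  if (min(schedule$dwell_start) < min(internal$time) ||
      last_t > max(internal$time))
    stop("simulate_acquisition: schedule exceeds the internal trace span",
         call. = FALSE)
  r <- range(internal$amplitude)
  frac <- if (diff(r) > 0) (internal$amplitude - r[1]) / diff(r)
          else rep(0, length(internal$amplitude))
  frames <- do.call(rbind, lapply(seq_len(schedule$n_positions), function(p) {
    tt <- schedule$dwell_start[p] + (seq_len(n_frames) - 1) / schedule$frame_rate
    data.frame(couch = p, time = tt,
               true_position = geometry$diaphragm_base_position +
                 geometry$diaphragm_excursion *
                 stats::approx(internal$time, frac, xout = tt)$y)
  }))
  class(frames) <- c("phantom_frames", class(frames))
  frames
}

# nominal limb of each phase; phase 6 (EOE) accepts either limb
phase_limb <- c(rep("exhale", 5), "either", rep("inhale", 4))

#' Reconstruct the ten-phase phantom series under one surrogate's sorting
#'
#' The surrogate trace (not the internal motion) is phase-sorted by local
#' amplitude; every frame inherits the amplitude fraction and limb of the
#' nearest-in-time retained surrogate sample.  For each couch position and
#' phase, the reconstructed frame is the candidate on the phase's limb whose
#' fraction is nearest the phase's nominal level (ties to the earliest
#' frame); phase 6 accepts either limb.  The per-phase diaphragm apex is the
#' maximum selected true position over couch positions, quantized to the
#' slice thickness, and lung volume follows the linear coupling.
#'
#' @param frames A [simulate_acquisition()] result.
#' @param surrogate The surrogate [resp_trace()] used for sorting.
#' @param extrema [detect_extrema()] result for the surrogate (computed with
#'   defaults when `NULL`).
#' @param geometry The [phantom_geometry()].
#' @return An object of class `phase4d_result`: data.frame `per_phase` with
#'   `phase_index`, `phase_name`, `apex_position` (mm, quantized),
#'   `relative_displacement` (mm vs phase 6), `lung_volume` (mL).
#' @export
reconstruct_phases <- function(frames, surrogate, extrema = NULL, geometry) {
  stopifnot_trace(surrogate, "surrogate")
  if (is.null(extrema)) extrema <- detect_extrema(normalize_global(surrogate))
  if (min(frames$time) < min(surrogate$time) - 1e-9 ||
      max(frames$time) > max(surrogate$time) + 1e-9)
    stop("reconstruct_phases: surrogate does not span the frame times",
         call. = FALSE)
  sorted <- assign_phases(surrogate, extrema)
  near <- findInterval(frames$time, sorted$time, all.inside = TRUE)
  lo_d <- abs(frames$time - sorted$time[near])
  hi_d <- abs(frames$time - sorted$time[pmin(near + 1L, nrow(sorted))])
  near <- ifelse(hi_d < lo_d, pmin(near + 1L, nrow(sorted)), near)
  frames$fraction <- sorted$fraction[near]
  frames$limb <- sorted$limb[near]

  sel_pos <- matrix(NA_real_, nrow = max(frames$couch), ncol = 10)
  for (p in seq_len(max(frames$couch))) {
    fp <- frames[frames$couch == p, ]
    for (ph in 1:10) {
      cand <- if (phase_limb[ph] == "either") fp
              else fp[fp$limb == phase_limb[ph], ]
      if (nrow(cand) == 0)
        stop(sprintf(
          "reconstruct_phases: no candidate frame for couch %d, phase %d (data sufficiency violated)",
          p, ph), call. = FALSE)
      d <- abs(cand$fraction - phase_levels[ph])
      best <- which(d == min(d))
      best <- best[which.min(cand$time[best])]    # tie -> earliest
      sel_pos[p, ph] <- cand$true_position[best]
    }
  }
  apex_raw <- apply(sel_pos, 2, max)
  q <- geometry$slice_thickness
  apex <- q * round(apex_raw / q)
  per_phase <- data.frame(
    phase_index = 1:10, phase_name = phase_names,
    apex_position = apex,
    relative_displacement = apex - apex[6],
    lung_volume = geometry$lung_volume_at_eoe + geometry$volume_per_mm *
      (apex - geometry$diaphragm_base_position)
  )
  structure(list(per_phase = per_phase, geometry = geometry),
            class = "phase4d_result")
}

#' @export
print.phase4d_result <- function(x, ...) {
  cat("<phase4d_result>\n")
  print(x$per_phase, row.names = FALSE)
  invisible(x)
}

#' Per-phase mismatch between two sortings of the same acquisition
#'
#' Single-phase differences (A - B) in lung volume (as percent of B's
#' volume) and in diaphragm apex position (mm), with the min/max range over
#' the ten phases.
#'
#' @param result_a,result_b [reconstruct_phases()] results sharing a
#'   geometry.
#' @return An object of class `mismatch_report`: data.frame `per_phase` and
#'   ranges `volume_diff_pct_range`, `position_diff_range`.
#' @export
compare_sortings <- function(result_a, result_b) {
  pa <- result_a$per_phase
  pb <- result_b$per_phase
  vol_pct <- 100 * (pa$lung_volume - pb$lung_volume) / pb$lung_volume
  pos <- pa$apex_position - pb$apex_position
  per_phase <- data.frame(phase_index = 1:10, phase_name = phase_names,
                          volume_diff_pct = vol_pct, position_diff = pos)
  structure(list(per_phase = per_phase,
                 volume_diff_pct_range = range(vol_pct),
                 position_diff_range = range(pos)),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf("<mismatch_report> volume diff %% range (%.2f, %.2f); position diff range (%.1f, %.1f) mm\n",
              x$volume_diff_pct_range[1], x$volume_diff_pct_range[2],
              x$position_diff_range[1], x$position_diff_range[2]))
  invisible(x)
}
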