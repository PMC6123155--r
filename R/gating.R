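#' Gating window definition
#'
#' Amplitude mode enables the beam while the surrogate amplitude lies in
#' `[lower, upper]` (0-100 normalized units); phase mode enables it for
#' samples sorted into the listed phase indices.
#'
#' @param mode `"amplitude"` or `"phase"`.
#' @param lower,upper Amplitude bounds (amplitude mode).
#' @param phases Integer phase indices 1-10 (phase mode).
#' @param defined_on Free-text identifier of the surrogate the window was
#'   planned on.
#' @return An object of class `gating_window`.
#' @export
gating_window <- function(mode = c("amplitude", "phase"), lower = NULL,
                          upper = NULL, phases = NULL, defined_on = "") {
  mode <- match.arg(mode)
  if (mode == "amplitude") {
    if (is.null(lower) || is.null(upper) || !(lower < upper))
      stop("gating_window: amplitude mode needs lower < upper", call. = FALSE)
  } else {
    if (is.null(phases) || length(phases) == 0 ||
        !all(phases %in% 1:10))
      stop("gating_window: phase mode needs a non-empty subset of 1:10",
           call. = FALSE)
  }
  structure(list(mode = mode, lower = lower, upper = upper,
                 phases = sort(unique(phases)), defined_on = defined_on),
            class = "gating_window")
}

# merge a per-sample logical mask into half-open [t_i, t_{i+1}) intervals
mask_to_intervals <- function(time, on) {
  n <- length(time)
  if (!any(on)) return(matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("on", "off"))))
  dt <- if (n > 1) stats::median(diff(time)) else 0
  edges <- diff(c(FALSE, on, FALSE))
  starts <- which(edges == 1)
  stops <- which(edges == -1)          # first index past the run
  off_t <- ifelse(stops > n, time[n] + dt, time[pmin(stops, n)])
  cbind(on = time[starts], off = off_t)
}

interval_total <- function(iv) if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

interval_intersect_total <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}

#' Apply a gating window to a surrogate trace
#'
#' Returns the beam-on time set: the union of maximal half-open intervals
#' (on the sample grid) where the gate condition holds.  A window lying
#' outside the signal range yields an empty set with a warning.
#'
#' @param window A [gating_window()].
#' @param surrogate A [resp_trace()]; normalize to 0-100 first for amplitude
#'   mode.
#' @param sorted Optional [assign_phases()] result (phase mode); computed
#'   with default extrema detection when needed.
#' @return An object of class `beam_on_set`: `intervals` (matrix),
#'   `duty_cycle`, `total_time`, plus the sample grid `time` and mask `on`.
#' @export
apply_gate <- function(window, surrogate, sorted = NULL) {
  stopifnot_trace(surrogate, "surrogate")
  t <- surrogate$time
  if (window$mode == "amplitude") {
    on <- surrogate$amplitude >= window$lower &
      surrogate$amplitude <= window$upper
  } else {
    if (is.null(sorted)) {
      ex <- detect_extrema(normalize_global(surrogate))
      sorted <- assign_phases(surrogate, ex)
    }
    on <- rep(FALSE, length(t))
    keep <- sorted$phase_index %in% window$phases
    on[match(round(sorted$time[keep], 9), round(t, 9))] <- TRUE
    on[is.na(on)] <- FALSE
  }
  if (!any(on))
    warning("apply_gate: gate never opens on this trace", call. = FALSE)
  iv <- mask_to_intervals(t, on)
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  total <- (max(t) - min(t)) + dt
  structure(list(intervals = iv, duty_cycle = interval_total(iv) / total,
                 total_time = total, time = t, on = on),
            class = "beam_on_set")
}

#' Gating-window mismatch between a planning and a delivery surrogate
#'
#' The same window is applied to the surrogate it was designed on and to the
#' surrogate monitoring delivery; the two beam-on time sets are compared by
#' their Jaccard overlap (intersection over union of total on-time), and the
#' residual internal motion (range of the internal-trace-implied diaphragm
#' position, in mm) is measured within each beam-on set.
#'
#' @param window A [gating_window()].
#' @param design_surrogate,applied_surrogate [resp_trace()]s sharing the
#'   time axis (normalized 0-100 for amplitude mode).
#' @param internal Internal-motion [resp_trace()] on the same time axis.
#' @param excursion_mm Diaphragm excursion corresponding to the internal
#'   trace's full amplitude range; default 20 mm.
#' @return An object of class `gating_mismatch`: `duty_cycle_design`,
#'   `duty_cycle_applied`, `beam_interval_overlap`,
#'   `residual_motion_design`, `residual_motion_applied` (mm).
#' @export
gating_mismatch <- function(window, design_surrogate, applied_surrogate,
                            internal, excursion_mm = 20) {
  gd <- apply_gate(window, design_surrogate)
  ga <- apply_gate(window, applied_surrogate)
  if (interval_total(gd$intervals) == 0)
    stop("gating_mismatch: design beam-on set is empty", call. = FALSE)
  inter <- interval_intersect_total(gd$intervals, ga$intervals)
  uni <- interval_total(gd$intervals) + interval_total(ga$intervals) - inter
  overlap <- if (uni > 0) inter / uni else 0

  r <- range(internal$amplitude)
  pos <- if (diff(r) > 0)
    excursion_mm * (internal$amplitude - r[1]) / diff(r)
  else rep(0, length(internal$amplitude))
  residual <- function(iv) {
    if (nrow(iv) == 0) return(NA_real_)
    inside <- rep(FALSE, length(internal$time))
    for (i in seq_len(nrow(iv)))
      inside <- inside | (internal$time >= iv[i, 1] &
                            internal$time < iv[i, 2])
    if (!any(inside)) return(NA_real_)
    diff(range(pos[inside]))
  }
  structure(list(duty_cycle_design = gd$duty_cycle,
                 duty_cycle_applied = ga$duty_cycle,
                 beam_interval_overlap = overlap,
                 residual_motion_design = residual(gd$intervals),
                 residual_motion_applied = residual(ga$intervals)),
            class = "gating_mismatch")
}

#' @export
print.gating_mismatch <- function(x, ...) {
  cat(sprintf("<gating_mismatch> duty design %.3f / applied %.3f; overlap %.3f\n",
              x$duty_cycle_design, x$duty_cycle_applied,
              x$beam_interval_overlap))
  cat(sprintf("  residual motion: design %.1f mm, applied %.1f mm\n",
              x$residual_motion_design, x$residual_motion_applied))
  invisible(x)
}
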