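#' Ten-phase labels of local amplitude sorting
#'
#' Phase indices 1-10 correspond to 100%Ex, 80%Ex, 60%Ex, 40%Ex, 20%Ex,
#' 0%In, 20%In, 40%In, 60%In, 80%In: index 1 is the end of inhalation (peak,
#' start of the exhale limb), index 6 the end of exhalation (valley).
#'
#' @format Character vector of length 10, names `1`-`10`.
#' @export
phase_names <- c("100%Ex", "80%Ex", "60%Ex", "40%Ex", "20%Ex",
                 "0%In", "20%In", "40%In", "60%In", "80%In")

# nominal amplitude-fraction level of each phase on its limb
phase_levels <- c(1.0, 0.8, 0.6, 0.4, 0.2, 0.0, 0.2, 0.4, 0.6, 0.8)
exhale_phases <- 1:6
inhale_phases <- 6:10

# Nearest-nominal-level binning on one limb. Ties at bin midpoints go to the
# first (lower-index) phase of the pair. Isolated behind this function so an
# interval-bin convention would be a one-line swap.
bin_fraction <- function(f, limb) {
  phases <- if (limb == "exhale") exhale_phases else inhale_phases
  vapply(f, function(fi) phases[which.min(abs(phase_levels[phases] - fi))],
         integer(1))
}

#' Local-amplitude phase sorting of a trace
#'
#' Assigns every sample inside a complete half-cycle to one of ten
#' respiratory phases.  A sample between an EOI and the next EOE lies on the
#' exhale limb; between an EOE and the next EOI on the inhale limb (the EOI
#' sample itself opens the exhale limb and is phase 1, the EOE sample opens
#' the inhale limb and is phase 6).  Its amplitude fraction
#' `f = (a - a_EOE) / (a_EOI - a_EOE)` uses the limb's own flanking EOE, so
#' baseline drift between successive EOEs is handled locally.  The phase is
#' the one whose nominal level (1.0, 0.8, ... on the exhale limb; 0.0, 0.2,
#' ... on the inhale limb) is nearest to `f`.
#'
#' Fractions up to 0.02 outside `[0, 1]` (noise overshooting the local
#' extrema) are clamped with a warning; samples further out are excluded with
#' a warning, as are samples before the first or after the last detected
#' extremum.
#'
#' @param trace A [resp_trace()].
#' @param extrema A [detect_extrema()] result for it.
#' @param clamp_tol Overshoot tolerance on the amplitude fraction.
#' @return data.frame of class `sorted_samples`: `time`, `amplitude`,
#'   `fraction`, `limb`, `phase_index`, `phase_name`, `cycle_id`.
#' @export
assign_phases <- function(trace, extrema, clamp_tol = 0.02) {
  stopifnot_trace(trace)
  t <- trace$time
  a <- trace$amplitude
  ev_idx <- sort(c(extrema$eoi_indices, extrema$eoe_indices))
  ev_type <- ifelse(ev_idx %in% extrema$eoi_indices, "EOI", "EOE")
  if (length(ev_idx) < 2)
    stop("assign_phases: need at least 2 extrema", call. = FALSE)

  out <- vector("list", length(ev_idx) - 1L)
  cycle_id <- 0L
  n_clamped <- 0L
  n_dropped <- 0L
  for (k in seq_len(length(ev_idx) - 1L)) {
    i0 <- ev_idx[k]; i1 <- ev_idx[k + 1L]
    if (ev_type[k] == ev_type[k + 1L]) next   # malformed alternation; skip
    limb <- if (ev_type[k] == "EOI") "exhale" else "inhale"
    if (ev_type[k] == "EOE") cycle_id <- cycle_id + 1L
    # limb samples: [event_k, event_{k+1}); the closing event opens the next
    # limb (EOI -> phase 1 there, EOE -> phase 6 there)
    seg <- i0:(i1 - 1L)
    a_eoi <- if (limb == "exhale") a[i0] else a[i1]
    a_eoe <- if (limb == "exhale") a[i1] else a[i0]
    denom <- a_eoi - a_eoe
    if (denom <= 0) next
    f <- (a[seg] - a_eoe) / denom
    drop <- f < -clamp_tol | f > 1 + clamp_tol
    n_dropped <- n_dropped + sum(drop)
    n_clamped <- n_clamped + sum(!drop & (f < 0 | f > 1))
    f <- pmin(pmax(f, 0), 1)
    keep <- !drop
    if (!any(keep)) next
    ph <- bin_fraction(f[keep], limb)
    out[[k]] <- data.frame(time = t[seg][keep], amplitude = a[seg][keep],
                           fraction = f[keep], limb = limb,
                           phase_index = ph, phase_name = phase_names[ph],
                           cycle_id = max(cycle_id, 1L),
                           stringsAsFactors = FALSE)
  }
  # the final extremum sample closes the last limb; assign it by its type
  last_i <- ev_idx[length(ev_idx)]
  last_type <- ev_type[length(ev_type)]
  out[[length(ev_idx)]] <- data.frame(
    time = t[last_i], amplitude = a[last_i],
    fraction = if (last_type == "EOI") 1 else 0,
    limb = if (last_type == "EOI") "exhale" else "inhale",
    phase_index = if (last_type == "EOI") 1L else 6L,
    phase_name = phase_names[if (last_type == "EOI") 1L else 6L],
    cycle_id = max(cycle_id, 1L), stringsAsFactors = FALSE)
  if (n_clamped > 0)
    warning(sprintf("assign_phases: %d fractions clamped into [0, 1]",
                    n_clamped), call. = FALSE)
  if (n_dropped > 0)
    warning(sprintf("assign_phases: %d samples beyond clamp tolerance excluded",
                    n_dropped), call. = FALSE)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$time), ]
  rownames(res) <- NULL
  class(res) <- c("sorted_samples", class(res))
  res
}

#' Per-phase occupancy of sorted samples
#'
#' Counts samples (and their total dwell time) per phase; empty phases are
#' flagged, since a phase with no data cannot be reconstructed (the
#' data-sufficiency condition fails there).
#'
#' @param sorted An [assign_phases()] result.
#' @param dt Sample dwell time in seconds; default the median time step.
#' @return data.frame with `phase_index`, `phase_name`, `n_samples`,
#'   `time_coverage`, `empty`.
#' @export
phase_occupancy <- function(sorted, dt = NULL) {
  if (nrow(sorted) == 0)
    stop("phase_occupancy: empty input", call. = FALSE)
  if (is.null(dt))
    dt <- stats::median(diff(sort(unique(sorted$time))))
  counts <- vapply(1:10, function(p) sum(sorted$phase_index == p), integer(1))
  data.frame(phase_index = 1:10, phase_name = phase_names,
             n_samples = counts, time_coverage = counts * dt,
             empty = counts == 0L)
}
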