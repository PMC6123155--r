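#' Renormalize a trace to the 0-100 range of its entire span
#'
#' Affine map sending the global minimum to 0 and the global maximum to 100.
#' Note that normalizing each surrogate by its own global range can enlarge
#' apparent depth differences between two traces; this mirrors standard
#' whole-trace renormalization practice and is deliberately not corrected.
#'
#' @param trace A [resp_trace()].
#' @return The normalized trace.  The generating-model attribute, if any, is
#'   dropped (its amplitude scale no longer applies); ground-truth marks are
#'   kept.
#' @export
normalize_global <- function(trace) {
  stopifnot_trace(trace)
  r <- range(trace$amplitude)
  if (diff(r) == 0)
    stop("normalize_global: constant trace has no amplitude range",
         call. = FALSE)
  trace$amplitude <- 100 * (trace$amplitude - r[1]) / diff(r)
  attr(trace, "model") <- NULL
  trace
}

#' End-of-inhale / end-of-exhale detection
#'
#' Finds the peaks (EOI) and valleys (EOE) of a breathing trace by an
#' exhaustive moving-window scan: a sample is a peak candidate if no sample
#' within `window / 2` seconds on either side exceeds it, and no earlier
#' sample within the window ties it (plateau ties go to the earliest sample).
#' Candidates are then forced to alternate (keeping the more extreme of any
#' same-type run) and adjacent peak-valley pairs closer in amplitude than
#' `min_prominence` are pruned.  When `window` is `NULL` a two-pass scheme is
#' used: a conservative 1 s window estimates the median inter-peak gap, and
#' the final window is 0.4 of that gap, honoring the requirement that the
#' search range stay below half a breathing period.
#'
#' The `override` argument is the programmatic analogue of dragging a
#' misplaced extremum marker by hand: each `(time, label)` row replaces the
#' detected extremum nearest in time with one at the sample nearest `time`.
#'
#' @param trace A [resp_trace()], normally 0-100 normalized.
#' @param window Search window in seconds, or `NULL` for the two-pass default.
#' @param min_prominence Minimum peak-to-valley amplitude difference
#'   (0-100 units) for a pair to survive; default 10.
#' @param override Optional data.frame with columns `time`, `label`
#'   (`"EOI"`/`"EOE"`).
#' @return An object of class `extrema_set`: list with `eoi_times`,
#'   `eoe_times`, `eoi_indices`, `eoe_indices`, `search_window`.
#' @export
detect_extrema <- function(trace, window = NULL, min_prominence = 10,
                           override = NULL) {
  stopifnot_trace(trace)
  if (is.null(window)) {
    first <- detect_extrema(trace, window = 1, min_prominence = min_prominence)
    gaps <- diff(first$eoi_times)
    window <- if (length(gaps) > 0) 0.4 * stats::median(gaps) else 1
  }
  if (window <= 0) stop("detect_extrema: window must be > 0", call. = FALSE)
  a <- trace$amplitude
  t <- trace$time
  n <- length(a)
  dt <- if (n > 1) stats::median(diff(t)) else Inf
  hw <- max(1L, floor((window / 2) / dt))

  cand <- scan_window_extrema(a, hw)
  ext <- prune_alternate(cand$idx, cand$type, a, min_prominence)

  if (length(ext$idx) == 0)
    stop("detect_extrema: no extrema found", call. = FALSE)

  if (!is.null(override) && nrow(override) > 0) {
    for (r in seq_len(nrow(override))) {
      tt <- override$time[r]
      lab <- override$label[r]
      j <- which.min(abs(t[ext$idx] - tt))
      ext$idx[j] <- which.min(abs(t - tt))
      ext$type[j] <- lab
    }
    o <- order(ext$idx)
    ext$idx <- ext$idx[o]
    ext$type <- ext$type[o]
    ext <- prune_alternate(ext$idx, ext$type, a, 0)
  }

  eoi <- ext$idx[ext$type == "EOI"]
  eoe <- ext$idx[ext$type == "EOE"]
  if (length(eoi) > 1) {
    med_T <- stats::median(diff(t[eoi]))
    if (is.finite(med_T) && window >= med_T / 2)
      warning("detect_extrema: window >= half the median breathing period",
              call. = FALSE)
  }
  structure(list(eoi_times = t[eoi], eoe_times = t[eoe],
                 eoi_indices = eoi, eoe_indices = eoe,
                 search_window = window),
            class = "extrema_set")
}

# Window-max/min candidate scan. A sample i is a max candidate iff its full
# window [i-hw, i+hw] lies inside the trace (a truncated window cannot
# certify an extremum), no j in the window has a[j] > a[i], and no j < i in
# the window ties a[i] (plateaus keep their earliest sample).
scan_window_extrema <- function(a, hw) {
  n <- length(a)
  idx <- integer(0)
  type <- character(0)
  if (n < 2 * hw + 1) return(list(idx = idx, type = type))
  for (i in (hw + 1L):(n - hw)) {
    lo <- i - hw
    hi <- i + hw
    w <- a[lo:hi]
    left <- if (i > lo) a[lo:(i - 1L)] else numeric(0)
    if (a[i] >= max(w) && !any(left >= a[i])) {
      idx <- c(idx, i); type <- c(type, "EOI")
    } else if (a[i] <= min(w) && !any(left <= a[i])) {
      idx <- c(idx, i); type <- c(type, "EOE")
    }
  }
  list(idx = idx, type = type)
}

# Enforce strict EOI/EOE alternation, then iteratively drop the adjacent
# alternating pair with the smallest amplitude swing while it is below the
# prominence floor.  Deterministic: same-type runs keep the most extreme
# member (earliest on ties); the weakest pair is removed first.
prune_alternate <- function(idx, type, a, min_prominence) {
  collapse <- function(idx, type) {
    if (length(idx) == 0) return(list(idx = idx, type = type))
    keep_idx <- idx[1]; keep_type <- type[1]
    for (j in seq_along(idx)[-1]) {
      last <- length(keep_idx)
      if (type[j] == keep_type[last]) {
        better <- if (type[j] == "EOI") a[idx[j]] > a[keep_idx[last]]
                  else a[idx[j]] < a[keep_idx[last]]
        if (better) keep_idx[last] <- idx[j]
      } else {
        keep_idx <- c(keep_idx, idx[j])
        keep_type <- c(keep_type, type[j])
      }
    }
    list(idx = keep_idx, type = keep_type)
  }
  cur <- collapse(idx, type)
  if (min_prominence > 0) {
    repeat {
      m <- length(cur$idx)
      if (m < 2) break
      swings <- abs(a[cur$idx[-1]] - a[cur$idx[-m]])
      if (all(swings >= min_prominence)) break
      j <- which.min(swings)
      keep <- setdiff(seq_len(m), c(j, j + 1L))
      cur <- collapse(cur$idx[keep], cur$type[keep])
    }
  }
  cur
}

#' Segment a trace into breathing cycles
#'
#' One cycle per EOE-to-EOE span containing exactly one EOI.  The period of
#' record (`period_T`) is the EOI-to-EOI time difference to the next cycle's
#' EOI (`NA` for the last cycle); the EOE-to-EOE span (`period_eoe`) is also
#' reported, since shape extraction works on that span.  Depth is the
#' amplitude increment from the preceding EOE to the EOI.
#'
#' @param trace A [resp_trace()] (use the normalized trace for 0-100 depths).
#' @param extrema An [detect_extrema()] result for the same trace.
#' @return A data.frame of class `breathing_cycles` with one row per cycle:
#'   `start_eoe_time`, `eoi_time`, `end_eoe_time`, `period_T`, `period_eoe`,
#'   `depth_d`, plus attribute `eoi_periods` (the raw EOI-to-EOI diffs).
#' @export
segment_cycles <- function(trace, extrema) {
  stopifnot_trace(trace)
  if (length(extrema$eoi_times) < 2)
    stop("segment_cycles: need at least 2 EOI points", call. = FALSE)
  t <- trace$time
  a <- trace$amplitude
  rows <- list()
  for (k in seq_len(length(extrema$eoe_times) - 1)) {
    s <- extrema$eoe_times[k]
    e <- extrema$eoe_times[k + 1]
    inside <- which(extrema$eoi_times > s & extrema$eoi_times < e)
    if (length(inside) != 1) next
    eoi_t <- extrema$eoi_times[inside]
    nxt <- which(extrema$eoi_times > eoi_t)
    rows[[length(rows) + 1]] <- data.frame(
      start_eoe_time = s, eoi_time = eoi_t, end_eoe_time = e,
      period_T = if (length(nxt) > 0) extrema$eoi_times[nxt[1]] - eoi_t
                 else NA_real_,
      period_eoe = e - s,
      depth_d = a[extrema$eoi_indices[inside]] - a[extrema$eoe_indices[k]]
    )
  }
  if (length(rows) == 0)
    stop("segment_cycles: no complete EOE-EOI-EOE cycles", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "eoi_periods") <- diff(extrema$eoi_times)
  class(out) <- c("breathing_cycles", class(out))
  out
}

# Nearest-EOI one-to-one pairing of two cycle sets, within half the local
# period. Returns index pairs (ia, ib).
pair_cycles <- function(a, b, tol_frac = 0.5) {
  ta <- a$eoi_time
  tb <- b$eoi_time
  used <- rep(FALSE, length(tb))
  ia <- integer(0); ib <- integer(0)
  for (i in seq_along(ta)) {
    local_T <- if (!is.na(a$period_T[i])) a$period_T[i]
               else stats::median(a$period_T, na.rm = TRUE)
    j_free <- which(!used)
    if (length(j_free) == 0) break
    j <- j_free[which.min(abs(tb[j_free] - ta[i]))]
    if (abs(tb[j] - ta[i]) <= tol_frac * local_T) {
      used[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  list(ia = ia, ib = ib)
}

#' Per-cycle period and depth statistics for a matched trace pair
#'
#' Cycles of the two traces are paired one-to-one by nearest EOI time within
#' half the local period.  Summary statistics (mean +/- SD of period and
#' depth for each trace over its own cycles) and per-pair difference ranges
#' (min, max of `T_a - T_b` and `d_a - d_b`) are returned.
#'
#' @param a,b [segment_cycles()] results for the two traces.
#' @return An object of class `cycle_stats`.
#' @export
paired_cycle_stats <- function(a, b) {
  pr <- pair_cycles(a, b)
  n_pairs <- length(pr$ia)
  unmatched <- 1 - n_pairs / max(length(a$eoi_time), length(b$eoi_time))
  if (n_pairs < 1 || unmatched > 0.2)
    stop(sprintf(
      "paired_cycle_stats: %.0f%% of cycles unmatched; traces not comparable",
      100 * unmatched), call. = FALSE)
  dT <- a$period_T[pr$ia] - b$period_T[pr$ib]
  dd <- a$depth_d[pr$ia] - b$depth_d[pr$ib]
  dT <- dT[!is.na(dT)]
  structure(list(
    n_cycles = n_pairs,
    period_mean_a = mean(a$period_T, na.rm = TRUE),
    period_sd_a = stats::sd(a$period_T, na.rm = TRUE),
    period_mean_b = mean(b$period_T, na.rm = TRUE),
    period_sd_b = stats::sd(b$period_T, na.rm = TRUE),
    depth_mean_a = mean(a$depth_d), depth_sd_a = stats::sd(a$depth_d),
    depth_mean_b = mean(b$depth_d), depth_sd_b = stats::sd(b$depth_d),
    period_diff_range = if (length(dT)) range(dT) else c(NA_real_, NA_real_),
    depth_diff_range = range(dd),
    pairs = data.frame(ia = pr$ia, ib = pr$ib)
  ), class = "cycle_stats")
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat(sprintf("<cycle_stats> %d matched cycles\n", x$n_cycles))
  cat(sprintf("  T: %.2f +/- %.2f s (a) vs %.2f +/- %.2f s (b); diff range (%.2f, %.2f)\n",
              x$period_mean_a, x$period_sd_a, x$period_mean_b, x$period_sd_b,
              x$period_diff_range[1], x$period_diff_range[2]))
  cat(sprintf("  d: %.1f +/- %.1f (a) vs %.1f +/- %.1f (b); diff range (%.1f, %.1f)\n",
              x$depth_mean_a, x$depth_sd_a, x$depth_mean_b, x$depth_sd_b,
              x$depth_diff_range[1], x$depth_diff_range[2]))
  invisible(x)
}

#' Whole-trace linear correlation between two surrogates
#'
#' Both traces are linearly interpolated onto a common uniform grid at the
#' finer of the two sampling rates, restricted to the overlap of their time
#' ranges, and the Pearson correlation coefficient is computed.
#'
#' @param a,b [resp_trace()]s sharing a time origin.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
trace_correlation <- function(a, b) {
  stopifnot_trace(a, "a"); stopifnot_trace(b, "b")
  lo <- max(min(a$time), min(b$time))
  hi <- min(max(a$time), max(b$time))
  dt <- 1 / max(a$sampling_rate, b$sampling_rate)
  if (!(hi - lo > dt))
    stop("trace_correlation: traces overlap by fewer than 2 samples",
         call. = FALSE)
  g <- seq(lo, hi, by = dt)
  av <- stats::approx(a$time, a$amplitude, xout = g)$y
  bv <- stats::approx(b$time, b$amplitude, xout = g)$y
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("trace_correlation: zero variance on the common grid", call. = FALSE)
  stats::cor(av, bv)
}
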