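#' Respiratory surrogate trace
#'
#' `resp_trace` is the common currency of the package: a uniformly sampled
#' 1-D respiratory signal with a shared time origin (t = 0 is the
#' acquisition trigger common to both monitoring systems), optional per-sample
#' beam-on state and optional per-sample extremum marks.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param amplitude Numeric vector, same length as `time`; marker displacement
#'   or relative belt pressure in arbitrary units.
#' @param beam_on Logical vector, same length; `TRUE` while the scanner /
#'   treatment beam is on. Defaults to all `FALSE`.
#' @param mark Character vector, same length, each element one of `""`,
#'   `"EOI"` (end of inhalation, a peak) or `"EOE"` (end of exhalation, a
#'   valley). Defaults to all `""`.
#' @param source_kind `"displacement"` (marker block) or `"pressure"` (belt).
#' @param sampling_rate Nominal sampling rate in Hz; inferred from the median
#'   timestep when `NULL`.
#' @return An object of class `resp_trace`: a list with the validated fields
#'   above.
#' @export
resp_trace <- function(time, amplitude, beam_on = NULL, mark = NULL,
                       source_kind = c("displacement", "pressure"),
                       sampling_rate = NULL) {
  source_kind <- match.arg(source_kind)
  time <- as.numeric(time)
  amplitude <- as.numeric(amplitude)
  n <- length(time)
  if (n < 1L) stop("resp_trace: empty trace", call. = FALSE)
  if (length(amplitude) != n)
    stop("resp_trace: time and amplitude lengths differ", call. = FALSE)
  if (n > 1L && any(diff(time) <= 0))
    stop("resp_trace: timestamps must be strictly increasing", call. = FALSE)
  if (is.null(beam_on)) beam_on <- rep(FALSE, n)
  if (is.null(mark)) mark <- rep("", n)
  beam_on <- as.logical(beam_on)
  mark <- as.character(mark)
  if (length(beam_on) != n || length(mark) != n)
    stop("resp_trace: per-sample field length mismatch", call. = FALSE)
  if (any(is.na(beam_on)))
    stop("resp_trace: beam_on contains NA", call. = FALSE)
  if (!all(mark %in% c("", "EOI", "EOE")))
    stop("resp_trace: mark values must be '', 'EOI' or 'EOE'", call. = FALSE)
  if (is.null(sampling_rate)) {
    sampling_rate <- if (n > 1L) 1 / stats::median(diff(time)) else NA_real_
  }
  structure(
    list(time = time, amplitude = amplitude, beam_on = beam_on, mark = mark,
         source_kind = source_kind, sampling_rate = sampling_rate),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %s, %d samples, %.3f-%.3f s, %.1f Hz nominal\n",
              x$source_kind, length(x$time), x$time[1],
              x$time[length(x$time)], x$sampling_rate))
  n_on <- sum(x$beam_on)
  cat(sprintf("  amplitude [%.3g, %.3g]; beam-on samples: %d; marks: %d EOI / %d EOE\n",
              min(x$amplitude), max(x$amplitude), n_on,
              sum(x$mark == "EOI"), sum(x$mark == "EOE")))
  invisible(x)
}

#' @export
as.data.frame.resp_trace <- function(x, ...) {
  data.frame(time = x$time, amplitude = x$amplitude, beam_on = x$beam_on,
             mark = x$mark, stringsAsFactors = FALSE)
}

#' @export
length.resp_trace <- function(x) length(x$time)

is_resp_trace <- function(x) inherits(x, "resp_trace")

stopifnot_trace <- function(x, what = "trace") {
  if (!is_resp_trace(x))
    stop(sprintf("%s must be a resp_trace object", what), call. = FALSE)
  invisible(x)
}

#' Beam-on segments of a trace
#'
#' Reduces the per-sample `beam_on` vector to an ordered two-column matrix of
#' half-open `[on, off)` intervals.  A trace that is still beam-on at its last
#' sample closes the segment one sampling step after that sample.
#'
#' @param trace A [resp_trace()].
#' @return Numeric matrix with columns `on`, `off` (seconds); zero rows when
#'   the beam never turns on.
#' @export
beam_segments <- function(trace) {
  stopifnot_trace(trace)
  b <- trace$beam_on
  t <- trace$time
  if (!any(b)) return(matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("on", "off"))))
  d <- diff(c(FALSE, b))
  on_idx <- which(d == 1)
  off_idx <- which(d == -1)
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  on_t <- t[on_idx]
  off_t <- t[off_idx]
  if (length(off_t) < length(on_t)) off_t <- c(off_t, t[length(t)] + dt)
  cbind(on = on_t, off = off_t)
}

#' Stamp beam-on intervals onto a trace
#'
#' Marks each sample beam-on iff its timestamp lies inside one of the given
#' half-open `[on, off)` intervals.
#'
#' @param trace A [resp_trace()].
#' @param segments Two-column matrix of `(on, off)` times in seconds, or a
#'   [scan_timeline()].
#' @return The trace with `beam_on` replaced.
#' @export
stamp_beam <- function(trace, segments) {
  stopifnot_trace(trace)
  if (inherits(segments, "scan_timeline")) segments <- segments$beam_segments
  segments <- as.matrix(segments)
  on <- rep(FALSE, length(trace$time))
  if (nrow(segments) > 0) {
    for (k in seq_len(nrow(segments))) {
      on <- on | (trace$time >= segments[k, 1] & trace$time < segments[k, 2])
    }
  }
  trace$beam_on <- on
  trace
}

#' Resample a trace onto a new uniform grid by linear interpolation
#'
#' @param trace A [resp_trace()].
#' @param times New timestamps (seconds), within the trace's span.
#' @return A resp_trace on the new grid. Marks are not carried over; beam
#'   state is resampled by segment membership.
#' @export
resample_trace <- function(trace, times) {
  stopifnot_trace(trace)
  amp <- stats::approx(trace$time, trace$amplitude, xout = times,
                       rule = 2)$y
  out <- resp_trace(times, amp, source_kind = trace$source_kind)
  stamp_beam(out, beam_segments(trace))
}

# Ground-truth bookkeeping for synthetic traces -------------------------------

trace_truth <- function(trace) attr(trace, "truth", exact = TRUE)

set_trace_truth <- function(trace, eoi_times, eoe_times) {
  attr(trace, "truth") <- list(eoi_times = eoi_times, eoe_times = eoe_times)
  # also set nearest-sample marks for plotting / export
  mk <- rep("", length(trace$time))
  near <- function(tt) vapply(tt, function(x) which.min(abs(trace$time - x)),
                              integer(1))
  if (length(eoe_times)) mk[near(eoe_times)] <- "EOE"
  if (length(eoi_times)) mk[near(eoi_times)] <- "EOI"
  trace$mark <- mk
  trace
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1664525 * as.double(k)) %% 2147483647)
}
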