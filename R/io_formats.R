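#' Trace file dialects
#'
#' Two plain-text dialects carry surrogate traces between tools.  Neither is
#' a claim about any vendor's binary format; they hold the *content* the
#' workflow needs (amplitude, timestamps, TTL beam events, extremum marks).
#'
#' `rpm_vxp_like`: `#`-prefixed header lines `version=1`,
#' `samples_per_second=<float>`, `scale_factor=<float>`, then one
#' comma-separated line per sample:
#' `amplitude,phase_placeholder,timestamp_ms,valid_flag,ttl_in,mark,ttl_out`.
#' `timestamp_ms` is an integer (so round trips are quantized to 1 ms),
#' `mark` is `""`, `Z` (EOE) or `P` (EOI), and `ttl_in`/`ttl_out` are 0/1
#' edge indicators set on the sample where the beam turns on / off.
#'
#' `anzai_csv_like`: header `time_s,pressure,ttl`; float seconds, float
#' pressure, and `ttl` the per-sample 0/1 beam state.
#'
#' @param name `"rpm_vxp_like"` or `"anzai_csv_like"`.
#' @return An object of class `file_dialect`.
#' @export
file_dialect <- function(name = c("rpm_vxp_like", "anzai_csv_like")) {
  name <- match.arg(name)
  structure(list(name = name), class = "file_dialect")
}

dialect_of <- function(x) {
  if (inherits(x, "file_dialect")) return(x$name)
  match.arg(x, c("rpm_vxp_like", "anzai_csv_like"))
}

fmt_amp <- function(x) sprintf("%.6f", x)

#' Read a surrogate trace file
#'
#' @param path File path.
#' @param dialect A [file_dialect()] or its name.
#' @return A [resp_trace()].
#' @export
read_trace <- function(path, dialect) {
  name <- dialect_of(dialect)
  lines <- readLines(path)
  if (name == "rpm_vxp_like") read_rpm_like(lines, path)
  else read_anzai_like(lines, path)
}

read_rpm_like <- function(lines, path) {
  is_header <- grepl("^#", lines)
  header <- lines[is_header]
  body <- lines[!is_header]
  body <- body[nzchar(body)]
  if (length(body) == 0)
    stop(sprintf("read_trace: empty data section in %s", path), call. = FALSE)
  get_hdr <- function(key, default = NA_real_) {
    hit <- grep(paste0("^#", key, "="), header, value = TRUE)
    if (length(hit) == 0) return(default)
    as.numeric(sub(paste0("^#", key, "="), "", hit[1]))
  }
  fs <- get_hdr("samples_per_second")
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 7L)
  if (length(bad) > 0)
    stop(sprintf("read_trace: malformed row at data line %d of %s",
                 bad[1], path), call. = FALSE)
  m <- do.call(rbind, parts)
  amp <- as.numeric(m[, 1])
  ts_ms <- as.numeric(m[, 3])
  if (anyNA(amp) || anyNA(ts_ms))
    stop(sprintf("read_trace: non-numeric field in %s", path), call. = FALSE)
  time <- ts_ms / 1000
  if (length(time) > 1 && any(diff(time) <= 0))
    stop(sprintf("read_trace: non-monotone timestamps in %s", path),
         call. = FALSE)
  ttl_in <- m[, 5] == "1"
  mark_raw <- m[, 6]
  ttl_out <- m[, 7] == "1"
  beam <- ttl_edges_to_state(ttl_in, ttl_out)
  mark <- ifelse(mark_raw == "P", "EOI", ifelse(mark_raw == "Z", "EOE", ""))
  resp_trace(time, amp, beam_on = beam, mark = mark,
             source_kind = "displacement",
             sampling_rate = if (is.na(fs)) NULL else fs)
}

# Reconstruct the per-sample beam state from on/off edge indicators.  A
# ttl_in with no matching ttl_out before EOF leaves the beam on through the
# final sample (with a warning): the file simply ended mid-segment.
ttl_edges_to_state <- function(ttl_in, ttl_out) {
  n <- length(ttl_in)
  state <- logical(n)
  on <- FALSE
  for (i in seq_len(n)) {
    if (ttl_out[i]) on <- FALSE
    if (ttl_in[i]) on <- TRUE
    state[i] <- on
  }
  if (on) warning("read_trace: beam on at end of file (ttl_in without ttl_out)",
                  call. = FALSE)
  state
}

read_anzai_like <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1 || lines[1] != "time_s,pressure,ttl")
    stop(sprintf("read_trace: missing 'time_s,pressure,ttl' header in %s",
                 path), call. = FALSE)
  body <- lines[-1]
  if (length(body) == 0)
    stop(sprintf("read_trace: empty data section in %s", path), call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad) > 0)
    stop(sprintf("read_trace: malformed row at data line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  m <- do.call(rbind, parts)
  time <- as.numeric(m[, 1])
  amp <- as.numeric(m[, 2])
  if (anyNA(time) || anyNA(amp))
    stop(sprintf("read_trace: non-numeric field in %s", path), call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop(sprintf("read_trace: non-monotone timestamps in %s", path),
         call. = FALSE)
  resp_trace(time, amp, beam_on = m[, 3] == "1", source_kind = "pressure")
}

#' Write a surrogate trace file
#'
#' Writing is byte-stable: `write_trace(read_trace(f))` reproduces `f`
#' exactly, and `read_trace(write_trace(t))` recovers timestamps to the
#' dialect's stored precision (1 ms for the displacement dialect, full float
#' precision for the CSV dialect), amplitudes to 1e-6 and beam markers
#' exactly.  A dialect/source-kind mismatch is allowed: conversion between
#' kinds is explicit via [convert_pressure_to_displacement()].
#'
#' @param trace A [resp_trace()].
#' @param path Output path.
#' @param dialect A [file_dialect()] or its name.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, dialect) {
  stopifnot_trace(trace)
  name <- dialect_of(dialect)
  if (name == "rpm_vxp_like") {
    b <- trace$beam_on
    d_on <- diff(c(FALSE, b)) == 1
    d_off <- c(diff(c(FALSE, b)) == -1)
    mark <- ifelse(trace$mark == "EOI", "P",
                   ifelse(trace$mark == "EOE", "Z", ""))
    lines <- c(
      "#version=1",
      sprintf("#samples_per_second=%g", trace$sampling_rate),
      "#scale_factor=1",
      sprintf("%s,0,%d,1,%d,%s,%d",
              fmt_amp(trace$amplitude), as.integer(round(trace$time * 1000)),
              as.integer(d_on), mark, as.integer(d_off))
    )
  } else {
    lines <- c("time_s,pressure,ttl",
               sprintf("%.6f,%s,%d", trace$time, fmt_amp(trace$amplitude),
                       as.integer(trace$beam_on)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert a pressure trace into the displacement file convention
#'
#' Re-labels a pressure-belt trace as displacement-file-compatible and
#' transfers the beam (TTL) markers from a reference displacement trace whose
#' recording was started by the same trigger: a pressure sample is beam-on
#' iff its timestamp lies inside one of the reference's half-open
#' `[on, off)` segments.  Timestamps and amplitudes of the pressure trace are
#' untouched.
#'
#' @param pressure A pressure-kind [resp_trace()].
#' @param reference A displacement-kind [resp_trace()] carrying beam markers.
#' @return A [resp_trace()] with `source_kind = "displacement"`.
#' @export
convert_pressure_to_displacement <- function(pressure, reference) {
  stopifnot_trace(pressure, "pressure")
  stopifnot_trace(reference, "reference")
  segs <- beam_segments(reference)
  if (max(pressure$time) < min(reference$time) ||
      min(pressure$time) > max(reference$time))
    stop("convert_pressure_to_displacement: time ranges do not overlap",
         call. = FALSE)
  out <- pressure
  out$source_kind <- "displacement"
  out <- stamp_beam(out, segs)
  out
}
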