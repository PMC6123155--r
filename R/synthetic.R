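#' Breathing model parameters
#'
#' Parameters for the quasi-periodic synthetic breathing generator.  The
#' waveform is a per-cycle raised-sine power: within a cycle of period T and
#' depth d running EOE-to-EOE, amplitude(u) = d * sin(pi * u)^(2 * n) for
#' cycle fraction u in [0, 1], where n = `plateau_exponent`.  n = 1 is a pure
#' raised cosine; n > 1 produces the end-of-exhale dwell typical of free
#' breathing.  Period and depth are redrawn each cycle from normal
#' distributions, a linear baseline drift and white Gaussian noise are added.
#'
#' @param mean_period Mean breathing period in seconds (> 0).
#' @param period_sd Cycle-to-cycle period SD in seconds (>= 0).
#' @param mean_depth Mean breathing depth in arbitrary amplitude units (> 0).
#' @param depth_sd Cycle-to-cycle depth SD, same units (>= 0).
#' @param plateau_exponent Dimensionless > 0; controls EOE dwell.
#' @param baseline_drift_rate Amplitude units per second.
#' @param noise_sd Additive Gaussian noise SD, amplitude units (>= 0).
#' @param sampling_rate Hz; must allow at least 10 samples per mean cycle.
#' @param duration Trace length in seconds; must cover >= 3 mean cycles.
#' @param seed Integer RNG seed.
#' @return An object of class `breathing_params`.
#' @export
breathing_params <- function(mean_period = 4, period_sd = 0.4,
                             mean_depth = 100, depth_sd = 10,
                             plateau_exponent = 1.5,
                             baseline_drift_rate = 0,
                             noise_sd = 0, sampling_rate = 25,
                             duration = 60, seed = 1L) {
  p <- list(mean_period = mean_period, period_sd = period_sd,
            mean_depth = mean_depth, depth_sd = depth_sd,
            plateau_exponent = plateau_exponent,
            baseline_drift_rate = baseline_drift_rate,
            noise_sd = noise_sd, sampling_rate = sampling_rate,
            duration = duration, seed = as.integer(seed))
  if (!(p$mean_period > 0))
    stop("breathing_params: mean_period must be > 0", call. = FALSE)
  if (p$period_sd < 0 || p$depth_sd < 0 || p$noise_sd < 0)
    stop("breathing_params: standard deviations must be >= 0", call. = FALSE)
  if (!(p$mean_depth > 0))
    stop("breathing_params: mean_depth must be > 0", call. = FALSE)
  if (!(p$plateau_exponent > 0))
    stop("breathing_params: plateau_exponent must be > 0", call. = FALSE)
  if (p$sampling_rate < 10 / p$mean_period)
    stop("breathing_params: sampling_rate must give >= 10 samples per cycle",
         call. = FALSE)
  if (p$duration < 3 * p$mean_period)
    stop("breathing_params: duration must cover >= 3 mean cycles",
         call. = FALSE)
  class(p) <- "breathing_params"
  p
}

#' Surrogate distortion parameters
#'
#' Describes how a surrogate system deviates from the internal motion it
#' samples: a pure time lag, per-limb monotone time warps that steepen or
#' flatten the inhalation / exhalation limbs, a pointwise monotone amplitude
#' nonlinearity, an affine gain/offset and extra sensor noise.
#'
#' @param lag Seconds.  Positive means the distorted surrogate reaches end of
#'   inhalation EARLIER than the source (the belt-leads-marker convention).
#' @param exhale_steepness Dimensionless >= 1; 1 leaves the exhalation limb
#'   unchanged, larger values make the post-EOI falloff steeper.
#' @param inhale_steepness Dimensionless > 0; 1 = unchanged; > 1 concentrates
#'   the inhalation rise just before EOI (steeper), < 1 flattens it.
#' @param response_exponent Dimensionless > 0 pointwise power law on the
#'   normalized amplitude; 1 = linear response.
#' @param extra_noise_sd Additional Gaussian noise SD, amplitude units.
#' @param gain,offset Affine output map `gain * a + offset`.
#' @return An object of class `surrogate_distortion`.
#' @export
surrogate_distortion <- function(lag = 0, exhale_steepness = 1,
                                 inhale_steepness = 1,
                                 response_exponent = 1,
                                 extra_noise_sd = 0, gain = 1, offset = 0) {
  d <- list(lag = lag, exhale_steepness = exhale_steepness,
            inhale_steepness = inhale_steepness,
            response_exponent = response_exponent,
            extra_noise_sd = extra_noise_sd, gain = gain, offset = offset)
  if (d$exhale_steepness < 1)
    stop("surrogate_distortion: exhale_steepness must be >= 1", call. = FALSE)
  if (!(d$inhale_steepness > 0))
    stop("surrogate_distortion: inhale_steepness must be > 0", call. = FALSE)
  if (!(d$response_exponent > 0))
    stop("surrogate_distortion: response_exponent must be > 0", call. = FALSE)
  if (d$extra_noise_sd < 0)
    stop("surrogate_distortion: extra_noise_sd must be >= 0", call. = FALSE)
  if (d$gain == 0)
    stop("surrogate_distortion: gain must be nonzero", call. = FALSE)
  class(d) <- "surrogate_distortion"
  d
}

identity_distortion <- function() surrogate_distortion()

#' Scanner beam timeline
#'
#' Ordered, non-overlapping beam-on intervals (the TTL-in / TTL-out events of
#' the CT acquisition), contained in `[scan_start, scan_stop]`.
#'
#' @param scan_start,scan_stop Seconds.
#' @param beam_segments Two-column matrix or list of `(on, off)` pairs.
#' @return An object of class `scan_timeline`.
#' @export
scan_timeline <- function(scan_start, scan_stop, beam_segments) {
  if (is.list(beam_segments))
    beam_segments <- do.call(rbind, lapply(beam_segments, as.numeric))
  beam_segments <- matrix(as.numeric(beam_segments), ncol = 2,
                          dimnames = list(NULL, c("on", "off")))
  if (nrow(beam_segments) > 0) {
    if (any(beam_segments[, 2] <= beam_segments[, 1]))
      stop("scan_timeline: each off time must exceed its on time",
           call. = FALSE)
    flat <- as.vector(t(beam_segments))
    if (any(diff(flat) < 0))
      stop("scan_timeline: segments must be ordered and non-overlapping",
           call. = FALSE)
    if (min(beam_segments) < scan_start || max(beam_segments) > scan_stop)
      stop("scan_timeline: segments must lie within [scan_start, scan_stop]",
           call. = FALSE)
  }
  structure(list(scan_start = scan_start, scan_stop = scan_stop,
                 beam_segments = beam_segments), class = "scan_timeline")
}

# Continuous breathing model --------------------------------------------------
#
# A realization of the cycle sequence: EOE boundaries `s` (extended two mean
# periods beyond both ends of the trace so that a lag shift never falls off
# the model), per-cycle periods and depths, plateau exponent, drift and a
# constant offset.  The model is carried on synthetic traces as an attribute
# so that distortions can re-evaluate it in continuous time.

realize_model <- function(params) {
  set.seed(derive_seed(params$seed, 1L))
  pad <- 2 * params$mean_period
  # draw enough cycles to span [-pad, duration + pad]
  span <- params$duration + 2 * pad
  n_guess <- ceiling(span / max(params$mean_period - 3 * params$period_sd,
                                0.3 * params$mean_period)) + 4L
  periods <- stats::rnorm(n_guess, params$mean_period, params$period_sd)
  periods <- pmax(periods, 0.3 * params$mean_period)
  while (sum(periods) < span) {
    extra <- pmax(stats::rnorm(4L, params$mean_period, params$period_sd),
                  0.3 * params$mean_period)
    periods <- c(periods, extra)
  }
  depths <- pmax(stats::rnorm(length(periods), params$mean_depth,
                              params$depth_sd), 0.1 * params$mean_depth)
  s <- -pad + c(0, cumsum(periods))
  list(boundaries = s, periods = periods, depths = depths,
       plateau = params$plateau_exponent,
       drift = params$baseline_drift_rate, offset = 0)
}

# Evaluate the noiseless model at arbitrary times.
eval_model <- function(model, t) {
  k <- findInterval(t, model$boundaries, rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), length(model$periods))
  u <- (t - model$boundaries[k]) / model$periods[k]
  u <- pmin(pmax(u, 0), 1)
  model$depths[k] * sin(pi * u)^(2 * model$plateau) +
    model$drift * t + model$offset
}

model_eoi_times <- function(model) {
  model$boundaries[-length(model$boundaries)] + model$periods / 2
}

truth_in_span <- function(times, lo, hi) times[times >= lo & times <= hi]

#' Generate synthetic internal respiratory motion
#'
#' Samples the continuous quasi-periodic breathing model on a uniform grid
#' and records the ground-truth EOI/EOE times.  The model realization is
#' attached to the returned trace so that [distort_to_surrogate()] can apply
#' lags and warps in continuous time (not quantized to the grid).
#'
#' @param params A [breathing_params()].
#' @return A [resp_trace()] (source_kind `"displacement"`) spanning
#'   `[0, duration]`, with ground-truth marks.
#' @export
generate_internal_motion <- function(params) {
  if (!inherits(params, "breathing_params"))
    params <- do.call(breathing_params, as.list(params))
  model <- realize_model(params)
  n <- floor(params$duration * params$sampling_rate) + 1L
  t <- (seq_len(n) - 1L) / params$sampling_rate
  amp <- eval_model(model, t)
  if (params$noise_sd > 0) {
    set.seed(derive_seed(params$seed, 2L))
    amp <- amp + stats::rnorm(n, 0, params$noise_sd)
  }
  tr <- resp_trace(t, amp, source_kind = "displacement",
                   sampling_rate = params$sampling_rate)
  tr <- set_trace_truth(tr,
                        eoi_times = truth_in_span(model_eoi_times(model), 0,
                                                  params$duration),
                        eoe_times = truth_in_span(model$boundaries, 0,
                                                  params$duration))
  attr(tr, "model") <- model
  attr(tr, "params") <- params
  tr
}

# Per-limb monotone warp of the cycle fraction u in [0, 1], EOI at u = 0.5.
# Exhale limb (u > 0.5): steepness s >= 1 maps x -> x^(1/s) of the fractional
# distance past EOI, pulling samples deeper into exhalation (faster falloff).
# Inhale limb mirrors it with exponent p: p > 1 concentrates the rise near
# EOI.  Both limbs are strictly increasing bijections of themselves, so the
# warp preserves EOE/EOI count, ordering and timing.
warp_fraction <- function(u, exhale_steepness, inhale_steepness) {
  w <- u
  ex <- u > 0.5
  if (any(ex)) {
    x <- (u[ex] - 0.5) / 0.5
    w[ex] <- 0.5 + 0.5 * x^(1 / exhale_steepness)
  }
  inh <- u < 0.5
  if (any(inh)) {
    y <- (0.5 - u[inh]) / 0.5
    w[inh] <- 0.5 - 0.5 * y^(1 / inhale_steepness)
  }
  w
}

#' Distort internal motion into a surrogate trace
#'
#' Applies, in order: a uniform time lag (by shifting the evaluation time of
#' the underlying continuous model), per-cycle limb warps between consecutive
#' ground-truth EOE boundaries, a pointwise response nonlinearity, gain and
#' offset, and extra Gaussian noise.  Any per-sample residual of the input
#' relative to its noiseless model (i.e. the input's own noise) is carried
#' through additively, so the identity distortion is an exact fixed point.
#'
#' Cycles not fully contained in the (lag-shifted) trace span keep their
#' unwarped shape: a partial edge cycle has no flanking EOE inside the trace
#' to anchor the warp.
#'
#' @param trace A synthetic [resp_trace()] carrying its generating model
#'   (from [generate_internal_motion()]).
#' @param distortion A [surrogate_distortion()].
#' @param seed Integer seed for the extra noise.
#' @param sampling_rate Optional new sampling rate in Hz; default keeps the
#'   input grid.
#' @param source_kind Source kind of the output trace.
#' @return A [resp_trace()] with ground-truth marks shifted by the lag.
#' @export
distort_to_surrogate <- function(trace, distortion, seed = 1L,
                                 sampling_rate = NULL,
                                 source_kind = "pressure") {
  stopifnot_trace(trace)
  model <- attr(trace, "model", exact = TRUE)
  if (is.null(model))
    stop("distort_to_surrogate: trace carries no generating model / cycle marks",
         call. = FALSE)
  if (!inherits(distortion, "surrogate_distortion"))
    distortion <- do.call(surrogate_distortion, as.list(distortion))

  if (is.null(sampling_rate)) {
    t_out <- trace$time
    sampling_rate <- trace$sampling_rate
  } else {
    span <- range(trace$time)
    n <- floor((span[2] - span[1]) * sampling_rate) + 1L
    t_out <- span[1] + (seq_len(n) - 1L) / sampling_rate
  }

  tau <- t_out + distortion$lag
  # per-cycle limb warp, anchored on ground-truth EOE boundaries; only cycles
  # fully inside the shifted span are warped
  k <- findInterval(tau, model$boundaries)
  k <- pmin(pmax(k, 1L), length(model$periods))
  u <- (tau - model$boundaries[k]) / model$periods[k]
  u <- pmin(pmax(u, 0), 1)
  full <- model$boundaries[k] >= min(tau) - 1e-9 &
    (model$boundaries[k] + model$periods[k]) <= max(tau) + 1e-9
  uw <- u
  if (distortion$exhale_steepness != 1 || distortion$inhale_steepness != 1) {
    uw[full] <- warp_fraction(u[full], distortion$exhale_steepness,
                              distortion$inhale_steepness)
  }
  tau_w <- model$boundaries[k] + uw * model$periods[k]
  amp <- eval_model(model, tau_w)

  if (distortion$response_exponent != 1) {
    r <- range(amp)
    if (diff(r) > 0) {
      x <- (amp - r[1]) / diff(r)
      amp <- r[1] + diff(r) * x^distortion$response_exponent
    }
  }

  # carry the input's own per-sample noise through (exact identity fixed point)
  residual <- trace$amplitude - eval_model(model, trace$time)
  if (any(residual != 0)) {
    res_out <- stats::approx(trace$time, residual, xout = t_out, rule = 2)$y
    amp <- amp + res_out
  }

  amp <- distortion$gain * amp + distortion$offset
  if (distortion$extra_noise_sd > 0) {
    set.seed(derive_seed(seed, 3L))
    amp <- amp + stats::rnorm(length(amp), 0, distortion$extra_noise_sd)
  }

  out <- resp_trace(t_out, amp, source_kind = source_kind,
                    sampling_rate = sampling_rate)
  truth <- trace_truth(trace)
  out <- set_trace_truth(out,
                         eoi_times = truth_in_span(
                           model_eoi_times(model) - distortion$lag,
                           min(t_out), max(t_out)),
                         eoe_times = truth_in_span(
                           model$boundaries - distortion$lag,
                           min(t_out), max(t_out)))
  out$beam_on <- stats::approx(trace$time, as.numeric(trace$beam_on),
                               xout = t_out, method = "constant",
                               rule = 2)$y > 0.5
  # a lag-only distortion yields another exact model realization; keep it so
  # that lags compose
  if (distortion$exhale_steepness == 1 && distortion$inhale_steepness == 1 &&
      distortion$response_exponent == 1) {
    m2 <- model
    m2$boundaries <- model$boundaries - distortion$lag
    m2$offset <- model$offset + model$drift * distortion$lag
    m2$depths <- model$depths * distortion$gain
    m2$drift <- model$drift * distortion$gain
    m2$offset <- m2$offset * distortion$gain + distortion$offset
    attr(out, "model") <- m2
  }
  out
}

#' Ground-truth extrema of a synthetic trace
#'
#' Returns the generator's known EOI/EOE times as an `extrema_set`, usable
#' everywhere a [detect_extrema()] result is: the programmatic analogue of
#' manually corrected extremum markers, free of the localization noise of
#' automatic peak search.
#'
#' @param trace A synthetic [resp_trace()] carrying ground-truth marks.
#' @return An `extrema_set` (see [detect_extrema()]).
#' @export
true_extrema <- function(trace) {
  stopifnot_trace(trace)
  truth <- trace_truth(trace)
  if (is.null(truth))
    stop("true_extrema: trace carries no ground-truth marks", call. = FALSE)
  near <- function(tt) vapply(tt, function(x) which.min(abs(trace$time - x)),
                              integer(1))
  structure(list(eoi_times = truth$eoi_times, eoe_times = truth$eoe_times,
                 eoi_indices = near(truth$eoi_times),
                 eoe_indices = near(truth$eoe_times),
                 search_window = NA_real_),
            class = "extrema_set")
}

#' Generate a synchronized surrogate pair
#'
#' Emulates simultaneous acquisition by two monitoring systems sharing a
#' single start trigger: one internal motion realization is sampled by two
#' surrogates, each with its own distortion and sampling rate, and both are
#' stamped with the scanner's beam timeline.
#'
#' @param params A [breathing_params()].
#' @param distortion_a,distortion_b [surrogate_distortion()]s for the two
#'   surrogates.
#' @param timeline Optional [scan_timeline()].
#' @param rate_a,rate_b Sampling rates (Hz) of the two surrogate streams;
#'   defaults 25 (displacement-style) and 40 (pressure-style).
#' @return List with elements `internal`, `surrogate_a`, `surrogate_b`, all
#'   sharing t = 0.
#' @export
generate_pair <- function(params, distortion_a = identity_distortion(),
                          distortion_b = identity_distortion(),
                          timeline = NULL, rate_a = 25, rate_b = 40) {
  internal <- generate_internal_motion(params)
  if (!is.null(timeline)) internal <- stamp_beam(internal, timeline)
  a <- distort_to_surrogate(internal, distortion_a,
                            seed = derive_seed(params$seed, 11L),
                            sampling_rate = rate_a,
                            source_kind = "displacement")
  b <- distort_to_surrogate(internal, distortion_b,
                            seed = derive_seed(params$seed, 13L),
                            sampling_rate = rate_b,
                            source_kind = "pressure")
  if (!is.null(timeline)) {
    a <- stamp_beam(a, timeline)
    b <- stamp_beam(b, timeline)
  }
  list(internal = internal, surrogate_a = a, surrogate_b = b)
}
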