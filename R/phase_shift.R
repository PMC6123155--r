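#' Phase shift by per-cycle end-of-inhale latency
#'
#' Pairs the EOI times of two traces one-to-one (nearest neighbor within half
#' the local period) and reports the per-cycle lag
#' `lag_i = t_EOI_b(i) - t_EOI_a(i)`.  Positive values mean the FIRST
#' argument reaches EOI earlier (plays the leading-surrogate role).  The lag
#' is also expressed as a percentage of the local respiratory period, using
#' the first trace's EOI-to-EOI period for the paired cycle.
#'
#' @param a,b [resp_trace()]s sharing a time origin.
#' @param extrema_a,extrema_b [detect_extrema()] results; computed with
#'   defaults when `NULL`.
#' @return An object of class `phase_shift_result`: `per_cycle_lags` (s),
#'   `per_cycle_pct`, `mean_lag`, `sd_lag`, `mean_lag_pct`, `sd_lag_pct`,
#'   `sign_convention`.
#' @export
eoi_latency_shift <- function(a, b, extrema_a = NULL, extrema_b = NULL) {
  stopifnot_trace(a, "a"); stopifnot_trace(b, "b")
  if (is.null(extrema_a)) extrema_a <- detect_extrema(normalize_global(a))
  if (is.null(extrema_b)) extrema_b <- detect_extrema(normalize_global(b))
  ta <- extrema_a$eoi_times
  tb <- extrema_b$eoi_times
  if (length(ta) < 2 || length(tb) < 2)
    stop("eoi_latency_shift: need at least 2 EOIs in each trace",
         call. = FALSE)
  Ta <- diff(ta)                      # local EOI-to-EOI periods of a
  med_T <- stats::median(Ta)
  used <- rep(FALSE, length(tb))
  lags <- numeric(0)
  pct <- numeric(0)
  for (i in seq_along(ta)) {
    local_T <- if (i <= length(Ta)) Ta[i] else med_T
    j_free <- which(!used)
    if (length(j_free) == 0) break
    j <- j_free[which.min(abs(tb[j_free] - ta[i]))]
    if (abs(tb[j] - ta[i]) <= 0.5 * local_T) {
      used[j] <- TRUE
      lags <- c(lags, tb[j] - ta[i])
      pct <- c(pct, 100 * (tb[j] - ta[i]) / local_T)
    }
  }
  if (length(lags) < 2)
    stop("eoi_latency_shift: fewer than 2 paired EOIs", call. = FALSE)
  structure(list(
    per_cycle_lags = lags, per_cycle_pct = pct,
    mean_lag = mean(lags), sd_lag = stats::sd(lags),
    mean_lag_pct = mean(pct), sd_lag_pct = stats::sd(pct),
    n_pairs = length(lags),
    sign_convention = "positive = first argument reaches EOI earlier"
  ), class = "phase_shift_result")
}

#' @export
print.phase_shift_result <- function(x, ...) {
  cat(sprintf("<phase_shift_result> %d cycle pairs: %.3f +/- %.3f s (%.1f%% +/- %.1f%% of period)\n",
              x$n_pairs, x$mean_lag, x$sd_lag, x$mean_lag_pct, x$sd_lag_pct))
  cat(" ", x$sign_convention, "\n")
  invisible(x)
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `a x^2 + b x y + c y^2 + d x + e y + f = 0` to scattered
#' points with the ellipse-specific constraint `4ac - b^2 = 1`, solved as a
#' generalized eigenproblem on the partitioned scatter matrix (the
#' numerically stable formulation of the direct least-squares method).  The
#' constraint guarantees an ellipse whenever a solution exists.
#'
#' @param x,y Coordinates of at least 6 non-collinear points.
#' @return An object of class `ellipse_params`: `center` (length-2),
#'   `semi_major`, `semi_minor`, `orientation` (radians of the major axis,
#'   in `(-pi/2, pi/2]`), and the raw conic coefficients `conic`.
#' @export
fit_ellipse <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 6)
    stop("fit_ellipse: need >= 6 points", call. = FALSE)
  # center/scale for conditioning
  mx <- mean(x); my <- mean(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  s <- max(sx, sy)
  if (!is.finite(s) || s == 0)
    stop("fit_ellipse: degenerate point set", call. = FALSE)
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("fit_ellipse: degenerate (collinear) data", call. = FALSE))
  M <- S1 + S2 %*% T2
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop("fit_ellipse: no elliptical solution (degenerate data)",
         call. = FALSE)
  a1 <- V[, ok[1]]
  coef_s <- c(a1, T2 %*% a1)           # (A,B,C,D,E,F) in scaled coords
  # undo scaling: x = (X - mx)/s etc.
  A <- coef_s[1] / s^2
  B <- coef_s[2] / s^2
  C <- coef_s[3] / s^2
  D <- coef_s[4] / s - 2 * A * mx - B * my
  E <- coef_s[5] / s - 2 * C * my - B * mx
  F <- coef_s[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef_s[4] * mx / s - coef_s[5] * my / s
  conic <- c(A = A, B = B, C = C, D = D, E = E, F = F)
  den <- 4 * A * C - B^2
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # value of the quadratic form at the center
  Fc <- F + A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy
  # eigen-decomposition of the quadratic part
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values                     # decreasing
  axes2 <- -Fc / lam
  if (any(axes2 <= 0))
    stop("fit_ellipse: degenerate conic", call. = FALSE)
  semi <- sqrt(axes2)                  # smaller eigenvalue -> larger axis
  major_i <- which.max(semi)
  vmaj <- eq$vectors[, major_i]
  ang <- atan2(vmaj[2], vmaj[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(list(center = c(cx, cy),
                 semi_major = max(semi), semi_minor = min(semi),
                 orientation = ang, conic = conic),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("<ellipse_params> center (%.3g, %.3g), semi-axes %.4g / %.4g, orientation %.1f deg\n",
              x$center[1], x$center[2], x$semi_major, x$semi_minor,
              180 / pi * x$orientation))
  invisible(x)
}

angdiff <- function(a, b) {
  d <- (a - b) %% pi
  min(d, pi - d)
}

#' Phase shift from the correlation-scatter ellipse
#'
#' For two signals of the same waveform differing by a phase lag, the scatter
#' of simultaneous amplitudes lies on an ellipse; with both signals
#' normalized to equal amplitude the ellipse's axes align with the +/-45-degree
#' diagonals, with semi-axes proportional to `cos(phi/2)` (diagonal) and
#' `sin(phi/2)` (antidiagonal).  The implied phase is therefore
#' `phi = 2 * atan(semi_antidiagonal / semi_diagonal)`, where the diagonal
#' axis is the fitted axis nearer +45 degrees.  When the major axis lies near
#' -45 degrees (negatively correlated signals) the supplementary angle is
#' reported, so `phi` falls in `(pi/2, pi]`.
#'
#' The mean lag in seconds is `phi * mean_period / (2*pi)`.  The sign is
#' taken from [eoi_latency_shift()] when extrema can be found; a
#' near-degenerate scatter (axis ratio below `degenerate_tol`, e.g. identical
#' traces collapsing to a line) is reported as `phi = 0` with
#' `degenerate = TRUE` rather than as an error.
#'
#' @param a,b [resp_trace()]s sharing a time origin; internally normalized
#'   0-100 and resampled to a common grid.
#' @param stats Optional [paired_cycle_stats()] supplying the mean period;
#'   estimated from `a`'s EOIs when `NULL`.
#' @param degenerate_tol Axis-ratio floor below which the scatter counts as a
#'   line; default 1e-3.
#' @return A `phase_shift_result` with extra fields `phi` (radians),
#'   `ellipse` and `degenerate`.
#' @export
ellipse_phase_shift <- function(a, b, stats = NULL, degenerate_tol = 1e-3) {
  stopifnot_trace(a, "a"); stopifnot_trace(b, "b")
  an <- normalize_global(a)
  bn <- normalize_global(b)
  lo <- max(min(a$time), min(b$time))
  hi <- min(max(a$time), max(b$time))
  g <- seq(lo, hi, by = 1 / max(a$sampling_rate, b$sampling_rate))
  xv <- stats::approx(an$time, an$amplitude, xout = g)$y
  yv <- stats::approx(bn$time, bn$amplitude, xout = g)$y

  latency <- tryCatch(eoi_latency_shift(a, b), error = function(e) NULL)
  mean_period <- if (!is.null(stats)) {
    mean(c(stats$period_mean_a, stats$period_mean_b))
  } else if (!is.null(latency) && !is.null(attr(latency, "period"))) {
    attr(latency, "period")
  } else {
    ex <- tryCatch(detect_extrema(an), error = function(e) NULL)
    if (!is.null(ex) && length(ex$eoi_times) > 1) mean(diff(ex$eoi_times))
    else NA_real_
  }

  fit <- tryCatch(fit_ellipse(xv, yv), error = function(e) NULL)
  degenerate <- FALSE
  if (is.null(fit)) {
    phi <- 0
    degenerate <- TRUE
  } else {
    diag_is_major <- angdiff(fit$orientation, pi / 4) <=
      angdiff(fit$orientation + pi / 2, pi / 4)
    ratio <- fit$semi_minor / fit$semi_major
    if (ratio < degenerate_tol) {
      phi <- 0
      degenerate <- TRUE
    } else if (diag_is_major) {
      phi <- 2 * atan(ratio)
    } else {
      phi <- pi - 2 * atan(ratio)
    }
  }
  lag_abs <- if (is.na(mean_period)) NA_real_ else phi * mean_period / (2 * pi)
  sgn <- if (!is.null(latency) && is.finite(latency$mean_lag) &&
             latency$mean_lag < 0) -1 else 1
  structure(list(
    phi = phi, degenerate = degenerate, ellipse = fit,
    mean_lag = sgn * lag_abs, sd_lag = NA_real_,
    mean_lag_pct = sgn * 100 * phi / (2 * pi), sd_lag_pct = NA_real_,
    per_cycle_lags = numeric(0), per_cycle_pct = numeric(0),
    n_pairs = 0L,
    sign_convention = "positive = first argument reaches EOI earlier (sign from EOI latency when available)"
  ), class = "phase_shift_result")
}
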