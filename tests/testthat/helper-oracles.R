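# Fixture builders and independent brute-force oracles used across tests.

make_sinusoid <- function(duration = 20, period = 4, rate = 25,
                          amplitude = 50, offset = 50, phase = 0,
                          eoe_start = FALSE) {
  t <- seq(0, duration, by = 1 / rate)
  a <- if (eoe_start) offset - amplitude * cos(2 * pi * (t - phase) / period)
       else offset + amplitude * sin(2 * pi * (t - phase) / period)
  resp_trace(t, a, sampling_rate = rate)
}

# Independent extrema oracle: literal per-sample double loop over the
# definition (full window inside the trace, strict window max/min, earliest
# of any tie run), followed by plain-loop alternation and prominence pruning.
oracle_extrema <- function(trace, window, min_prominence = 10) {
  a <- trace$amplitude
  t <- trace$time
  n <- length(a)
  dt <- stats::median(diff(t))
  hw <- max(1L, floor((window / 2) / dt))
  idx <- integer(0)
  type <- character(0)
  for (i in seq_len(n)) {
    if (i - hw < 1 || i + hw > n) next
    is_max <- TRUE
    is_min <- TRUE
    for (j in (i - hw):(i + hw)) {
      if (a[j] > a[i]) is_max <- FALSE
      if (a[j] < a[i]) is_min <- FALSE
      if (j < i && a[j] >= a[i]) is_max <- FALSE
      if (j < i && a[j] <= a[i]) is_min <- FALSE
    }
    if (is_max) { idx <- c(idx, i); type <- c(type, "EOI") }
    if (is_min) { idx <- c(idx, i); type <- c(type, "EOE") }
  }
  collapse <- function(idx, type) {
    ki <- integer(0); kt <- character(0)
    for (j in seq_along(idx)) {
      m <- length(ki)
      if (m > 0 && type[j] == kt[m]) {
        if ((type[j] == "EOI" && a[idx[j]] > a[ki[m]]) ||
            (type[j] == "EOE" && a[idx[j]] < a[ki[m]])) ki[m] <- idx[j]
      } else {
        ki <- c(ki, idx[j]); kt <- c(kt, type[j])
      }
    }
    list(idx = ki, type = kt)
  }
  cur <- collapse(idx, type)
  repeat {
    m <- length(cur$idx)
    if (m < 2) break
    swings <- numeric(m - 1)
    for (j in seq_len(m - 1)) swings[j] <- abs(a[cur$idx[j + 1]] - a[cur$idx[j]])
    if (all(swings >= min_prominence)) break
    j <- which.min(swings)
    keep <- setdiff(seq_len(m), c(j, j + 1L))
    cur <- collapse(cur$idx[keep], cur$type[keep])
  }
  list(eoi_indices = cur$idx[cur$type == "EOI"],
       eoe_indices = cur$idx[cur$type == "EOE"])
}

# Independent phase-sorting oracle: per-sample loop that scans the extremum
# event list and all nominal levels explicitly.
oracle_assign_phases <- function(trace, extrema, clamp_tol = 0.02) {
  t <- trace$time
  a <- trace$amplitude
  ev_idx <- sort(c(extrema$eoi_indices, extrema$eoe_indices))
  ev_type <- ifelse(ev_idx %in% extrema$eoi_indices, "EOI", "EOE")
  levels_ex <- c(1, 0.8, 0.6, 0.4, 0.2, 0)   # phases 1..6
  levels_in <- c(0, 0.2, 0.4, 0.6, 0.8)       # phases 6..10
  rows <- list()
  for (s in seq_along(t)) {
    # find the limb [event_k, event_{k+1}) containing sample s
    k <- NA
    for (e in seq_len(length(ev_idx) - 1)) {
      if (s >= ev_idx[e] && s < ev_idx[e + 1] &&
          ev_type[e] != ev_type[e + 1]) { k <- e; break }
    }
    if (is.na(k)) {
      if (s == ev_idx[length(ev_idx)]) {     # closing event sample
        ty <- ev_type[length(ev_type)]
        rows[[length(rows) + 1]] <- data.frame(
          time = t[s], phase_index = if (ty == "EOI") 1L else 6L)
      }
      next
    }
    limb <- if (ev_type[k] == "EOI") "exhale" else "inhale"
    a_eoi <- if (limb == "exhale") a[ev_idx[k]] else a[ev_idx[k + 1]]
    a_eoe <- if (limb == "exhale") a[ev_idx[k + 1]] else a[ev_idx[k]]
    if (a_eoi - a_eoe <= 0) next
    f <- (a[s] - a_eoe) / (a_eoi - a_eoe)
    if (f < -clamp_tol || f > 1 + clamp_tol) next
    f <- min(max(f, 0), 1)
    if (limb == "exhale") {
      best <- 1L
      for (p in 1:6) if (abs(levels_ex[p] - f) < abs(levels_ex[best] - f))
        best <- p
      ph <- best
    } else {
      best <- 1L
      for (p in 1:5) if (abs(levels_in[p] - f) < abs(levels_in[best] - f))
        best <- p
      ph <- best + 5L
    }
    rows[[length(rows) + 1]] <- data.frame(time = t[s], phase_index = ph)
  }
  do.call(rbind, rows)
}

random_breathing <- function(seed, duration = 30, noise_sd = 2) {
  set.seed(seed)
  breathing_params(mean_period = stats::runif(1, 2.5, 5.6),
                   period_sd = stats::runif(1, 0.05, 0.4),
                   mean_depth = 100,
                   depth_sd = stats::runif(1, 2, 12),
                   plateau_exponent = stats::runif(1, 1, 2.5),
                   noise_sd = noise_sd,
                   sampling_rate = 25, duration = duration,
                   seed = seed)
}
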