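#' Scan-line level of a trace
#'
#' Breathing events are carved out of the XTF by a horizontal scan line at the
#' level of the trace mean plus 33% of its standard deviation (sample SD,
#' n - 1 denominator).
#'
#' @param trace an [xlf_trace()].
#' @param frac fraction of the SD added to the mean (default 0.33).
#' @return the level (unitless scalar).
#' @export
scan_line_level <- function(trace, frac = 0.33) {
  stopifnot(inherits(trace, "xlf_trace"))
  s <- sd(trace$value)
  if (s == 0) stop_xlf("degenerate trace: zero standard deviation")
  mean(trace$value) + frac * s
}

#' Smooth a trace with a short centered moving average
#'
#' Light noise suppression applied before event detection and fitting. The
#' window must be odd. The effect of an odd centered moving average on any
#' cubic polynomial is an exact linear map of its coefficients
#' (`c1 += 3 c3 m2`, `c0 += c2 m2`, with `m2` the window's mean squared
#' offset); [fit_breath()] inverts that map, so smoothing does not bias the
#' fitted parameters of model-shaped breaths at all. Edges are
#' reflect-padded. The result carries the attribute `ma_m2` consumed by the
#' fitter.
#'
#' @param trace an [xlf_trace()].
#' @param window odd window length in samples (default 9, about 300 ms at
#'   30 fps — short relative to a breathing event).
#' @return the smoothed [xlf_trace()].
#' @export
smooth_trace <- function(trace, window = 9L) {
  stopifnot(inherits(trace, "xlf_trace"))
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) stop_xlf("'window' must be odd and >= 1")
  out <- trace
  if (window > 1L) {
    out$value <- moving_average(trace$value, window)
    h <- (window - 1L) %/% 2L
    attr(out, "ma_m2") <- mean(((-h):h)^2)
  }
  out
}

#' Detect breathing events above a scan line
#'
#' A breathing event is a maximal run of samples strictly above the level,
#' bounded by the two crossing times of the piecewise-linear trace with the
#' scan line. Runs touching the first or last sample are incomplete breaths
#' and are discarded, as are runs with fewer than `min_samples` interior
#' samples (noise guard; a cubic fit needs a residual degree of freedom).
#'
#' @param trace an [xlf_trace()] (normally detrended; possibly
#'   [smooth_trace()]-ed).
#' @param level scan-line level, typically from [scan_line_level()].
#' @param min_samples minimum interior samples per event (default 5).
#' @return A list of `breath_event` objects (possibly empty), each with
#'   `start_ms`, `end_ms` (interpolated crossing times), `sample_times_ms`,
#'   `sample_values` (the interior samples framed by the two boundary points
#'   at the level), `dt_ms`, `level` and `ma_m2`.
#' @export
detect_breaths <- function(trace, level, min_samples = 5L) {
  stopifnot(inherits(trace, "xlf_trace"))
  check_scalar(level, "level", positive = FALSE)
  v <- trace$value; t <- trace$time_ms
  n <- length(v)
  above <- v > level
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  m2 <- attr(trace, "ma_m2")
  events <- list()
  for (k in which(r$values)) {
    i0 <- run_start[k]; i1 <- run_end[k]
    if (i0 == 1L || i1 == n) next                  # incomplete breath at record edge
    if (i1 - i0 + 1L < min_samples) next
    start_ms <- t[i0 - 1L] + (level - v[i0 - 1L]) / (v[i0] - v[i0 - 1L]) * (t[i0] - t[i0 - 1L])
    end_ms <- t[i1] + (level - v[i1]) / (v[i1 + 1L] - v[i1]) * (t[i1 + 1L] - t[i1])
    ev <- structure(list(
      start_ms = start_ms, end_ms = end_ms,
      sample_times_ms = c(start_ms, t[i0:i1], end_ms),
      sample_values = c(level, v[i0:i1], level),
      dt_ms = median(diff(t[i0:i1])),
      level = level, ma_m2 = if (is.null(m2)) 0 else m2),
      class = "breath_event")
    events[[length(events) + 1L]] <- ev
  }
  events
}

#' Fit the shifted cubic breathing-peak model to one event
#'
#' Each breathing peak is approximated by the third-order polynomial
#' `P(x) = b2 (x - b1)^3 - b3 (x - b1)^2 - b4 (x - b1) + b5`,
#' where `x` counts samples from the event start (unitless, like the XTF
#' itself). `b1` locates the peak maximum, `b5` is the peak value (maximum
#' relative air content), `b3` the curvature at the peak (air-flow dynamic),
#' and `b2`, `b4` capture asymmetry.
#'
#' The fit is deterministic and two-staged: a full cubic is estimated from
#' the event's interior samples by ordinary least squares (the two
#' interpolated boundary points define the event span but carry interpolation
#' error, so they are excluded from the fit); `b1` is then the stationary
#' maximum of that cubic (falling back to the argmax sample when the fitted
#' cubic has no interior maximum, ties towards the earlier sample), and
#' `b2..b5` are its Taylor re-expansion about `b1`. At an interior stationary
#' maximum `b4 = -P'(b1)` vanishes by construction. If the samples came from
#' a smoothed trace the smoother's exact coefficient map is inverted first.
#'
#' The relative inspiration time is `t_in = 100 * b1 * dt / duration` (% of
#' the event length needed to reach the maximum).
#'
#' @param event a `breath_event` from [detect_breaths()].
#' @return A one-row data.frame of class `breath_params` with columns
#'   `b1, b2, b3, b4, b5, t_in_pct, duration_ms, peak_value`.
#' @export
fit_breath <- function(event) {
  stopifnot(inherits(event, "breath_event"))
  m <- length(event$sample_times_ms)
  ti <- event$sample_times_ms[2:(m - 1L)]          # interior samples only
  yi <- event$sample_values[2:(m - 1L)]
  if (length(yi) < 5L) stop_xlf("unfittable event: fewer than 5 interior samples")
  if (max(yi) == min(yi)) stop_xlf("unfittable event: flat samples")
  dt <- event$dt_ms
  x <- (ti - event$start_ms) / dt
  X <- cbind(x^3, x^2, x, 1)
  cf <- tryCatch(qr.solve(X, yi), error = function(e) stop_xlf("unfittable event: degenerate design"))
  # undo the smoother's exact action on cubics: c1 += 3 c3 m2, c0 += c2 m2
  m2 <- event$ma_m2
  if (m2 > 0) {
    cf[3L] <- cf[3L] - 3 * cf[1L] * m2
    cf[4L] <- cf[4L] - cf[2L] * m2
  }
  xmax <- x[which.max(yi)]                          # which.max takes the earliest tie
  b1 <- cubic_peak(cf, lo = 0, hi = (event$end_ms - event$start_ms) / dt, fallback = xmax)
  p <- function(z) ((cf[1L] * z + cf[2L]) * z + cf[3L]) * z + cf[4L]
  dp <- function(z) (3 * cf[1L] * z + 2 * cf[2L]) * z + cf[3L]
  ddp <- function(z) 6 * cf[1L] * z + 2 * cf[2L]
  duration_ms <- event$end_ms - event$start_ms
  out <- data.frame(b1 = b1, b2 = cf[1L], b3 = -ddp(b1) / 2, b4 = -dp(b1),
                    b5 = p(b1), t_in_pct = 100 * b1 * dt / duration_ms,
                    duration_ms = duration_ms, peak_value = max(yi))
  class(out) <- c("breath_params", "data.frame")
  out
}

# stationary maximum of a cubic in (lo, hi); NA-safe fallback to the argmax
cubic_peak <- function(cf, lo, hi, fallback) {
  a <- 3 * cf[1L]; b <- 2 * cf[2L]; cc <- cf[3L]
  roots <- if (abs(a) < .Machine$double.eps * max(1, abs(b), abs(cc))) {
    if (b != 0) -cc / b else numeric()
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric() else (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[is.finite(roots) & 6 * cf[1L] * roots + 2 * cf[2L] < 0]  # maxima only
  roots <- roots[roots > lo & roots < hi]
  if (length(roots) == 0L) return(fallback)
  roots[which.min(abs(roots - fallback))]
}

#' Fit all events of a scan
#'
#' @param events list of `breath_event` objects.
#' @return A `breath_params` data.frame with one row per event.
#' @export
fit_breaths <- function(events) {
  if (length(events) == 0L) stop_xlf("no breaths detected")
  out <- do.call(rbind, lapply(events, fit_breath))
  class(out) <- c("breath_params", "data.frame")
  out
}

#' Extrema of the first time-derivative of a trace
#'
#' Central differences on the sample grid, in value per second; surrogates
#' for air flow (MaxSlope / MinSlope in plethysmography).
#'
#' @param trace an [xlf_trace()].
#' @return `c(max_slope, min_slope)`.
#' @export
trace_slopes <- function(trace) {
  stopifnot(inherits(trace, "xlf_trace"))
  v <- trace$value; t <- trace$time_ms
  n <- length(v)
  if (n < 3L) stop_xlf("trace too short for central differences")
  d <- (v[3:n] - v[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)]) * 1000
  c(max_slope = max(d), min_slope = min(d))
}

#' Summarize a scan from its fitted breathing events
#'
#' Averages each parameter over all breathing cycles of the captured time
#' frame, and adds the respiratory rate (events per minute of trace
#' duration), the slope extrema of the full trace, and the mean event
#' maximum above the scan line (peak amplitude).
#'
#' @param params a `breath_params` data.frame ([fit_breaths()]).
#' @param trace the analyzed [xlf_trace()].
#' @param level the scan-line level used for detection; defaults to
#'   [scan_line_level()] of `trace`.
#' @return A one-row data.frame of class `scan_summary` with columns
#'   `b1..b5`, `t_in_pct`, `n_events`, `bpm`, `max_slope`, `min_slope`,
#'   `peak_amplitude`, `duration_s`, `level`.
#' @export
summarize_scan <- function(params, trace, level = scan_line_level(trace)) {
  stopifnot(inherits(trace, "xlf_trace"))
  if (is.null(params) || nrow(params) == 0L) stop_xlf("no breaths detected")
  sl <- trace_slopes(trace)
  dur_s <- trace_duration_s(trace)
  out <- data.frame(
    b1 = mean(params$b1), b2 = mean(params$b2), b3 = mean(params$b3),
    b4 = mean(params$b4), b5 = mean(params$b5),
    t_in_pct = mean(params$t_in_pct),
    n_events = nrow(params),
    bpm = nrow(params) / (dur_s / 60),
    max_slope = unname(sl["max_slope"]), min_slope = unname(sl["min_slope"]),
    peak_amplitude = mean(params$peak_value - level),
    duration_s = dur_s, level = level)
  class(out) <- c("scan_summary", "data.frame")
  out
}

#' Analyze one trace end to end
#'
#' Convenience pipeline: scan-line level on the raw (detrended) trace, light
#' smoothing, event detection, cubic fits, scan summary.
#'
#' @param trace a detrended [xlf_trace()] (use [detrend_xtf()] first for raw
#'   XTF traces).
#' @param level scan-line override; default [scan_line_level()].
#' @param smooth_window odd moving-average window for [smooth_trace()]
#'   (default 9); `1` disables smoothing.
#' @param min_samples passed to [detect_breaths()].
#' @return A list with elements `summary` (one-row `scan_summary`), `params`
#'   (per-event `breath_params`), `events`, `level`.
#' @export
analyze_trace <- function(trace, level = NULL, smooth_window = 9L, min_samples = 5L) {
  stopifnot(inherits(trace, "xlf_trace"))
  if (is.null(level)) level <- scan_line_level(trace)
  sm <- smooth_trace(trace, smooth_window)
  events <- detect_breaths(sm, level, min_samples = min_samples)
  params <- fit_breaths(events)
  list(summary = summarize_scan(params, trace, level = level),
       params = params, events = events, level = level)
}

#' Zero-phase band-pass filter for plethysmography-style traces
#'
#' 4th-order Butterworth applied forward and backward (zero phase); the pass
#' band 0.5-20 Hz brackets murine breathing and rejects DC and high-frequency
#' noise. The trace mean is removed before filtering.
#'
#' @param trace an [xlf_trace()].
#' @param low_hz,high_hz band edges in Hz (defaults 0.5 and 20).
#' @param order filter order (default 4).
#' @return the filtered [xlf_trace()].
#' @export
bandpass_trace <- function(trace, low_hz = 0.5, high_hz = 20, order = 4L) {
  stopifnot(inherits(trace, "xlf_trace"))
  fs <- 1000 / trace_dt_ms(trace)
  if (fs <= 2 * high_hz)
    stop_xlf("sampling rate too low: %.3g Hz for a %.3g Hz band edge", fs, high_hz)
  if (low_hz <= 0 || low_hz >= high_hz) stop_xlf("need 0 < low_hz < high_hz")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- trace
  out$value <- as.numeric(signal::filtfilt(bf, trace$value - mean(trace$value)))
  out$source <- paste0(trace$source, if (nzchar(trace$source)) " " else "", "bandpassed")
  out
}
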