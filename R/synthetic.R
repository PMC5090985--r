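# Breathing pulses are drawn from the fitting model itself: a cubic
# P(u) = b2 (u - b1)^3 - b3 (u - b1)^2 + b5  on unit cycle time u in [0, 1],
# with b4 = 0, peak (b1, b5) and endpoints pinned to the inter-breath
# baseline. Solving P(0) = P(1) = y0 for (b2, b3) is a 2x2 linear system.
pulse_coefficients <- function(inspiration_fraction, peak_amplitude, baseline) {
  b1 <- inspiration_fraction
  A <- rbind(c(-b1^3, -b1^2),
             c((1 - b1)^3, -(1 - b1)^2))
  ab <- solve(A, rep(baseline - peak_amplitude, 2L))
  list(b2 = ab[1L], b3 = ab[2L])
}

pulse_value <- function(u, b1, b2, b3, b5) b2 * (u - b1)^3 - b3 * (u - b1)^2 + b5

raised_cosine_value <- function(u, b1, b5, y0) {
  ifelse(u < b1,
         y0 + (b5 - y0) * (1 - cos(pi * u / b1)) / 2,
         y0 + (b5 - y0) * (1 + cos(pi * (u - b1) / (1 - b1))) / 2)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Trace simulator configuration
#'
#' Defaults emulate the standard acquisition: 34 s of cinematic radiography
#' at 30 frames per second with the anesthesia depth adjusted to roughly one
#' breathing event per 1400 ms. Each breath is a cubic-model pulse (peak
#' position = `inspiration_fraction` of the pulse, height `peak_amplitude`)
#' whose endpoints sit on the inter-breath baseline at
#' `-0.4 * peak_amplitude`; breaths are separated by `pause_ms` of baseline.
#'
#' @param duration_s record length in seconds (default 34).
#' @param sample_rate_hz frame rate (default 30).
#' @param breath_period_ms duration of one breathing pulse (default 1400);
#'   the full cycle is `breath_period_ms + pause_ms`.
#' @param inspiration_fraction fraction of the pulse needed to reach the
#'   maximum, in (0, 1) (default 0.45).
#' @param peak_amplitude pulse height above zero (unitless XTF scale,
#'   default 1).
#' @param baseline_drift quadratic drift coefficients `c(c0, c1, c2)` in
#'   value, value/s, value/s^2 added to the trace (default none).
#' @param noise_sd Gaussian detector noise SD, absolute (default 0.02).
#' @param pause_ms inter-breath pause at baseline (default 0).
#' @param shape `"cubic"` (the fitting model; exact ground truth) or
#'   `"raised_cosine"` (asymmetric model-mismatch pulse).
#' @param seed integer RNG seed (default 1).
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(duration_s = 34, sample_rate_hz = 30,
                             breath_period_ms = 1400,
                             inspiration_fraction = 0.45,
                             peak_amplitude = 1,
                             baseline_drift = c(0, 0, 0),
                             noise_sd = 0.02, pause_ms = 0,
                             shape = c("cubic", "raised_cosine"),
                             seed = 1L) {
  check_scalar(duration_s, "duration_s"); check_scalar(sample_rate_hz, "sample_rate_hz")
  check_scalar(breath_period_ms, "breath_period_ms")
  check_scalar(peak_amplitude, "peak_amplitude")
  check_scalar(noise_sd, "noise_sd", positive = FALSE)
  check_scalar(pause_ms, "pause_ms", positive = FALSE)
  if (noise_sd < 0 || pause_ms < 0) stop_xlf("noise_sd and pause_ms must be >= 0")
  if (inspiration_fraction <= 0 || inspiration_fraction >= 1)
    stop_xlf("inspiration_fraction must be in (0, 1)")
  if (breath_period_ms < 5 * 1000 / sample_rate_hz)
    stop_xlf("breath_period_ms shorter than 5 samples")
  if (length(baseline_drift) != 3L) stop_xlf("baseline_drift must have 3 coefficients")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 breath_period_ms = breath_period_ms,
                 inspiration_fraction = inspiration_fraction,
                 peak_amplitude = peak_amplitude,
                 baseline_drift = as.numeric(baseline_drift),
                 noise_sd = noise_sd, pause_ms = pause_ms,
                 shape = match.arg(shape), seed = seed),
            class = "trace_sim_config")
}

#' Simulate a breathing trace with known ground truth
#'
#' Generates the noiseless pulse train defined by `cfg`, then adds the
#' quadratic baseline drift and Gaussian detector noise. The ground truth
#' records, for every complete pulse, its exact support and the true cubic
#' parameters in the sample-index coordinates used by [fit_breath()]
#' (`b1` = samples from pulse start to peak, `b3` and `b2` rescaled by
#' `(dt / width)^2` and `(dt / width)^3`, `b5` = peak value). Reproducible
#' given the seed.
#'
#' @param cfg a [trace_sim_config()].
#' @return A list with `trace` (an [xlf_trace()], `detrended = TRUE` when no
#'   drift is requested since the pulse train is stationary) and
#'   `ground_truth` (class `breath_ground_truth`).
#' @export
simulate_trace <- function(cfg = trace_sim_config()) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  dt <- 1000 / cfg$sample_rate_hz
  n <- round(cfg$duration_s * cfg$sample_rate_hz)
  t <- (seq_len(n) - 1L) * dt
  y0 <- -0.4 * cfg$peak_amplitude
  width <- cfg$breath_period_ms
  cycle <- width + cfg$pause_ms
  v <- rep(y0, n)
  cf <- pulse_coefficients(cfg$inspiration_fraction, cfg$peak_amplitude, y0)
  starts <- seq(0, max(t), by = cycle)
  events <- list()
  for (s in starts) {
    if (s + width > max(t)) break                  # incomplete pulse at record end
    idx <- which(t > s & t < s + width)
    u <- (t[idx] - s) / width
    v[idx] <- if (cfg$shape == "cubic")
      pulse_value(u, cfg$inspiration_fraction, cf$b2, cf$b3, cfg$peak_amplitude)
    else
      raised_cosine_value(u, cfg$inspiration_fraction, cfg$peak_amplitude, y0)
    events[[length(events) + 1L]] <- data.frame(
      event = length(events) + 1L,
      start_ms = s, end_ms = s + width,
      b1 = cfg$inspiration_fraction * width / dt,
      b2 = if (cfg$shape == "cubic") cf$b2 * (dt / width)^3 else NA_real_,
      b3 = if (cfg$shape == "cubic") cf$b3 * (dt / width)^2 else NA_real_,
      b4 = if (cfg$shape == "cubic") 0 else NA_real_,
      b5 = cfg$peak_amplitude,
      t_in_pct = 100 * cfg$inspiration_fraction)
  }
  if (length(events) == 0L) stop_xlf("record shorter than one breathing pulse")
  drift <- cfg$baseline_drift
  ts <- t / 1000
  v <- v + drift[1L] + drift[2L] * ts + drift[3L] * ts^2
  if (cfg$noise_sd > 0)
    v <- v + with_seed(cfg$seed, rnorm(n, 0, cfg$noise_sd))
  gt <- structure(do.call(rbind, events), class = c("breath_ground_truth", "data.frame"))
  attr(gt, "baseline") <- y0
  attr(gt, "dt_ms") <- dt
  attr(gt, "width_ms") <- width
  attr(gt, "cycle_coefficients") <- c(b2 = cf$b2, b3 = cf$b3)
  attr(gt, "inspiration_fraction") <- cfg$inspiration_fraction
  attr(gt, "peak_amplitude") <- cfg$peak_amplitude
  attr(gt, "shape") <- cfg$shape
  detrended <- all(drift == 0)
  list(trace = xlf_trace(t, v, detrended = detrended, source = "simulate_trace"),
       ground_truth = gt)
}

#' Ground-truth breath parameters at a detection level
#'
#' The detected portion of a breathing event depends on where the scan line
#' cuts the pulse. Given a level, this reparameterizes the *noiseless* pulse
#' analytically: the crossing times are solved on the continuous pulse (not
#' the sampled trace), the index-unit parameters `b2, b3, b5` are unchanged
#' by construction (they are invariant to the support), and `b1` / `t_in`
#' are re-expressed on the above-level support. Use it as the exact oracle
#' when comparing pipeline output at an operating scan-line level against
#' truth.
#'
#' @param gt a `breath_ground_truth` from [simulate_trace()].
#' @param level detection level; must lie strictly between the baseline and
#'   the peak. `NULL` returns the full-pulse truth unchanged.
#' @return A data.frame like `gt` with `start_ms`, `end_ms`, `b1`,
#'   `t_in_pct` re-expressed for the above-level support.
#' @export
true_params_at_level <- function(gt, level = NULL) {
  stopifnot(inherits(gt, "breath_ground_truth"))
  if (is.null(level)) return(gt)
  if (!identical(attr(gt, "shape"), "cubic"))
    stop_xlf("level reparameterization is defined for cubic pulses only")
  y0 <- attr(gt, "baseline"); amp <- attr(gt, "peak_amplitude")
  if (level <= y0 || level >= amp)
    stop_xlf("level must lie strictly between baseline (%.3g) and peak (%.3g)", y0, amp)
  cf <- attr(gt, "cycle_coefficients")
  b1u <- attr(gt, "inspiration_fraction")
  w <- attr(gt, "width_ms"); dt <- attr(gt, "dt_ms")
  f <- function(u) pulse_value(u, b1u, cf[["b2"]], cf[["b3"]], amp) - level
  u_lo <- stats::uniroot(f, c(0, b1u), tol = 1e-13)$root
  u_hi <- stats::uniroot(f, c(b1u, 1), tol = 1e-13)$root
  out <- gt
  out$start_ms <- gt$start_ms + u_lo * w
  out$end_ms <- gt$start_ms + u_hi * w
  out$b1 <- (b1u - u_lo) * w / dt
  out$t_in_pct <- 100 * (b1u - u_lo) / (u_hi - u_lo)
  out
}

#' Stack simulator configuration
#'
#' Forward model of the acquisition: background pixels are
#' `B0 * g(t) + noise`, lung pixels `B0 * g(t) * (1 + s(t)) + noise`, where
#' `s(t)` is the simulated breathing signal of [simulate_trace()] and
#' `g(t) = 1 + tube_gain_drift * sin(2 pi t / duration)` a slow
#' tube-intensity drift. With zero noise and no drift, [compute_xtf()]
#' reproduces `s(t)` up to floating-point error.
#'
#' @param trace_cfg a [trace_sim_config()].
#' @param frame_shape `c(H, W)` (default 64 x 64).
#' @param lung_roi,background_roi rectangles (0-based half-open); defaults
#'   place a central lung and a corner background patch.
#' @param b0 mean detector intensity (default 1000).
#' @param tube_gain_drift relative amplitude of the tube drift (default 0).
#' @param pixel_noise_sd Gaussian pixel noise SD in detector units
#'   (default 0).
#' @return A list of class `stack_sim_config`.
#' @export
stack_sim_config <- function(trace_cfg = trace_sim_config(),
                             frame_shape = c(64L, 64L),
                             lung_roi = c(16, 48, 16, 48),
                             background_roi = c(0, 8, 0, 8),
                             b0 = 1000, tube_gain_drift = 0,
                             pixel_noise_sd = 0) {
  stopifnot(inherits(trace_cfg, "trace_sim_config"))
  spec <- roi_spec(list(lung_roi), background_roi, frame_shape = frame_shape)
  check_scalar(b0, "b0")
  structure(list(trace_cfg = trace_cfg, frame_shape = as.integer(frame_shape),
                 roi_spec = spec, b0 = b0,
                 tube_gain_drift = tube_gain_drift,
                 pixel_noise_sd = pixel_noise_sd),
            class = "stack_sim_config")
}

#' Simulate a cinematic radiograph stack
#'
#' @param cfg a [stack_sim_config()].
#' @return A list with `stack` ([frame_stack()]), `roi_spec`, `signal` (the
#'   noiseless breathing trace `s(t)`) and `ground_truth`.
#' @export
simulate_stack <- function(cfg = stack_sim_config()) {
  stopifnot(inherits(cfg, "stack_sim_config"))
  tcfg <- cfg$trace_cfg
  tcfg$noise_sd <- 0                               # pixel noise is added per pixel below
  sim <- simulate_trace(tcfg)
  s <- sim$trace$value
  n <- length(s)
  H <- cfg$frame_shape[1L]; W <- cfg$frame_shape[2L]
  tsec <- sim$trace$time_ms / 1000
  g <- 1 + cfg$tube_gain_drift * sin(2 * pi * tsec / max(tsec[n], 1))
  frames <- array(0, c(n, H, W))
  lr <- cfg$roi_spec$lung_rois[[1L]]
  for (k in seq_len(n)) {
    fr <- matrix(cfg$b0 * g[k], H, W)
    fr[(lr[1L] + 1L):lr[2L], (lr[3L] + 1L):lr[4L]] <- cfg$b0 * g[k] * (1 + s[k])
    frames[k, , ] <- fr
  }
  if (cfg$pixel_noise_sd > 0)
    frames <- frames + with_seed(tcfg$seed,
      array(rnorm(length(frames), 0, cfg$pixel_noise_sd), dim(frames)))
  frames[frames < 0] <- 0
  list(stack = frame_stack(frames, frame_rate_hz = tcfg$sample_rate_hz),
       roi_spec = cfg$roi_spec, signal = sim$trace, ground_truth = sim$ground_truth)
}

#' Cohort presets: healthy, inflamed, treated
#'
#' Effect-size presets for the three study arms. `CN` (healthy control)
#' breathes with a compact pulse and a clear end-expiratory pause; `SAA`
#' (severe acute allergic airway inflammation) shows the obstructed
#' signature - reduced amplitude (lower air content, `b5`), a prolonged
#' breathing event without pause (airflow limitation, lower `b3`, higher
#' absolute time-to-peak `b1`) and a relatively shorter inspiration (lower
#' `t_in`); `SAA-DEX` (dexamethasone treated) is intermediate. Cycle lengths
#' stay near the anesthesia-controlled 1400 ms.
#'
#' @return Named list of per-group parameter lists
#'   (`breath_period_ms`, `pause_ms`, `inspiration_fraction`,
#'   `peak_amplitude`).
#' @export
cohort_presets <- function() {
  list(
    CN = list(breath_period_ms = 950, pause_ms = 450,
              inspiration_fraction = 0.46, peak_amplitude = 1.0),
    SAA = list(breath_period_ms = 1550, pause_ms = 0,
               inspiration_fraction = 0.34, peak_amplitude = 0.6),
    `SAA-DEX` = list(breath_period_ms = 1175, pause_ms = 250,
                     inspiration_fraction = 0.40, peak_amplitude = 0.8))
}

#' Cohort simulator configuration
#'
#' @param groups named list of group presets (default [cohort_presets()]).
#' @param n_per_group animals per group (default 6, >= 2).
#' @param variability inter-animal lognormal SDs:
#'   `c(amplitude = 0.15, timing = 0.03)`; amplitude applies to
#'   `peak_amplitude`, timing to `inspiration_fraction` and
#'   `breath_period_ms` (breathing timing is tightly controlled by
#'   anesthesia, so it varies less than amplitude).
#' @param noise_sd detector noise SD passed to each trace (default 0.02).
#' @param duration_s,sample_rate_hz acquisition settings.
#' @param seed integer seed; all animal draws derive from it.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(groups = cohort_presets(), n_per_group = 6L,
                              variability = c(amplitude = 0.15, timing = 0.03),
                              noise_sd = 0.02, duration_s = 34,
                              sample_rate_hz = 30, seed = 1L) {
  if (n_per_group < 2L) stop_xlf("n_per_group must be >= 2")
  if (is.null(names(groups))) stop_xlf("'groups' must be named")
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 variability = variability, noise_sd = noise_sd,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 seed = seed),
            class = "cohort_sim_config")
}

#' Simulate a cohort of animals with known ground truth
#'
#' Per-animal parameters are the group preset times multiplicative lognormal
#' draws (`exp(N(0, sd))`), keeping every parameter positive; each animal
#' then gets its own simulated scan. Deterministic given the seed.
#'
#' @param cfg a [cohort_sim_config()].
#' @return Named list (one element per group) of per-animal lists with
#'   `trace`, `ground_truth` and the drawn `params`.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  v_amp <- cfg$variability[["amplitude"]]
  v_tim <- cfg$variability[["timing"]]
  with_seed(cfg$seed, {
    out <- lapply(seq_along(cfg$groups), function(gi) {
      pr <- cfg$groups[[gi]]
      lapply(seq_len(cfg$n_per_group), function(ai) {
        amp <- pr$peak_amplitude * exp(rnorm(1, 0, v_amp))
        insp <- pr$inspiration_fraction * exp(rnorm(1, 0, v_tim))
        width <- pr$breath_period_ms * exp(rnorm(1, 0, v_tim))
        insp <- min(max(insp, 0.05), 0.95)
        tseed <- sample.int(.Machine$integer.max, 1L)
        tc <- trace_sim_config(duration_s = cfg$duration_s,
                               sample_rate_hz = cfg$sample_rate_hz,
                               breath_period_ms = width,
                               inspiration_fraction = insp,
                               peak_amplitude = amp,
                               noise_sd = cfg$noise_sd,
                               pause_ms = pr$pause_ms, seed = tseed)
        sim <- simulate_trace(tc)
        c(sim, list(params = data.frame(group = names(cfg$groups)[gi], animal = ai,
                                        peak_amplitude = amp,
                                        inspiration_fraction = insp,
                                        breath_period_ms = width,
                                        pause_ms = pr$pause_ms)))
      })
    })
    names(out) <- names(cfg$groups)
    out
  })
}

#' Analyze every animal of a simulated cohort
#'
#' @param cohort result of [simulate_cohort()].
#' @param ... passed to [analyze_trace()].
#' @return Named list of scan-summary data.frames (one row per animal),
#'   ready for [compare_groups()].
#' @export
cohort_summaries <- function(cohort, ...) {
  lapply(cohort, function(animals)
    do.call(rbind, lapply(animals, function(a) analyze_trace(a$trace, ...)$summary)))
}

#' Simulate a methacholine dose-response series
#'
#' Each animal is measured at baseline and after nebulization of increasing
#' methacholine concentrations. Bronchoconstriction is modeled as a
#' hyperbolic amplitude reduction, `amplitude * 1 / (1 + dose / d50)`, which
#' depresses `b5` and (through the flatter pulse) `b3` monotonically with
#' dose; a small lognormal repeat-measurement jitter is added per scan.
#'
#' @param doses concentrations in mg/ml, baseline first
#'   (default `c(0, 3, 10, 50)`).
#' @param preset group preset for the animals (default the healthy `CN`
#'   preset).
#' @param n_animals animals (default 6).
#' @param d50 dose halving the amplitude (default 40 mg/ml).
#' @param repeat_sd lognormal SD of scan-to-scan jitter (default 0.02).
#' @param variability,noise_sd,duration_s,sample_rate_hz,seed as in
#'   [cohort_sim_config()].
#' @return A list with `per_dose` (list over doses of per-animal
#'   `trace` + `ground_truth`), `doses`, and the per-animal base parameters.
#' @export
simulate_dose_series <- function(doses = c(0, 3, 10, 50),
                                 preset = cohort_presets()$CN,
                                 n_animals = 6L, d50 = 40, repeat_sd = 0.02,
                                 variability = c(amplitude = 0.15, timing = 0.03),
                                 noise_sd = 0.02, duration_s = 34,
                                 sample_rate_hz = 30, seed = 1L) {
  if (doses[1L] != 0) stop_xlf("first dose must be the 0 mg/ml baseline")
  with_seed(seed, {
    base <- data.frame(
      animal = seq_len(n_animals),
      peak_amplitude = preset$peak_amplitude *
        exp(rnorm(n_animals, 0, variability[["amplitude"]])),
      inspiration_fraction = pmin(pmax(preset$inspiration_fraction *
        exp(rnorm(n_animals, 0, variability[["timing"]])), 0.05), 0.95),
      breath_period_ms = preset$breath_period_ms *
        exp(rnorm(n_animals, 0, variability[["timing"]])))
    per_dose <- lapply(doses, function(d) {
      mult <- 1 / (1 + d / d50)
      lapply(seq_len(n_animals), function(ai) {
        amp <- base$peak_amplitude[ai] * mult * exp(rnorm(1, 0, repeat_sd))
        tc <- trace_sim_config(duration_s = duration_s,
                               sample_rate_hz = sample_rate_hz,
                               breath_period_ms = base$breath_period_ms[ai],
                               inspiration_fraction = base$inspiration_fraction[ai],
                               peak_amplitude = amp, noise_sd = noise_sd,
                               pause_ms = preset$pause_ms,
                               seed = sample.int(.Machine$integer.max, 1L))
        simulate_trace(tc)
      })
    })
    list(per_dose = per_dose, doses = doses, base_params = base)
  })
}
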