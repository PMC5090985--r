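# independent brute-force oracles and small builders used across tests

# run-finder oracle: scan sample by sample, mark maximal runs strictly above
# the level, drop runs touching either end or shorter than min_samples
bf_find_runs <- function(v, level, min_samples = 5L) {
  runs <- list()
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (v[i] > level) {
      j <- i
      while (j < n && v[j + 1L] > level) j <- j + 1L
      if (i > 1L && j < n && (j - i + 1L) >= min_samples)
        runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# stack whose lung and background regions take prescribed per-frame values
make_two_region_stack <- function(lung_vals, bkg_vals, rate = 30,
                                  shape = c(16L, 16L)) {
  stopifnot(length(lung_vals) == length(bkg_vals))
  frames <- array(0, c(length(lung_vals), shape))
  for (k in seq_along(lung_vals)) {
    fr <- matrix(bkg_vals[k], shape[1L], shape[2L])
    fr[5:12, 5:12] <- lung_vals[k]
    frames[k, , ] <- fr
  }
  frame_stack(frames, frame_rate_hz = rate)
}

two_region_rois <- function() roi_spec(list(c(4, 12, 4, 12)), c(0, 3, 0, 3))

# event object built directly, bypassing detection
make_event <- function(values, dt_ms = 10, level = min(values) - 1) {
  n <- length(values)
  times <- seq(0, by = dt_ms, length.out = n)
  structure(list(start_ms = -dt_ms / 2, end_ms = times[n] + dt_ms / 2,
                 sample_times_ms = c(-dt_ms / 2, times, times[n] + dt_ms / 2),
                 sample_values = c(level, values, level),
                 dt_ms = dt_ms, level = level, ma_m2 = 0),
            class = "breath_event")
}
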