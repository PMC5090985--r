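test_that("scan line sits at mean + 0.33 sample-SD", {
  tr <- xlf_trace(0:3, c(0, 1, 0, 1))
  expect_equal(scan_line_level(tr), 0.5 + 0.33 * sd(c(0, 1, 0, 1)))
  expect_equal(scan_line_level(tr), 0.69053, tolerance = 1e-5)
  withr::local_seed(1)
  v <- rnorm(100)
  v <- (v - mean(v)) / sd(v)     # mean 0, sample SD 1
  expect_equal(scan_line_level(xlf_trace(seq_along(v), v)), 0.33)
  expect_error(scan_line_level(xlf_trace(0:5, rep(2, 6))), "degenerate trace")
})

test_that("event detection matches the brute-force run-finder", {
  tr <- xlf_trace(0:9, rep(0, 10))
  expect_length(detect_breaths(tr, 1), 0)
  # one triangular pulse centered mid-trace
  tri <- c(rep(0, 10), seq(0, 1, length.out = 11), seq(1, 0, length.out = 11)[-1], rep(0, 10))
  ev <- detect_breaths(xlf_trace(seq_along(tri), tri), 0.5)
  expect_length(ev, 1)
  expect_gt(ev[[1]]$start_ms, 0)
  withr::local_seed(99)
  for (rep in 1:60) {
    n <- sample(20:1000, 1)
    v <- cumsum(rnorm(n))          # correlated, crossing-rich
    level <- stats::quantile(v, runif(1, 0.3, 0.9))
    got <- detect_breaths(xlf_trace(seq_len(n), v), level)
    want <- bf_find_runs(v, level)
    expect_length(got, length(want))
    for (k in seq_along(got)) {
      interior <- got[[k]]$sample_times_ms[-c(1, length(got[[k]]$sample_times_ms))]
      expect_equal(range(interior), as.numeric(want[[k]]), label = paste("run", k))
    }
  }
})

test_that("crossing times are linearly interpolated", {
  v <- c(0, 0, 1, 1, 1, 1, 1, 0, 0)
  ev <- detect_breaths(xlf_trace((0:8) * 10, v), 0.25)[[1]]
  expect_equal(ev$start_ms, 10 + 0.25 * 10)   # between samples 2 and 3
  expect_equal(ev$end_ms, 60 + 0.75 * 10)
})

test_that("a symmetric parabolic peak yields symmetric cubic parameters", {
  # y = 1 - 4 (p - 1/2)^2 sampled at 41 points; detection at level 0.5
  p <- seq(0, 1, length.out = 41)
  y <- 1 - 4 * (p - 0.5)^2
  res <- analyze_trace(xlf_trace(p * 400, y), level = 0.5, smooth_window = 1)
  prm <- res$params
  expect_equal(nrow(prm), 1)
  expect_equal(prm$t_in_pct, 50, tolerance = 1e-6)
  expect_equal(prm$b5, 1, tolerance = 1e-9)
  expect_equal(prm$b4, 0, tolerance = 1e-9)
  expect_lt(abs(prm$b2), 1e-12)
  # index units: p = x/40, so the quadratic coefficient 4 becomes 4/40^2
  expect_equal(prm$b3, 4 / 40^2, tolerance = 1e-9)
})

test_that("noiseless model events are recovered exactly", {
  # samples drawn from P with b4 = 0, peak inside the event
  dt <- 10
  x <- 0:40
  truth <- list(b1 = 16, b2 = 2e-5, b3 = 8e-4, b5 = 1)
  y <- truth$b2 * (x - truth$b1)^3 - truth$b3 * (x - truth$b1)^2 + truth$b5
  ev <- make_event(y, dt_ms = dt)
  prm <- fit_breath(ev)
  expect_equal(prm$b2, truth$b2, tolerance = 1e-9)
  expect_equal(prm$b3, truth$b3, tolerance = 1e-9)
  expect_equal(prm$b5, truth$b5, tolerance = 1e-9)
  expect_lt(abs(prm$b4), 1e-9)
  # b1 is measured from the interpolated event start, half a sample before x = 0
  expect_equal(prm$b1, truth$b1 + 0.5, tolerance = 1e-6)
})

test_that("degenerate events are rejected", {
  expect_error(fit_breath(make_event(rep(1, 10))), "flat")
  expect_error(fit_breath(make_event(c(1, 2, 1))), "fewer than 5")
  expect_error(fit_breaths(list()), "no breaths")
})

test_that("scan summaries average events and derive rate and slopes", {
  sim <- simulate_trace(trace_sim_config(noise_sd = 0, seed = 2))
  res <- analyze_trace(sim$trace)
  prm3 <- rbind(res$params[1, ], res$params[1, ], res$params[1, ])
  su <- summarize_scan(prm3, sim$trace, level = res$level)
  expect_equal(su$b3, res$params$b3[1])
  expect_equal(su$t_in_pct, res$params$t_in_pct[1])
  expect_equal(su$n_events, 3)
  # 24 events over a 1024-sample 30 fps record: 24 / (34.133 s / 60) bpm
  tr1024 <- simulate_trace(trace_sim_config(duration_s = 1024 / 30, noise_sd = 0))$trace
  res1024 <- analyze_trace(tr1024)
  expect_equal(res1024$summary$n_events, 24)
  expect_equal(res1024$summary$bpm, 24 / ((1024 / 30) / 60), tolerance = 1e-12)
  expect_equal(round(res1024$summary$bpm, 2), 42.19)
  expect_lt(res1024$summary$min_slope, 0)
  expect_gt(res1024$summary$max_slope, 0)
})

test_that("slope metrics alone work on event-free ramps", {
  tr <- xlf_trace((0:99) * 10, (0:99) * 0.02)    # 2 units per second
  sl <- trace_slopes(tr)
  expect_equal(unname(sl["max_slope"]), 2)
  expect_equal(unname(sl["min_slope"]), 2)
  expect_error(summarize_scan(NULL, tr), "no breaths")
})

test_that("band-pass keeps the breathing band and rejects DC and drift", {
  fs <- 1000
  t_ms <- 0:(10 * fs - 1)
  expect_lt(max(abs(bandpass_trace(xlf_trace(t_ms, rep(5, length(t_ms))))$value)), 1e-9)
  mid <- 2001:8000
  s5 <- sin(2 * pi * 5 * t_ms / 1000)
  g5 <- bandpass_trace(xlf_trace(t_ms, s5))
  expect_equal(max(abs(g5$value[mid])), 1, tolerance = 0.02)
  t40 <- 0:(40 * fs - 1)
  s005 <- sin(2 * pi * 0.05 * t40 / 1000)
  g005 <- bandpass_trace(xlf_trace(t40, s005))
  expect_lt(max(abs(g005$value[10001:30000])), 0.1)
  expect_error(bandpass_trace(xlf_trace((0:99) * (1000 / 30), rnorm(100))),
               "sampling rate too low")
})
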