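test_that("trace simulation is deterministic and counts complete pulses", {
  cfg <- trace_sim_config(seed = 42)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$value, b$trace$value)
  # 34.13 s at one 1400 ms pulse per cycle: 24 complete pulses
  g <- simulate_trace(trace_sim_config(duration_s = 1024 / 30, noise_sd = 0))$ground_truth
  expect_equal(nrow(g), 24)
  expect_equal(g$end_ms - g$start_ms, rep(1400, 24))
  # pulse boundaries tile the cycle grid exactly
  expect_equal(g$start_ms, (0:23) * 1400)
  expect_error(simulate_trace(trace_sim_config(breath_period_ms = 100)),
               "shorter than 5 samples")
})

test_that("ground-truth events span the configured pauses", {
  g <- simulate_trace(trace_sim_config(pause_ms = 400, noise_sd = 0))$ground_truth
  expect_equal(diff(g$start_ms), rep(1800, nrow(g) - 1))
})

test_that("noiseless closure: extract -> detect -> fit reproduces ground truth", {
  for (cfg in list(trace_sim_config(noise_sd = 0),
                   trace_sim_config(noise_sd = 0, inspiration_fraction = 0.34,
                                    breath_period_ms = 1550, peak_amplitude = 0.6))) {
    sim <- simulate_trace(cfg)
    res <- analyze_trace(sim$trace)
    gt <- sim$ground_truth
    expect_equal(res$summary$n_events, nrow(gt))
    expect_lt(max(abs(res$params$b2 / gt$b2 - 1)), 1e-6)
    expect_lt(max(abs(res$params$b3 / gt$b3 - 1)), 1e-6)
    expect_lt(max(abs(res$params$b5 / gt$b5 - 1)), 1e-6)
    gl <- true_params_at_level(gt, res$level)
    expect_lt(max(abs(res$params$b1 - gl$b1)), 1)      # within one sample
    # every detected event contains its ground-truth peak time
    peaks <- gt$start_ms + gt$b1 * attr(gt, "dt_ms")
    for (k in seq_along(res$events))
      expect_true(res$events[[k]]$start_ms < peaks[k] && peaks[k] < res$events[[k]]$end_ms)
  }
})

test_that("level reparameterization keeps shape parameters and is sane", {
  sim <- simulate_trace(trace_sim_config(noise_sd = 0))
  gt <- sim$ground_truth
  gl <- true_params_at_level(gt, 0.3)
  expect_equal(gl$b3, gt$b3)
  expect_equal(gl$b5, gt$b5)
  expect_true(all(gl$start_ms > gt$start_ms & gl$end_ms < gt$end_ms))
  expect_true(all(gl$t_in_pct > 0 & gl$t_in_pct < 100))
  expect_error(true_params_at_level(gt, 2), "strictly between")
})

test_that("decreasing the inspiration fraction decreases t_in", {
  tins <- vapply(c(0.30, 0.38, 0.46), function(f) {
    sim <- simulate_trace(trace_sim_config(noise_sd = 0, inspiration_fraction = f))
    analyze_trace(sim$trace)$summary$t_in_pct
  }, 0)
  expect_true(all(diff(tins) > 0))
})

test_that("stack forward model closes through XTF extraction", {
  scfg <- stack_sim_config(trace_sim_config(duration_s = 8, noise_sd = 0, seed = 3),
                           frame_shape = c(32L, 32L),
                           lung_roi = c(8, 24, 8, 24), background_roi = c(0, 6, 0, 6))
  sim <- simulate_stack(scfg)
  x <- compute_xtf(sim$stack, sim$roi_spec)
  expect_lt(max(abs(x$value - sim$signal$value)), 1e-9)
  # tube gain drift enters only through the documented g(t)/mean(g) factor
  scfg2 <- scfg; scfg2$tube_gain_drift <- 0.05
  sim2 <- simulate_stack(scfg2)
  x2 <- compute_xtf(sim2$stack, sim2$roi_spec)
  expect_lt(max(abs(x2$value - sim2$signal$value)), 0.1)
  expect_gt(max(abs(x2$value - sim2$signal$value)), 1e-9)
})

test_that("moderate pixel noise leaves scan-mean b5 within 5% of truth", {
  ok <- 0
  for (s in 1:10) {
    scfg <- stack_sim_config(trace_sim_config(duration_s = 20, noise_sd = 0, seed = s),
                             frame_shape = c(32L, 32L),
                             lung_roi = c(8, 24, 8, 24), background_roi = c(0, 6, 0, 6),
                             pixel_noise_sd = 10)   # 1% of B0
    sim <- simulate_stack(scfg)
    res <- analyze_trace(compute_xtf(sim$stack, sim$roi_spec))
    gt <- sim$ground_truth
    ok <- ok + (abs(res$summary$b5 / gt$b5[1] - 1) < 0.05)
  }
  expect_gte(ok, 9)
})

test_that("cohort simulation is reproducible and respects presets", {
  cfg <- cohort_sim_config(n_per_group = 2, seed = 7)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$CN[[1]]$trace$value, b$CN[[1]]$trace$value)
  expect_named(a, c("CN", "SAA", "SAA-DEX"))
  # zero variability: all animals of a group share parameters
  cfg0 <- cohort_sim_config(n_per_group = 3, variability = c(amplitude = 0, timing = 0),
                            noise_sd = 0, seed = 1)
  c0 <- simulate_cohort(cfg0)
  expect_identical(c0$CN[[1]]$trace$value, c0$CN[[3]]$trace$value)
  expect_error(cohort_sim_config(n_per_group = 1), "n_per_group")
})

test_that("cohort presets reproduce the disease signature and treatment effect", {
  su <- cohort_summaries(simulate_cohort(cohort_sim_config(seed = 11)))
  cn <- colMeans(su$CN); saa <- colMeans(su$SAA); dex <- colMeans(su$`SAA-DEX`)
  expect_gt(saa["b1"], cn["b1"])          # later absolute peak in disease
  expect_lt(saa["t_in_pct"], cn["t_in_pct"])  # relatively shorter inspiration
  expect_lt(saa["b3"], cn["b3"])          # reduced airflow dynamic
  expect_lt(saa["b5"], cn["b5"])          # reduced peak air content
  # treated animals sit between disease and control
  expect_true(dex["b3"] > saa["b3"] && dex["b3"] < cn["b3"])
  expect_true(dex["t_in_pct"] > saa["t_in_pct"] && dex["t_in_pct"] < cn["t_in_pct"])
  expect_true(dex["b5"] > saa["b5"] && dex["b5"] < cn["b5"])
})

test_that("raised-cosine pulses exercise model mismatch but keep timing truth", {
  sim <- simulate_trace(trace_sim_config(noise_sd = 0, shape = "raised_cosine"))
  res <- analyze_trace(sim$trace)
  expect_equal(res$summary$n_events, nrow(sim$ground_truth))
  expect_true(all(is.na(sim$ground_truth$b3)))
  expect_equal(res$summary$b5, 1, tolerance = 0.02)  # peak height still recovered
})

test_that("dose series reduces amplitude monotonically with concentration", {
  ds <- simulate_dose_series(seed = 3, n_animals = 3, duration_s = 20)
  med_amp <- vapply(ds$per_dose, function(an)
    mean(vapply(an, function(a) max(a$trace$value), 0)), 0)
  expect_true(all(diff(med_amp) < 0))
  expect_error(simulate_dose_series(doses = c(3, 10)), "baseline")
})
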