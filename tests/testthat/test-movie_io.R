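test_that("stack construction enforces geometry and positivity", {
  s <- frame_stack(array(1, c(4, 8, 8)), frame_rate_hz = 30)
  expect_equal(dim(s$frames), c(4, 8, 8))
  expect_error(frame_stack(array(1, c(1, 8, 8)), 30), "stack too short")
  expect_error(frame_stack(array(-1, c(2, 4, 4)), 30), "nonnegative")
  expect_error(frame_stack(array(1, c(2, 4, 4)), 0), "positive")
  expect_error(frame_stack(list(matrix(0, 4, 4), matrix(0, 5, 4)), 30),
               "inconsistent page shapes")
})

test_that("protocol stack duration matches the acquisition arithmetic", {
  s <- frame_stack(array(1, c(1024, 2, 2)), frame_rate_hz = 30)
  expect_equal(stack_duration_s(s), 1024 / 30)
  expect_equal(round(stack_duration_s(s), 2), 34.13)
})

test_that("stack TIFF round-trip preserves frames and metadata", {
  withr::local_seed(42)
  frames <- array(runif(3 * 6 * 5, 0, 2000), c(3, 6, 5))
  s <- frame_stack(frames, frame_rate_hz = 30, pixel_spacing_mm = 0.05)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, path)
  r <- read_stack(path)
  expect_equal(r$frame_rate_hz, 30)
  expect_equal(r$pixel_spacing_mm, 0.05)
  expect_lt(max(abs(r$frames - frames)), 1e-6 * max(frames))
  # frame rate is required, never silently defaulted
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path), "missing frame rate")
  expect_equal(read_stack(path, frame_rate_hz = 15)$frame_rate_hz, 15)
  expect_error(read_stack("no/such/file.tif"), "missing file")
})

test_that("single-page TIFF is rejected as too short", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), path)
  expect_error(read_stack(path, frame_rate_hz = 1), "stack too short")
})

test_that("ROI specs validate overlap, bounds and emptiness", {
  expect_silent(roi_spec(list(c(10, 40, 10, 30)), c(0, 5, 0, 5), frame_shape = c(64, 64)))
  expect_error(roi_spec(list(c(10, 40, 10, 30)), c(10, 40, 10, 30)), "overlaps")
  expect_error(roi_spec(list(c(60, 70, 0, 5)), c(0, 5, 10, 15), frame_shape = c(64, 64)),
               "outside frame")
  expect_error(roi_spec(list(c(5, 5, 0, 2)), c(0, 2, 0, 2)), "empty ROI")
})

test_that("ROI JSON round-trip and validation on load", {
  spec <- roi_spec(list(c(10, 40, 10, 30), c(10, 40, 34, 54)), c(0, 5, 0, 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_spec(spec, path)
  r <- load_roi_spec(path, frame_shape = c(64, 64))
  expect_equal(r$lung_rois, spec$lung_rois)
  expect_equal(r$background_roi, spec$background_roi)
  expect_error(load_roi_spec(path, frame_shape = c(32, 32)), "outside frame")
})

test_that("ROI validation agrees with a brute-force rectangle enumerator", {
  # every rectangle on a 0..4 grid; pixel-set oracle for overlap and bounds
  rects <- list()
  for (r0 in 0:3) for (r1 in (r0 + 1):4) for (c0 in 0:3) for (c1 in (c0 + 1):4)
    rects[[length(rects) + 1L]] <- c(r0, r1, c0, c1)
  pixset <- function(r) {
    m <- matrix(FALSE, 8, 8)
    m[(r[1] + 1):r[2], (r[3] + 1):r[4]] <- TRUE
    m
  }
  for (a in rects) for (b in rects) {
    expect_overlap <- any(pixset(a) & pixset(b))
    got_err <- inherits(tryCatch(roi_spec(list(a), b), error = identity), "error")
    expect_identical(got_err, expect_overlap,
                     info = paste("lung", toString(a), "bkg", toString(b)))
  }
  # out-of-bounds against a 3 x 3 frame
  for (a in rects) {
    oob <- a[2] > 3 || a[4] > 3
    got_err <- inherits(tryCatch(roi_spec(list(a), c(90, 91, 90, 91), frame_shape = c(3, 3)),
                                 error = identity), "error")
    expect_true(got_err >= oob)  # bkg is always out of bounds here; lung may be too
  }
  bkg0 <- c(3, 4, 3, 4)
  for (a in rects) {
    oob <- a[2] > 4 || a[4] > 4
    overlaps_bkg <- any(pixset(a)[1:8, 1:8] & pixset(bkg0)[1:8, 1:8])
    spec_ok <- !inherits(tryCatch(
      validate_roi_spec(roi_spec(list(a), bkg0), c(4, 4)), error = identity), "error")
    expect_identical(spec_ok, !(oob || overlaps_bkg), info = toString(a))
  }
})

test_that("trace CSV round-trip is lossless to 1e-9", {
  t_ms <- (0:1023) * (1000 / 30)
  withr::local_seed(7)
  v <- rnorm(1024)
  tr <- xlf_trace(t_ms, v, detrended = TRUE, source = "sim")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  r <- read_trace(path)
  expect_lt(max(abs(r$time_ms - t_ms)), 1e-9)
  expect_lt(max(abs(r$value - v)), 1e-9)
})

test_that("malformed traces are rejected", {
  expect_error(xlf_trace(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(xlf_trace(c(0, 1), c(1, NA)), "finite")
  expect_error(xlf_trace(c(0, 1, 2), c(1, 2)), "lengths differ")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,value", "0,1.0", "0,1.1"), path)
  expect_error(read_trace(path), "strictly increasing")
  writeLines(c("a,b", "0,1"), path)
  expect_error(read_trace(path), "header")
})
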