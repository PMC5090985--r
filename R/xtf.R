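#' Per-frame mean transmission over one or more rectangles
#'
#' Averages all pixels in the union of the given rectangles in every frame,
#' so multiple lung lobes pool into one area-weighted mean. Overlapping
#' rectangles count each pixel once.
#'
#' @param stack a [frame_stack()].
#' @param roi one rectangle `c(row0, row1, col0, col1)` (0-based, half-open)
#'   or a list of rectangles.
#' @return numeric vector, one mean per frame.
#' @export
mean_transmission <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"))
  s <- roi_sums(stack, roi)
  s$sum / s$npix
}

# per-frame pixel sums over the union mask; kept separate from the mean so
# compute_xtf can arrange the arithmetic to cancel a global gain exactly
roi_sums <- function(stack, roi) {
  if (!is.list(roi)) roi <- list(roi)
  roi <- lapply(roi, as_rect)
  d <- dim(stack$frames)
  mask <- matrix(FALSE, d[2L], d[3L])
  for (r in roi) {
    if (!rect_inside(r, d[2:3])) stop_xlf("ROI outside frame")
    mask[(r[1L] + 1L):r[2L], (r[3L] + 1L):r[4L]] <- TRUE
  }
  npix <- sum(mask)
  if (npix == 0L) stop_xlf("empty ROI union")
  flat <- matrix(stack$frames, nrow = d[1L])   # T x (H*W), column-major over (H,W)
  s <- rowSums(flat[, as.vector(mask), drop = FALSE])
  list(sum = s, npix = npix)
}

#' Compute the x-ray transmission function (XTF)
#'
#' For each frame the pooled lung-ROI mean transmission `L(t)` and the
#' background mean `B(t)` are taken; the XTF is their difference normalized by
#' the time-averaged background signal,
#' `XTF(t) = (L(t) - B(t)) / mean(B)`,
#' which cancels global tube-intensity fluctuations. The ratio is unitless.
#' The arithmetic is arranged over pixel sums so that a constant detector gain
#' cancels exactly (bit-for-bit) rather than only to rounding error.
#'
#' @param stack a [frame_stack()].
#' @param rois an [roi_spec()].
#' @return An [xlf_trace()] with `detrended = FALSE` and sample times
#'   `t_k = k / frame_rate_hz` (ms).
#' @export
compute_xtf <- function(stack, rois) {
  stopifnot(inherits(stack, "frame_stack"), inherits(rois, "roi_spec"))
  lung <- roi_sums(stack, rois$lung_rois)
  bkg <- roi_sums(stack, list(rois$background_roi))
  nT <- dim(stack$frames)[1L]
  sum_b <- sum(bkg$sum)
  if (sum_b == 0) stop_xlf("degenerate background: time-averaged background is zero")
  # (SL/a - SB/b) / (sum(SB)/(b*T))  ==  T*(b*SL - a*SB) / (a*sum(SB))
  value <- (nT * (bkg$npix * lung$sum - lung$npix * bkg$sum)) / (lung$npix * sum_b)
  xlf_trace(time_ms = (seq_len(nT) - 1L) * 1000 / stack$frame_rate_hz,
            value = value, detrended = FALSE, source = "compute_xtf")
}

#' Detrending configuration
#'
#' @param window moving-average window in samples (default 200, about 6.7 s at
#'   30 fps — long relative to the ~1.4 s breathing cycle, so breaths average
#'   out and only the drift survives).
#' @param poly_order order of the polynomial fitted to the smoothed series
#'   (default 2).
#' @return A list of class `detrend_config`.
#' @export
detrend_config <- function(window = 200L, poly_order = 2L) {
  window <- as.integer(window); poly_order <- as.integer(poly_order)
  if (window < 1L) stop_xlf("'window' must be >= 1")
  if (poly_order < 0L || poly_order > 5L) stop_xlf("'poly_order' must be in 0..5")
  structure(list(window = window, poly_order = poly_order), class = "detrend_config")
}

moving_average <- function(v, w) {
  n <- length(v)
  left <- w %/% 2L
  right <- w - 1L - left
  # reflect padding keeps the output the same length as the input
  pad <- c(v[(left + 1L):2L], v, v[(n - 1L):(n - right)])
  cs <- cumsum(c(0, pad))
  (cs[(w + 1L):(w + n)] - cs[1L:n]) / w
}

#' Remove slow drift from an XTF trace
#'
#' Mimics the drift correction of the method: a centered moving average
#' (reflect-padded) smooths the trace, a polynomial of `poly_order` in time is
#' least-squares fitted to the smoothed series, and that polynomial is
#' subtracted from the *original* trace. The polynomial is fitted on the
#' interior of the smoothed series (samples whose averaging window contains no
#' padding), where the moving average of a polynomial is again a polynomial of
#' the same degree; together with a final re-centering to zero interior mean
#' this makes the operator annihilate any polynomial of degree
#' `<= poly_order` exactly, and makes it idempotent to machine precision.
#'
#' @param trace an [xlf_trace()].
#' @param cfg a [detrend_config()].
#' @return The detrended [xlf_trace()] (`detrended = TRUE`).
#' @export
detrend_xtf <- function(trace, cfg = detrend_config()) {
  stopifnot(inherits(trace, "xlf_trace"), inherits(cfg, "detrend_config"))
  n <- length(trace$value)
  w <- cfg$window
  if (n < w) stop_xlf("trace shorter than window (%d < %d)", n, w)
  sm <- moving_average(trace$value, w)
  left <- w %/% 2L
  right <- w - 1L - left
  interior <- (left + 1L):(n - right)
  # time in seconds, centered at the trace midpoint for conditioning
  ts <- (trace$time_ms - mean(range(trace$time_ms))) / 1000
  # an even window is half a sample off center; regressing the smoothed series
  # against the window-centroid times keeps polynomial drift exactly fittable
  centroid <- mean((-left):right) * trace_dt_ms(trace) / 1000
  basis_fit <- outer(ts + centroid, 0:cfg$poly_order, `^`)
  basis <- outer(ts, 0:cfg$poly_order, `^`)
  fit <- lm.fit(basis_fit[interior, , drop = FALSE], sm[interior])
  resid <- trace$value - drop(basis %*% fit$coefficients)
  resid <- resid - mean(resid[interior])
  xlf_trace(trace$time_ms, resid, detrended = TRUE,
            source = paste0(trace$source, if (nzchar(trace$source)) " " else "", "detrended"))
}
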