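#' Construct a frame stack
#'
#' A `frame_stack` holds an ordered cinematic radiograph movie as a numeric
#' `T x H x W` array of nonnegative transmission intensities (arbitrary
#' detector units) together with its acquisition frame rate. The standard
#' murine protocol acquires 1024 frames continuously at 30 frames per second,
#' i.e. about 34 s of chest motion.
#'
#' @param frames numeric `T x H x W` array, or a list of `T` equal-sized
#'   matrices (frames in acquisition order).
#' @param frame_rate_hz acquisition rate in frames per second (> 0). Required;
#'   there is no silent default.
#' @param pixel_spacing_mm optional isotropic pixel spacing in mm.
#' @return An object of class `frame_stack` with elements `frames`,
#'   `frame_rate_hz`, `pixel_spacing_mm`.
#' @examples
#' s <- frame_stack(array(1, c(4, 8, 8)), frame_rate_hz = 30)
#' stack_duration_s(s)
#' @export
frame_stack <- function(frames, frame_rate_hz, pixel_spacing_mm = NULL) {
  if (is.list(frames)) {
    shapes <- vapply(frames, function(f) paste(dim(as.matrix(f)), collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop_xlf("inconsistent page shapes: %s", paste(unique(shapes), collapse = ", "))
    d <- dim(as.matrix(frames[[1L]]))
    frames <- aperm(array(unlist(frames), c(d[1L], d[2L], length(shapes))), c(3L, 1L, 2L))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_xlf("'frames' must be a T x H x W array or a list of matrices")
  if (dim(frames)[1L] < 2L)
    stop_xlf("stack too short: need at least 2 frames, got %d", dim(frames)[1L])
  if (!all(is.finite(frames)) || any(frames < 0))
    stop_xlf("all intensities must be finite and nonnegative")
  check_scalar(frame_rate_hz, "frame_rate_hz")
  if (!is.null(pixel_spacing_mm)) check_scalar(pixel_spacing_mm, "pixel_spacing_mm")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d at %g fps (%.2f s)\n",
              d[1L], d[2L], d[3L], x$frame_rate_hz, stack_duration_s(x)))
  invisible(x)
}

#' Acquisition duration of a stack in seconds
#'
#' Frames are acquired continuously, so the duration is `T / frame_rate_hz`.
#'
#' @param stack a [frame_stack()].
#' @return duration in seconds.
#' @export
stack_duration_s <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[1L] / stack$frame_rate_hz
}

#' Read a cinematic radiograph stack from a multi-page TIFF
#'
#' The frame rate is not stored by all acquisition systems; it is taken from
#' the `frame_rate_hz` argument or, failing that, from a JSON sidecar file
#' `<path>.json` with a `frame_rate_hz` field (as written by [write_stack()]).
#' A `scale` field in the sidecar, if present, rescales the stored `[0, 1]`
#' TIFF samples back to detector units.
#'
#' @param path path to a multi-page TIFF file.
#' @param frame_rate_hz frames per second; overrides any sidecar value.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, frame_rate_hz = NULL) {
  if (!file.exists(path)) stop_xlf("missing file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop_xlf("stack too short: need at least 2 pages, got %d", length(pages))
  meta <- read_sidecar(path)
  if (is.null(frame_rate_hz)) frame_rate_hz <- meta$frame_rate_hz
  if (is.null(frame_rate_hz))
    stop_xlf("missing frame rate: give 'frame_rate_hz' or provide a sidecar %s", sidecar_path(path))
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  st <- frame_stack(pages, frame_rate_hz = frame_rate_hz,
                    pixel_spacing_mm = meta$pixel_spacing_mm)
  if (scale != 1) st$frames <- st$frames * scale
  st
}

#' Write a stack to a multi-page TIFF plus JSON sidecar
#'
#' Samples are stored as 32-bit values in `[0, 1]`; intensities above 1 are
#' divided by their maximum and the factor is recorded in the sidecar so that
#' [read_stack()] restores detector units. XTF extraction is invariant to this
#' global gain in any case.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(stack$frames)
  scale <- if (mx > 1) mx else 1
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[1L]), function(k) stack$frames[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(frame_rate_hz = stack$frame_rate_hz, scale = scale,
         pixel_spacing_mm = stack$pixel_spacing_mm),
    sidecar_path(path), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else list()
}

# rectangles ------------------------------------------------------------------
# all rectangles are 0-based half-open [row0, row1) x [col0, col1)

as_rect <- function(r, what = "ROI") {
  r <- as.numeric(unlist(r))
  if (length(r) != 4L || any(!is.finite(r)) || any(r != floor(r)))
    stop_xlf("%s must be four integers [row0, row1, col0, col1]", what)
  if (any(r < 0)) stop_xlf("%s has negative coordinates", what)
  if (r[1L] >= r[2L] || r[3L] >= r[4L]) stop_xlf("empty ROI: %s", paste(r, collapse = ","))
  r
}

rect_area <- function(r) (r[2L] - r[1L]) * (r[4L] - r[3L])

rects_overlap <- function(a, b) {
  a[1L] < b[2L] && b[1L] < a[2L] && a[3L] < b[4L] && b[3L] < a[4L]
}

rect_inside <- function(r, frame_shape) {
  r[2L] <= frame_shape[1L] && r[4L] <= frame_shape[2L]
}

#' Construct and validate an ROI specification
#'
#' Holds one or more lung regions of interest (typically left and right lobe,
#' placed at maximal contraction and kept static) plus one background region
#' outside the animal used for tube-intensity calibration. Rectangles are
#' 0-based half-open `[row0, row1) x [col0, col1)`.
#'
#' @param lung_rois a list of rectangles (each `c(row0, row1, col0, col1)`),
#'   or a single rectangle.
#' @param background_roi one rectangle; must not overlap any lung ROI.
#' @param frame_shape optional `c(H, W)`; when given, all rectangles are
#'   checked against the frame bounds.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(list(c(10, 40, 10, 30)), c(0, 5, 0, 5), frame_shape = c(64, 64))
#' @export
roi_spec <- function(lung_rois, background_roi, frame_shape = NULL) {
  if (!is.list(lung_rois)) lung_rois <- list(lung_rois)
  if (length(lung_rois) < 1L) stop_xlf("need at least one lung ROI")
  lung_rois <- lapply(lung_rois, as_rect, what = "lung ROI")
  background_roi <- as_rect(background_roi, what = "background ROI")
  for (r in lung_rois)
    if (rects_overlap(background_roi, r))
      stop_xlf("background overlaps lung ROI")
  spec <- structure(list(lung_rois = lung_rois, background_roi = background_roi),
                    class = "roi_spec")
  if (!is.null(frame_shape)) validate_roi_spec(spec, frame_shape)
  spec
}

#' Check an ROI specification against frame bounds
#'
#' @param spec an [roi_spec()].
#' @param frame_shape `c(H, W)` of the frames the ROIs apply to.
#' @return `spec`, invisibly; errors if any rectangle extends outside.
#' @export
validate_roi_spec <- function(spec, frame_shape) {
  stopifnot(inherits(spec, "roi_spec"))
  for (r in c(spec$lung_rois, list(spec$background_roi)))
    if (!rect_inside(r, frame_shape))
      stop_xlf("ROI outside frame: [%s) on %d x %d", paste(r, collapse = ","),
               frame_shape[1L], frame_shape[2L])
  invisible(spec)
}

#' Load an ROI specification from JSON
#'
#' The document must contain `lung_rois` (array of `[row0,row1,col0,col1]`
#' rectangles) and `background_roi` (one rectangle).
#'
#' @param path JSON file path.
#' @param frame_shape optional `c(H, W)` for bounds checking.
#' @return An [roi_spec()].
#' @export
load_roi_spec <- function(path, frame_shape = NULL) {
  if (!file.exists(path)) stop_xlf("missing file: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$lung_rois) || is.null(doc$background_roi))
    stop_xlf("ROI spec must have 'lung_rois' and 'background_roi'")
  lungs <- doc$lung_rois
  if (is.matrix(lungs)) lungs <- lapply(seq_len(nrow(lungs)), function(i) lungs[i, ])
  roi_spec(lungs, doc$background_roi, frame_shape = frame_shape)
}

#' Write an ROI specification to JSON
#'
#' @param spec an [roi_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_spec <- function(spec, path) {
  stopifnot(inherits(spec, "roi_spec"))
  jsonlite::write_json(list(lung_rois = spec$lung_rois,
                            background_roi = spec$background_roi),
                       path, digits = NA)
  invisible(path)
}

# traces ----------------------------------------------------------------------

#' Construct an XTF / breathing trace
#'
#' The central signal of the method: a unitless value-versus-time series with
#' strictly increasing sample times in milliseconds. Raw XTF traces carry
#' `detrended = FALSE`; [detrend_xtf()] sets the flag.
#'
#' @param time_ms strictly increasing nonnegative sample times (ms).
#' @param value finite numeric samples, same length as `time_ms`.
#' @param detrended logical flag.
#' @param source free-text provenance label.
#' @return An object of class `xlf_trace`.
#' @export
xlf_trace <- function(time_ms, value, detrended = FALSE, source = "") {
  time_ms <- as.numeric(time_ms); value <- as.numeric(value)
  if (length(time_ms) != length(value))
    stop_xlf("time and value lengths differ (%d vs %d)", length(time_ms), length(value))
  if (length(time_ms) < 2L) stop_xlf("trace too short")
  if (any(!is.finite(time_ms)) || any(time_ms < 0))
    stop_xlf("times must be finite and nonnegative")
  if (any(diff(time_ms) <= 0)) stop_xlf("times not strictly increasing")
  if (any(!is.finite(value))) stop_xlf("values must be finite")
  structure(list(time_ms = time_ms, value = value,
                 detrended = isTRUE(detrended), source = as.character(source)),
            class = "xlf_trace")
}

#' @export
print.xlf_trace <- function(x, ...) {
  cat(sprintf("xlf_trace: %d samples over %.1f ms%s%s\n",
              length(x$value), diff(range(x$time_ms)),
              if (x$detrended) ", detrended" else "",
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Median sampling interval of a trace in ms
#' @param trace an [xlf_trace()].
#' @return sampling interval (ms).
#' @export
trace_dt_ms <- function(trace) median(diff(trace$time_ms))

#' Trace duration in seconds
#'
#' Span plus one sampling interval, so a uniformly sampled trace of `n`
#' samples at rate `r` has duration `n / r` (matching the acquisition time).
#'
#' @param trace an [xlf_trace()].
#' @return duration in seconds.
#' @export
trace_duration_s <- function(trace) {
  (diff(range(trace$time_ms)) + trace_dt_ms(trace)) / 1000
}

#' Write / read a trace as CSV
#'
#' Plain CSV with header `time_ms,value`; numbers are written with 15
#' significant digits so that a write/read round-trip is the identity to
#' better than 1e-12 relative error.
#'
#' @param trace an [xlf_trace()].
#' @param path CSV file path.
#' @return `write_trace`: `path` invisibly; `read_trace`: an [xlf_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "xlf_trace"))
  df <- data.frame(time_ms = format(trace$time_ms, digits = 15, trim = TRUE,
                                    scientific = FALSE),
                   value = format(trace$value, digits = 15, trim = TRUE))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param detrended,source passed to [xlf_trace()]; `source` defaults to the
#'   file name.
#' @export
read_trace <- function(path, detrended = FALSE, source = basename(path)) {
  if (!file.exists(path)) stop_xlf("missing file: %s", path)
  df <- tryCatch(read.csv(path, colClasses = "numeric"),
                 error = function(e) stop_xlf("malformed trace CSV: %s", conditionMessage(e)))
  if (!identical(names(df)[1:2], c("time_ms", "value")))
    stop_xlf("trace CSV must have header 'time_ms,value'")
  xlf_trace(df$time_ms, df$value, detrended = detrended, source = source)
}
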