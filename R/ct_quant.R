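#' Construct a 3-D refractive-index volume
#'
#' Holds a reconstructed phase-contrast CT volume whose voxel values are
#' proportional to the delta-part of the complex refractive index
#' (delta-values); higher values mean denser soft tissue, air is near zero.
#'
#' @param voxels 3-D numeric array (all finite).
#' @param voxel_size_um isotropic voxel edge in micrometers (default 9).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size_um = 9) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_xlf("'voxels' must be a 3-D array")
  if (!all(is.finite(voxels))) stop_xlf("voxel values must be finite")
  check_scalar(voxel_size_um, "voxel_size_um")
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um), class = "volume3d")
}

#' Read / write a volume as a multi-page TIFF (pages = z slices)
#'
#' Values are stored in `[0, 1]`; larger dynamic ranges are rescaled with the
#' factor kept in a JSON sidecar, like [write_stack()].
#'
#' @param path TIFF path.
#' @param voxel_size_um voxel size override for [read_volume()].
#' @return `read_volume`: a [volume3d()]; `write_volume`: `path` invisibly.
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop_xlf("missing file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_sidecar(path)
  if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
  if (is.null(voxel_size_um)) voxel_size_um <- 9
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  d <- dim(pages[[1L]])
  vox <- array(unlist(pages), c(d[1L], d[2L], length(pages))) * scale
  volume3d(vox, voxel_size_um = voxel_size_um)
}

#' @rdname read_volume
#' @param vol a [volume3d()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  mx <- max(vol$voxels); mn <- min(vol$voxels)
  scale <- if (mx > 1 || mn < 0) max(abs(mx), 1) else 1
  if (mn < 0) stop_xlf("negative delta-values cannot be stored")
  pages <- lapply(seq_len(dim(vol$voxels)[3L]), function(z) vol$voxels[, , z] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size_um, scale = scale),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a cubic volume of interest
#'
#' @param origin 0-based voxel indices `c(x0, y0, z0)` of the cube corner.
#' @param edge edge length in voxels (>= 1).
#' @return An object of class `voi_box`.
#' @export
voi_box <- function(origin, edge) {
  origin <- as.integer(origin)
  if (length(origin) != 3L || any(origin < 0L)) stop_xlf("origin must be 3 nonnegative indices")
  edge <- as.integer(edge)
  if (edge < 1L) stop_xlf("edge must be >= 1 voxel")
  structure(list(origin = origin, edge = edge), class = "voi_box")
}

voi_inside <- function(voi, dims) all(voi$origin + voi$edge <= dims)

vois_overlap <- function(a, b) {
  all(a$origin < b$origin + b$edge & b$origin < a$origin + a$edge)
}

voi_values <- function(vol, voi) {
  o <- voi$origin; e <- voi$edge
  vol$voxels[(o[1L] + 1L):(o[1L] + e), (o[2L] + 1L):(o[2L] + e), (o[3L] + 1L):(o[3L] + e)]
}

#' Global Otsu threshold of a volume
#'
#' Maximizes the between-class variance of the global voxel histogram;
#' separates the (dark) air compartment from soft tissue and liquids.
#' Deterministic for a given volume.
#'
#' @param x numeric array or vector of voxel values.
#' @param levels number of histogram bins (default 256).
#' @return the threshold value (voxels strictly above it count as non-air).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1L] == rng[2L]) stop_xlf("constant volume: no threshold separates air from tissue")
  breaks <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  h <- as.numeric(tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE), levels), levels))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(levels))
  n <- w[levels]; mtot <- mu[levels]
  w0 <- w[-levels]; mu0 <- mu[-levels]
  between <- (mtot * w0 - n * mu0)^2 / (w0 * (n - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]
}

#' Quantify soft-tissue content in volumes of interest
#'
#' For each VOI, voxels above the threshold count as non-air (soft tissue
#' and liquids): `vol_ratio` is their fraction of the VOI and `mean_delta`
#' the mean delta-value over them (reported as `NA` for an all-air VOI, not
#' zero). The canonical protocol places eight non-overlapping 2 x 2 x 2 mm
#' VOIs in the lung periphery.
#'
#' @param vol a [volume3d()].
#' @param vois list of [voi_box()]es; must be pairwise non-overlapping and
#'   inside the volume.
#' @param threshold numeric threshold, or `"otsu"` for a global
#'   [otsu_threshold()] of the whole volume.
#' @return A list of class `voi_quant` with `per_voi` (data.frame:
#'   `voi`, `vol_ratio`, `mean_delta`, `n_voxels`), `threshold`,
#'   `mean_vol_ratio` and `mean_delta` aggregates.
#' @export
quantify_vois <- function(vol, vois, threshold = "otsu") {
  stopifnot(inherits(vol, "volume3d"))
  if (inherits(vois, "voi_box")) vois <- list(vois)
  if (length(vois) == 0L) stop_xlf("need at least one VOI")
  dims <- dim(vol$voxels)
  for (v in vois) if (!voi_inside(v, dims)) stop_xlf("VOI outside volume")
  if (length(vois) > 1L)
    for (i in seq_len(length(vois) - 1L))
      for (j in (i + 1L):length(vois))
        if (vois_overlap(vois[[i]], vois[[j]])) stop_xlf("overlapping VOIs")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vol$voxels)
         else check_scalar(threshold, "threshold", positive = FALSE)
  per <- do.call(rbind, lapply(seq_along(vois), function(i) {
    vals <- voi_values(vol, vois[[i]])
    tissue <- vals > thr
    data.frame(voi = i,
               vol_ratio = mean(tissue),
               mean_delta = if (any(tissue)) mean(vals[tissue]) else NA_real_,
               n_voxels = length(vals))
  }))
  structure(list(per_voi = per, threshold = thr,
                 mean_vol_ratio = mean(per$vol_ratio),
                 mean_delta = mean(per$mean_delta, na.rm = TRUE)),
            class = "voi_quant")
}

#' @export
print.voi_quant <- function(x, ...) {
  cat(sprintf("voi_quant: %d VOIs, threshold %.4g, mean vol.ratio %.3f, mean delta %.4g\n",
              nrow(x$per_voi), x$threshold, x$mean_vol_ratio, x$mean_delta))
  invisible(x)
}

# 6-neighbour erosion distance: number of erosions a voxel survives.
# Small and exact enough for shell classification; runs vectorized.
erosion_distance <- function(mask) {
  dist <- array(0L, dim(mask))
  cur <- mask
  d <- dim(mask)
  while (any(cur)) {
    dist <- dist + as.integer(cur)
    shifted <- function(arr, axis, by) {
      idx <- lapply(d, seq_len)
      src <- idx
      src[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
      out <- do.call(`[`, c(list(arr), src))
      pad <- idx[[axis]] + by < 1L | idx[[axis]] + by > d[axis]
      if (any(pad)) {
        sel <- idx; sel[[axis]] <- which(pad)
        out <- array(out, d)
        out <- do.call(`[<-`, c(list(out), sel, list(FALSE)))
      }
      array(out, d)
    }
    cur <- cur &
      shifted(cur, 1L, -1L) & shifted(cur, 1L, 1L) &
      shifted(cur, 2L, -1L) & shifted(cur, 2L, 1L) &
      shifted(cur, 3L, -1L) & shifted(cur, 3L, 1L)
  }
  dist
}

#' Place VOIs in the peripheral region of a lung mask
#'
#' Deterministic greedy placement: candidate cube centers lie on a regular
#' grid restricted to the peripheral shell of the mask (the outer 30% by
#' distance to the mask boundary), are ranked by the fraction of the cube
#' inside the mask (ties broken by grid order), and accepted greedily when
#' non-overlapping, until `n` cubes are placed. Manual VOI lists remain the
#' primary path; this placement is a convenience.
#'
#' @param vol a [volume3d()].
#' @param lung_mask logical 3-D array, same dimensions as the volume.
#' @param n number of VOIs to place (default 8).
#' @param edge_mm cube edge in mm (default 2.0); converted with the volume's
#'   voxel size.
#' @param peripheral_fraction shell depth as a fraction of the maximum
#'   distance-to-boundary (default 0.3).
#' @return List of [voi_box()]es; shorter than `n` with a warning when the
#'   mask cannot host enough disjoint cubes.
#' @export
place_vois <- function(vol, lung_mask, n = 8L, edge_mm = 2.0,
                       peripheral_fraction = 0.3) {
  stopifnot(inherits(vol, "volume3d"))
  dims <- dim(vol$voxels)
  if (!identical(dim(lung_mask), dims)) stop_xlf("mask dimensions must match the volume")
  if (!any(lung_mask)) stop_xlf("empty lung mask")
  edge <- max(1L, as.integer(round(edge_mm * 1000 / vol$voxel_size_um)))
  if (any(edge > dims)) {
    warning("mask too small for any VOI cube")
    return(list())
  }
  dist <- erosion_distance(lung_mask)
  maxd <- max(dist)
  shell <- lung_mask & dist <= peripheral_fraction * maxd
  stride <- max(1L, edge %/% 2L)
  gx <- seq(0L, dims[1L] - edge, by = stride)
  gy <- seq(0L, dims[2L] - edge, by = stride)
  gz <- seq(0L, dims[3L] - edge, by = stride)
  cand <- expand.grid(x = gx, y = gy, z = gz)
  ctr <- as.matrix(cand) + edge %/% 2L + 1L
  in_shell <- shell[ctr]
  cand <- cand[in_shell, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no candidate cube centers in the peripheral shell")
    return(list())
  }
  frac <- vapply(seq_len(nrow(cand)), function(i) {
    o <- as.integer(cand[i, ])
    mean(lung_mask[(o[1L] + 1L):(o[1L] + edge),
                   (o[2L] + 1L):(o[2L] + edge),
                   (o[3L] + 1L):(o[3L] + edge)])
  }, 0)
  ord <- order(-frac, seq_len(nrow(cand)))
  placed <- list()
  for (i in ord) {
    box <- voi_box(as.integer(cand[i, ]), edge)
    if (!any(vapply(placed, vois_overlap, TRUE, b = box))) {
      placed[[length(placed) + 1L]] <- box
      if (length(placed) == n) break
    }
  }
  if (length(placed) < n)
    warning(sprintf("placed only %d of %d requested VOIs", length(placed), n))
  placed
}
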