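#' Voxel mask on a reference grid
#'
#' @param mask logical 3D array with `dim(mask) == grid$dims`.
#' @param grid a [reference_grid()].
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(mask, grid) {
  mask <- as.array(mask)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(as.integer(dim(mask)), grid$dims))
    stop("mask shape does not match grid dims")
  structure(list(mask = mask, grid = grid), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("Voxel mask: %d of %d voxels set (%.3g mm^3)\n",
              sum(x$mask), length(x$mask), mask_volume(x)))
  invisible(x)
}

# Resample a polyline to (at most) step mm spacing by linear interpolation
# along arc length; original vertices are kept as interpolation nodes.
resample_polyline <- function(pts, step) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) return(pts)
  n <- max(2L, ceiling(total / step) + 1L)
  si <- seq(0, total, length.out = n)
  # drop duplicate arc-length nodes (repeated points) for approx()
  keep <- c(TRUE, d > 0)
  cbind(stats::approx(s[keep], pts[keep, 1], xout = si)$y,
        stats::approx(s[keep], pts[keep, 2], xout = si)$y,
        stats::approx(s[keep], pts[keep, 3], xout = si)$y)
}

#' Voxelize a bundle
#'
#' Marks every voxel that any resampled streamline point falls into, under
#' the shared voxel-center convention. Streamlines are resampled to a step of
#' `step_factor` times the smallest voxel size before marking, so no crossed
#' voxel is skipped at realistic curvature.
#'
#' @param bundle a [streamline_bundle()].
#' @param grid a [reference_grid()]; defaults to the bundle's own grid.
#' @param step_factor resampling step as a fraction of the smallest voxel
#'   size (default 0.2).
#' @return A [voxel_mask()].
#' @export
voxelize_bundle <- function(bundle, grid = bundle$grid, step_factor = 0.2) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  if (is.null(grid)) stop("voxelize_bundle needs a reference grid")
  step <- step_factor * min(grid$voxel_sizes)
  mask <- array(FALSE, dim = grid$dims)
  for (s in bundle$streamlines) {
    pts <- resample_polyline(s, step)
    idx <- nearest_voxel(grid, pts)
    if (!all(voxel_in_grid(grid, idx))) {
      out <- pts[!voxel_in_grid(grid, idx), , drop = FALSE][1L, ]
      stop(sprintf("streamline point (%.2f, %.2f, %.2f) falls outside the grid",
                   out[1], out[2], out[3]))
    }
    mask[idx + 1L] <- TRUE
  }
  voxel_mask(mask, grid)
}

#' Bundle length, span and curl
#'
#' Length is the mean streamline arc length (mm); span is the mean Euclidean
#' distance between each streamline's first and last point (mm); curl is
#' length divided by span, a curvature measure that is exactly 1 for a
#' straight bundle and grows with curvature. An alternative span definition
#' (distance between the head and tail end centroids) is available via
#' `span_mode = "centroid"`.
#'
#' @param bundle a [streamline_bundle()].
#' @param span_mode `"per_streamline"` (default: mean per-streamline
#'   endpoint distance) or `"centroid"` (distance between mean first-point
#'   and mean last-point, after consistent reorientation).
#' @return named list with `length_mm`, `span_mm`, `curl`.
#' @export
streamline_geometry <- function(bundle,
                                span_mode = c("per_streamline", "centroid")) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  span_mode <- match.arg(span_mode)
  lens <- vapply(bundle$streamlines, polyline_length, numeric(1))
  ends <- vapply(bundle$streamlines, function(s) {
    sqrt(sum((s[nrow(s), ] - s[1L, ])^2))
  }, numeric(1))
  if (any(ends <= 0))
    stop("streamline ", which(ends <= 0)[1L],
         " has zero span (closed loop); curl is undefined")
  if (span_mode == "per_streamline") {
    span <- mean(ends)
  } else {
    o <- orient_streamlines(bundle)
    firsts <- t(vapply(o, function(s) s[1L, ], numeric(3)))
    lasts <- t(vapply(o, function(s) s[nrow(s), ], numeric(3)))
    span <- sqrt(sum((colMeans(lasts) - colMeans(firsts))^2))
  }
  list(length_mm = mean(lens), span_mm = span, curl = mean(lens) / span)
}

# Flip streamlines to a consistent direction: each streamline is flipped if
# its last point is closer than its first point to the running centroid of
# first points, seeded by the first streamline.
orient_streamlines <- function(bundle) {
  sl <- bundle$streamlines
  out <- vector("list", length(sl))
  out[[1L]] <- sl[[1L]]
  head_sum <- sl[[1L]][1L, ]
  n_head <- 1L
  for (i in seq_along(sl)[-1L]) {
    s <- sl[[i]]
    centroid <- head_sum / n_head
    d_first <- sum((s[1L, ] - centroid)^2)
    d_last <- sum((s[nrow(s), ] - centroid)^2)
    if (d_last < d_first) s <- s[nrow(s):1L, , drop = FALSE]
    out[[i]] <- s
    head_sum <- head_sum + s[1L, ]
    n_head <- n_head + 1L
  }
  out
}

#' Head and tail endpoint masks
#'
#' Streamlines are first reoriented to a consistent direction (see Details),
#' then the two end-groups are labelled: the head is the end whose centroid
#' has the lower coordinate on the axis of largest head-tail centroid
#' separation — in RAS, lower means more left, posterior or inferior. The
#' returned masks mark the voxels containing first points (head) and last
#' points (tail).
#'
#' @details Reorientation flips each streamline so its first point is the
#' one closer to the running centroid of first points, seeded by the first
#' streamline; labelling is therefore invariant to the input order and the
#' stored orientation of individual streamlines. Ties in centroid separation
#' are broken with axis priority X, then Y, then Z.
#'
#' @param bundle a [streamline_bundle()].
#' @param grid a [reference_grid()]; defaults to the bundle's grid.
#' @return list with `head` and `tail` [voxel_mask()]s.
#' @export
endpoint_mask <- function(bundle, grid = bundle$grid) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  if (is.null(grid)) stop("endpoint_mask needs a reference grid")
  oriented <- orient_streamlines(bundle)
  firsts <- t(vapply(oriented, function(s) s[1L, ], numeric(3)))
  lasts <- t(vapply(oriented, function(s) s[nrow(s), ], numeric(3)))
  sep <- colMeans(firsts) - colMeans(lasts)
  axis <- which.max(abs(sep))  # ties: first max wins -> X, Y, Z priority
  if (sep[axis] > 0) {  # head must be the lower-coordinate end
    tmp <- firsts; firsts <- lasts; lasts <- tmp
  }
  mark <- function(pts) {
    idx <- nearest_voxel(grid, pts)
    if (!all(voxel_in_grid(grid, idx)))
      stop("endpoint falls outside the grid")
    m <- array(FALSE, dim = grid$dims)
    m[idx + 1L] <- TRUE
    voxel_mask(m, grid)
  }
  list(head = mark(firsts), tail = mark(lasts))
}

#' Volume of a voxel mask
#'
#' Number of set voxels times the voxel volume.
#'
#' @param mask a [voxel_mask()].
#' @return volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$mask) * prod(mask$grid$voxel_sizes)
}

#' Surface area of a voxel mask
#'
#' Exposed-face counting under 6-connectivity: a voxel face contributes when
#' the neighbouring voxel across it is unset or outside the grid. With
#' anisotropic voxels each face is weighted by the product of the two voxel
#' sizes spanning it.
#'
#' @param mask a [voxel_mask()].
#' @return surface area in mm^2.
#' @export
mask_surface_area <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  m <- mask$mask
  vs <- mask$grid$voxel_sizes
  d <- dim(m)
  exposed_along <- function(axis) {
    # pad with FALSE on both sides of `axis`, then count set->unset faces
    pd <- d
    pd[axis] <- d[axis] + 2L
    p <- array(FALSE, dim = pd)
    idx <- lapply(d, seq_len)
    idx[[axis]] <- idx[[axis]] + 1L
    p[idx[[1]], idx[[2]], idx[[3]]] <- m
    lo <- hi <- lapply(pd, seq_len)
    lo[[axis]] <- seq_len(pd[axis] - 1L)
    hi[[axis]] <- seq_len(pd[axis] - 1L) + 1L
    a <- p[lo[[1]], lo[[2]], lo[[3]]]
    b <- p[hi[[1]], hi[[2]], hi[[3]]]
    sum(xor(a, b))
  }
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  sum(vapply(1:3, exposed_along, numeric(1)) * face_area)
}

#' The ten macrostructural shape features of a bundle
#'
#' Computes, from streamline geometry and voxel occupancy on the bundle's
#' grid: total tract volume (mm^3), volume of the voxels containing bundle
#' endpoints (mm^3, union of head and tail masks), length (mean streamline
#' arc length, mm), span (mm), curl (length/span, unitless, >= 1), diameter
#' (of the equivalent cylinder, `2*sqrt(volume/(pi*length))`, mm), elongation
#' (length/diameter, unitless), total surface area (mm^2), and the surface
#' areas of the head and tail endpoint regions (mm^2).
#'
#' @param bundle a [streamline_bundle()] carrying a grid (or pass `grid`).
#' @param grid optional [reference_grid()] overriding the bundle's grid.
#' @param span_mode see [streamline_geometry()].
#' @return An object of class `shape_features`: a named list of the 10
#'   metrics, in the order `volume_mm3, endpoint_volume_mm3, length_mm,
#'   span_mm, curl, diameter_mm, elongation, surface_area_mm2,
#'   head_surface_area_mm2, tail_surface_area_mm2`.
#' @examples
#' g <- reference_grid(diag(4), c(30, 12, 12))
#' b <- make_bundle("straight", params = list(length = 25, jitter_sd = 0),
#'                  n_streamlines = 9, grid = g, seed = 1,
#'                  origin = c(2, 5, 5))
#' compute_shape_features(b)
#' @export
compute_shape_features <- function(bundle, grid = bundle$grid,
                                   span_mode = "per_streamline") {
  stopifnot(inherits(bundle, "streamline_bundle"))
  if (is.null(grid)) stop("compute_shape_features needs a reference grid")
  geo <- streamline_geometry(bundle, span_mode = span_mode)
  whole <- voxelize_bundle(bundle, grid)
  ends <- endpoint_mask(bundle, grid)
  endpoint_union <- voxel_mask(ends$head$mask | ends$tail$mask, grid)
  volume <- mask_volume(whole)
  diameter <- 2 * sqrt(volume / (pi * geo$length_mm))
  structure(list(
    volume_mm3 = volume,
    endpoint_volume_mm3 = mask_volume(endpoint_union),
    length_mm = geo$length_mm,
    span_mm = geo$span_mm,
    curl = geo$curl,
    diameter_mm = diameter,
    elongation = geo$length_mm / diameter,
    surface_area_mm2 = mask_surface_area(whole),
    head_surface_area_mm2 = mask_surface_area(ends$head),
    tail_surface_area_mm2 = mask_surface_area(ends$tail)
  ), class = "shape_features")
}

#' @export
print.shape_features <- function(x, ...) {
  cat("Bundle shape features:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.shape_features <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
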