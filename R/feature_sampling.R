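#' Tract-averaged scalar value
#'
#' Unweighted mean of a scalar map over the voxels of a mask (typically the
#' voxelized bundle), ignoring missing-coded (`NA`) voxels. No
#' streamline-density weighting is applied: every occupied voxel counts once.
#'
#' @param scalar a [scalar_volume()].
#' @param mask a [voxel_mask()] on the same grid.
#' @return the mean scalar value.
#' @export
tract_mean <- function(scalar, mask) {
  stopifnot(inherits(scalar, "scalar_volume"), inherits(mask, "voxel_mask"))
  if (!grids_compatible(scalar$grid, mask$grid))
    stop("scalar and mask are on different grids")
  vals <- scalar$values[mask$mask]
  if (length(vals) == 0L) stop("empty mask")
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("all voxels under the mask are missing")
  mean(vals)
}

#' Sample a scalar map at world points
#'
#' Nearest-voxel lookup under the shared voxel-center convention. When the
#' nearest voxel is missing-coded (`NA`), the nearest non-missing voxel
#' center within `fallback_radius_mm` of the point is used instead; if none
#' exists (or the radius is 0) the sample is missing. Points outside the
#' grid yield missing values (counted in the `n_outside` attribute), not
#' errors.
#'
#' @param scalar a [scalar_volume()].
#' @param points N x 3 matrix of world mm coordinates.
#' @param fallback_radius_mm search radius for the nearest valid voxel when
#'   the direct hit is missing (default 2 mm).
#' @return numeric vector of length N with attribute `n_outside`.
#' @export
sample_at_points <- function(scalar, points, fallback_radius_mm = 2) {
  stopifnot(inherits(scalar, "scalar_volume"))
  points <- as_points_matrix(points)
  grid <- scalar$grid
  idx <- nearest_voxel(grid, points)
  inside <- voxel_in_grid(grid, idx)
  out <- rep(NA_real_, nrow(points))
  out[inside] <- scalar$values[idx[inside, , drop = FALSE] + 1L]
  need_fallback <- which(inside & is.na(out))
  if (fallback_radius_mm > 0 && length(need_fallback) > 0L) {
    reach <- ceiling(fallback_radius_mm / grid$voxel_sizes)
    offs <- as.matrix(expand.grid(x = -reach[1]:reach[1],
                                  y = -reach[2]:reach[2],
                                  z = -reach[3]:reach[3]))
    for (i in need_fallback) {
      cand <- sweep(offs, 2L, idx[i, ], "+")
      cand <- cand[voxel_in_grid(grid, cand), , drop = FALSE]
      if (nrow(cand) == 0L) next
      vals <- scalar$values[cand + 1L]
      ok <- !is.na(vals)
      if (!any(ok)) next
      centers <- voxel_to_world(grid, cand[ok, , drop = FALSE])
      d <- sqrt(rowSums(sweep(centers, 2L, points[i, ], "-")^2))
      j <- which.min(d)
      if (d[j] <= fallback_radius_mm) out[i] <- vals[ok][j]
    }
  }
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Bundle-level cortical feature from streamline endpoints
#'
#' Probes a (voxelized) cortical feature map at both endpoints of every
#' streamline, averages the two ends of each streamline (a missing end is
#' dropped), and averages over all streamlines with at least one valid end.
#' Returns `NA` when no streamline has a valid endpoint — several mid-brain
#' pathways have no associated cortex, and missingness must propagate rather
#' than error.
#'
#' @param bundle a [streamline_bundle()].
#' @param scalar a [scalar_volume()] holding the voxelized cortical map.
#' @param fallback_radius_mm endpoint lookup fallback (see
#'   [sample_at_points()]); streamline termini often sit at the white/gray
#'   interface just off the ribbon, so a small nonzero radius is the default.
#' @return the bundle-level feature value, or `NA`.
#' @export
bundle_cortical_feature <- function(bundle, scalar, fallback_radius_mm = 2) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  firsts <- t(vapply(bundle$streamlines, function(s) s[1L, ], numeric(3)))
  lasts <- t(vapply(bundle$streamlines,
                    function(s) s[nrow(s), ], numeric(3)))
  v_first <- sample_at_points(scalar, firsts, fallback_radius_mm)
  v_last <- sample_at_points(scalar, lasts, fallback_radius_mm)
  per_streamline <- rowMeans(cbind(v_first, v_last), na.rm = TRUE)
  per_streamline[is.nan(per_streamline)] <- NA_real_
  if (all(is.na(per_streamline))) return(NA_real_)
  mean(per_streamline, na.rm = TRUE)
}
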