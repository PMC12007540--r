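#' Reference voxel grid
#'
#' A reference grid ties voxel indices to world coordinates. It stores the
#' 4x4 voxel-to-world affine (mm, RAS), the grid dimensions and the voxel
#' sizes (the column norms of the affine's 3x3 block). All modules share one
#' coordinate convention: world coordinates are RAS mm, voxel indices are
#' 0-based, and voxel centers sit at integer voxel coordinates, so a world
#' point belongs to voxel `v` iff its voxel-space coordinate satisfies
#' `floor(x + 0.5) == v`.
#'
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm
#'   (RAS). Must be invertible with last row `(0, 0, 0, 1)`.
#' @param dims integer vector of length 3, the grid extent in voxels.
#' @return An object of class `reference_grid` with elements `affine`, `dims`
#'   and `voxel_sizes`.
#' @examples
#' g <- reference_grid(diag(4), c(10, 10, 10))
#' g$voxel_sizes
#' @export
reference_grid <- function(affine, dims) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine is not invertible")
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be 3 positive integers")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(
    list(affine = affine, dims = dims, voxel_sizes = vs,
         inv_affine = solve(affine)),
    class = "reference_grid")
}

#' @export
print.reference_grid <- function(x, ...) {
  cat("Reference grid:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_sizes, 4), collapse = " x "), "mm\n")
  invisible(x)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix")
  storage.mode(points) <- "double"
  points
}

#' Map world coordinates to continuous voxel coordinates
#'
#' @param grid a [reference_grid()].
#' @param points N x 3 matrix of world mm coordinates.
#' @return N x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(grid, points) {
  points <- as_points_matrix(points)
  v <- grid$inv_affine %*% rbind(t(points), 1)
  t(v[1:3, , drop = FALSE])
}

#' Map 0-based voxel coordinates to world mm
#'
#' @inheritParams world_to_voxel
#' @param voxels N x 3 matrix of (possibly fractional) 0-based voxel coordinates.
#' @export
voxel_to_world <- function(grid, voxels) {
  voxels <- as_points_matrix(voxels)
  w <- grid$affine %*% rbind(t(voxels), 1)
  t(w[1:3, , drop = FALSE])
}

#' Nearest voxel index of world points
#'
#' Applies the shared rounding convention `floor(x + 0.5)` (voxel centers at
#' integer voxel coordinates) after the world-to-voxel transform.
#'
#' @inheritParams world_to_voxel
#' @return N x 3 integer matrix of 0-based voxel indices (possibly outside
#'   the grid; see [voxel_in_grid()]).
#' @export
nearest_voxel <- function(grid, points) {
  v <- world_to_voxel(grid, points)
  storage.mode(v) <- "double"
  matrix(as.integer(floor(v + 0.5)), ncol = 3)
}

#' Which 0-based voxel indices fall inside the grid
#'
#' @param grid a [reference_grid()].
#' @param idx N x 3 integer matrix of 0-based voxel indices.
#' @return logical vector of length N.
#' @export
voxel_in_grid <- function(grid, idx) {
  idx[, 1] >= 0L & idx[, 1] < grid$dims[1] &
    idx[, 2] >= 0L & idx[, 2] < grid$dims[2] &
    idx[, 3] >= 0L & idx[, 3] < grid$dims[3]
}

grids_compatible <- function(a, b, tol = 1e-4) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) < tol
}
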