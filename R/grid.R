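#' Regular 3D sampling grid in world coordinates
#'
#' A `grid3d` describes where a volume's voxels sit in the patient/world
#' coordinate system (millimetres): the world position of the first voxel
#' centre (`origin`), the per-axis voxel size (`spacing`), the voxel counts
#' (`dims`) and an orthonormal 3x3 `direction` matrix whose columns are the
#' world directions of the three voxel axes. Voxel indexing is 0-based and
#' voxel-centred: continuous voxel coordinate `i` along an axis corresponds
#' to the world position `origin + direction %*% (i * spacing)`, and voxel
#' `i` covers the half-open slab `[i - 0.5, i + 0.5)` in voxel units.
#'
#' Oblique (rotated) grids are supported; sheared grids (non-orthonormal
#' direction matrices) are rejected, matching the DICOM patient-orientation
#' model.
#'
#' @param origin numeric length-3, world position of voxel (0,0,0) centre, mm.
#' @param spacing numeric length-3, strictly positive voxel sizes, mm.
#' @param dims integer length-3, voxel counts per axis (>= 1).
#' @param direction 3x3 orthonormal matrix (columns = axis directions).
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 3), dims = c(64, 64, 32))
#' world_to_voxel(g, c(10, 0, 9))
#' @export
grid3d <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims,
                   direction = diag(3)) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(round(dims))
  direction <- as.matrix(direction)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dims) == 3,
            all(dim(direction) == c(3, 3)))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be strictly positive on all axes")
  if (any(dims < 1L))
    stop("grid dims must be >= 1 on all axes")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal (sheared grids are not supported)")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 direction = direction),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  if (max(abs(x$direction - diag(3))) > 1e-12)
    cat("  oblique direction matrix\n")
  invisible(x)
}

is_grid3d <- function(x) inherits(x, "grid3d")

#' Identical-geometry test for two grids
#' @param a,b `grid3d` objects.
#' @param tol numeric tolerance, mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3)
    matrix(as.numeric(p), ncol = 3)
  } else {
    stopifnot(ncol(p) == 3)
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
  }
}

#' Map world points to continuous 0-based voxel coordinates
#'
#' The inverse of [voxel_to_world()]. Points outside the grid simply map to
#' coordinates outside `[0, dims - 1]`; no error is raised.
#'
#' @param grid a [grid3d()].
#' @param p a world point (length-3) or an n x 3 matrix of points, mm.
#' @return Continuous voxel coordinates, same shape as `p` (n x 3 matrix for
#'   matrix input, length-3 vector otherwise).
#' @export
world_to_voxel <- function(grid, p) {
  pm <- as_point_matrix(p)
  local <- sweep(pm, 2, grid$origin) %*% grid$direction  # = t(D) applied rowwise
  v <- sweep(local, 2, grid$spacing, "/")
  if (is.null(dim(p))) drop(v) else v
}

#' Map continuous 0-based voxel coordinates to world points
#' @param grid a [grid3d()].
#' @param v voxel coordinate (length-3) or n x 3 matrix.
#' @return World coordinates in mm, same shape as `v`.
#' @export
voxel_to_world <- function(grid, v) {
  vm <- as_point_matrix(v)
  local <- sweep(vm, 2, grid$spacing, "*")
  p <- sweep(local %*% t(grid$direction), 2, grid$origin, "+")
  if (is.null(dim(v))) drop(p) else p
}

# Extent of the grid's voxel slabs along its own axes, in local mm:
# axis a covers [-spacing/2, (dims - 1 + 1/2) * spacing].
grid_local_extent <- function(grid) {
  rbind(low = -0.5 * grid$spacing,
        high = (grid$dims - 0.5) * grid$spacing)
}

# World coordinates of all voxel centres (n x 3), index order = array order.
grid_voxel_centers <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$dims[1]) - 1,
                               j = seq_len(grid$dims[2]) - 1,
                               k = seq_len(grid$dims[3]) - 1))
  voxel_to_world(grid, idx)
}

# Voxel volume in mm^3
grid_voxel_volume <- function(grid) prod(grid$spacing)
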