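#' Image, delineation and dose volumes on their own grids
#'
#' The three source types fused by the renderer, each kept on its own grid —
#' no volume is ever resampled onto another's grid:
#' * `scalar_volume()` — image data (CT in HU, PET activity, ...), optionally
#'   4D as an ordered list of per-time-bin frames;
#' * `binary_volume()` — a target or organ-at-risk delineation as a 0/1 mask,
#'   optionally per time bin, with a display name and colour;
#' * `dose_volume()` — a single-frame 3D dose distribution in Gy.
#'
#' @param grid a [grid3d()].
#' @param frames a 3D array, or a list of 3D arrays (one per time bin), each
#'   with dimensions `grid$dims`.
#' @param modality modality tag, e.g. `"CT"`, `"PET"`.
#' @param units value units, e.g. `"HU"`.
#' @param name structure name (binary volumes).
#' @param color length-4 RGBA display colour in \[0,1\] (binary volumes).
#' @param values 3D array of doses in Gy (dose volumes).
#' @return An object of class `scalar_volume`, `binary_volume` or
#'   `dose_volume` (all also class `vox_volume`).
#' @examples
#' g <- grid3d(dims = c(8, 8, 8))
#' v <- scalar_volume(g, array(0, dim = c(8, 8, 8)), modality = "CT")
#' n_frames(v)
#' @name volumes
NULL

check_frames <- function(frames, grid) {
  if (is.array(frames) && length(dim(frames)) == 3) frames <- list(frames)
  if (!is.list(frames) || length(frames) < 1)
    stop("frames must be a 3D array or a non-empty list of 3D arrays")
  for (f in frames) {
    if (!is.array(f) || length(dim(f)) != 3 || !all(dim(f) == grid$dims))
      stop("every frame must be a 3D array with dimensions matching grid$dims")
  }
  lapply(frames, function(f) { storage.mode(f) <- "double"; f })
}

#' @rdname volumes
#' @export
scalar_volume <- function(grid, frames, modality = "other", units = "arbitrary") {
  stopifnot(is_grid3d(grid))
  frames <- check_frames(frames, grid)
  structure(list(grid = grid, frames = frames, modality = modality,
                 units = units),
            class = c("scalar_volume", "vox_volume"))
}

#' @rdname volumes
#' @export
binary_volume <- function(grid, frames, name = "structure",
                          color = c(1, 0, 0, 1)) {
  stopifnot(is_grid3d(grid), length(color) == 4)
  frames <- check_frames(frames, grid)
  for (f in frames)
    if (!all(f %in% c(0, 1)))
      stop("binary volume values must be 0 or 1")
  structure(list(grid = grid, frames = frames, name = name,
                 color = as.numeric(color)),
            class = c("binary_volume", "vox_volume"))
}

#' @rdname volumes
#' @export
dose_volume <- function(grid, values) {
  stopifnot(is_grid3d(grid))
  values <- check_frames(values, grid)
  if (length(values) != 1)
    stop("dose volumes are single-frame 3D volumes")
  if (any(values[[1]] < 0))
    stop("dose values must be >= 0 Gy")
  structure(list(grid = grid, frames = values),
            class = c("dose_volume", "vox_volume"))
}

#' Number of time bins of a volume
#' @param vol a volume object.
#' @return integer.
#' @export
n_frames <- function(vol) length(vol$frames)

#' @export
print.vox_volume <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s> %d frame(s)%s\n", kind, n_frames(x),
              if (!is.null(x$name)) paste0(", '", x$name, "'") else ""))
  print(x$grid)
  invisible(x)
}

# Pick the frame for time bin t (1-based). Static volumes ignore t.
get_frame <- function(vol, t = 1L) {
  nf <- n_frames(vol)
  if (nf == 1L) return(vol$frames[[1L]])
  if (t < 1L || t > nf)
    stop(sprintf("time bin %d out of range: volume has bins 1..%d", t, nf))
  vol$frames[[t]]
}

#' Trilinear sampling of a volume at world points
#'
#' Samples frame `t` of `vol` by trilinear interpolation in the volume's own
#' grid (no resampling to any other grid). The interpolation support is the
#' hull of voxel centres; points outside it return the designated outside
#' value 0 together with an outside flag. Axes with a single voxel are treated
#' as constant across their slab thickness.
#'
#' @param vol a `scalar_volume`, `binary_volume` or `dose_volume`.
#' @param p world point (length-3) or n x 3 matrix, mm.
#' @param t time bin, 1-based; static volumes ignore it.
#' @return A list with `value` (numeric n) and `outside` (logical n).
#' @export
sample_trilinear <- function(vol, p, t = 1L) {
  fr <- get_frame(vol, t)
  grid <- vol$grid
  v <- world_to_voxel(grid, as_point_matrix(p))
  sample_trilinear_vox(fr, grid$dims, v)
}

# Core: sample a 3D array at continuous 0-based voxel coordinates (n x 3).
sample_trilinear_vox <- function(fr, dims, v) {
  n <- nrow(v)
  inside <- rep(TRUE, n)
  for (a in 1:3) {
    if (dims[a] == 1L) {
      inside <- inside & abs(v[, a]) <= 0.5 + 1e-12
    } else {
      inside <- inside & v[, a] >= -1e-12 & v[, a] <= dims[a] - 1 + 1e-12
    }
  }
  val <- numeric(n)
  if (any(inside)) {
    vi <- v[inside, , drop = FALSE]
    i0 <- matrix(0L, nrow(vi), 3)
    fx <- matrix(0, nrow(vi), 3)
    for (a in 1:3) {
      if (dims[a] == 1L) {
        i0[, a] <- 0L
        fx[, a] <- 0
      } else {
        ia <- pmin.int(pmax.int(floor(vi[, a]), 0), dims[a] - 2L)
        i0[, a] <- as.integer(ia)
        fx[, a] <- pmin(pmax(vi[, a] - ia, 0), 1)
      }
    }
    d1 <- dims[1]; d12 <- dims[1] * dims[2]
    base <- 1L + i0[, 1] + i0[, 2] * d1 + i0[, 3] * d12
    ox <- ifelse(dims[1] == 1L, 0L, 1L)
    oy <- ifelse(dims[2] == 1L, 0L, d1)
    oz <- ifelse(dims[3] == 1L, 0L, d12)
    wx <- fx[, 1]; wy <- fx[, 2]; wz <- fx[, 3]
    c000 <- fr[base];                 c100 <- fr[base + ox]
    c010 <- fr[base + oy];            c110 <- fr[base + ox + oy]
    c001 <- fr[base + oz];            c101 <- fr[base + ox + oz]
    c011 <- fr[base + oy + oz];       c111 <- fr[base + ox + oy + oz]
    c00 <- c000 * (1 - wx) + c100 * wx
    c10 <- c010 * (1 - wx) + c110 * wx
    c01 <- c001 * (1 - wx) + c101 * wx
    c11 <- c011 * (1 - wx) + c111 * wx
    c0 <- c00 * (1 - wy) + c10 * wy
    c1 <- c01 * (1 - wy) + c11 * wy
    val[inside] <- c0 * (1 - wz) + c1 * wz
  }
  list(value = val, outside = !inside)
}

#' Nearest-neighbour mask membership at world points
#'
#' Categorical (0/1) masks are looked up by rounding to the nearest voxel,
#' never interpolated — interpolation would invent geometry between voxels.
#'
#' @param mask a `binary_volume`.
#' @param p world point or n x 3 matrix, mm.
#' @param t time bin, 1-based.
#' @return logical vector: `TRUE` where the nearest voxel is foreground
#'   (points outside the mask grid are `FALSE`).
#' @export
mask_contains <- function(mask, p, t = 1L) {
  fr <- get_frame(mask, t)
  grid <- mask$grid
  v <- round(world_to_voxel(grid, as_point_matrix(p)))
  inside <- v[, 1] >= 0 & v[, 1] <= grid$dims[1] - 1 &
    v[, 2] >= 0 & v[, 2] <= grid$dims[2] - 1 &
    v[, 3] >= 0 & v[, 3] <= grid$dims[3] - 1
  out <- rep(FALSE, nrow(v))
  if (any(inside)) {
    vi <- v[inside, , drop = FALSE]
    idx <- 1L + vi[, 1] + vi[, 2] * grid$dims[1] +
      vi[, 3] * grid$dims[1] * grid$dims[2]
    out[inside] <- fr[idx] > 0.5
  }
  out
}

#' Crop a delineation to the tight bounding box of its content
#'
#' Keeps the minimal sub-grid containing every foreground voxel (union over
#' all time bins), shifting the origin so that retained voxels keep their
#' world positions — world-space membership is unchanged.
#'
#' @param b a `binary_volume`.
#' @return A `binary_volume` on the cropped grid.
#' @export
crop_to_content <- function(b) {
  stopifnot(inherits(b, "binary_volume"))
  any_fg <- Reduce(`+`, b$frames) > 0
  if (!any(any_fg)) stop("empty structure: cannot crop an all-zero volume")
  idx <- which(any_fg, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  new_dims <- hi - lo + 1L
  # new origin: world position of old voxel (lo - 1) [0-based]
  new_origin <- voxel_to_world(b$grid, lo - 1)
  new_grid <- grid3d(origin = new_origin, spacing = b$grid$spacing,
                     dims = new_dims, direction = b$grid$direction)
  frames <- lapply(b$frames, function(f)
    f[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
  binary_volume(new_grid, frames, name = b$name, color = b$color)
}
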