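#' Specification of the synthetic 4D breathing phantom
#'
#' Defines a desk-scale multi-source acquisition layout for one virtual
#' patient: a full-body CT, a 4D-CT and 4D-PET (shared breathing cycle, the
#' PET on a much coarser grid), a planning CT, delineations and a dose
#' volume — each source on its own grid with its own spacing, mirroring the
#' mixed-resolution layout of clinical 4D-PET/CT planning data (CT-class
#' ~1 mm in-plane grids vs a 4-mm PET grid, 10 respiratory bins). A single
#' spherical lesion moves cranio-caudally with a sinusoidal breathing
#' trajectory; an airway tube and a mediastinum slab serve as organs at
#' risk for location classification.
#'
#' All randomness (CT/PET noise) is driven by `seed`; geometry is
#' noise-free and identical across seeds.
#'
#' @param seed integer RNG seed.
#' @param amplitude breathing amplitude, mm (peak cranio-caudal shift).
#' @param bins number of respiratory time bins.
#' @param radius lesion radius, mm.
#' @param lesion_center lesion centre at mid-breathing, world mm.
#' @param contrast PET lesion-to-background uptake ratio.
#' @param noise_ct additive Gaussian CT noise SD, HU.
#' @param noise_pet PET noise scale (Gaussian approximation to Poisson:
#'   SD = `noise_pet * sqrt(activity)`).
#' @param prescription dose prescription, Gy.
#' @param falloff dose falloff length, mm (logistic edge scale).
#' @param dose_iso iso-dose level(s) of interest, Gy (also the default
#'   rendering iso value and DVH `V_x` level).
#' @param airway_center_xy,airway_radius airway tube axis (x, y) and
#'   radius, mm.
#' @param mediastinum_x,mediastinum_y mediastinum slab extents, mm.
#' @param grids per-source grid layout; override single entries if needed.
#' @return A `phantom_spec` (validated list).
#' @export
phantom_spec <- function(seed = 1L, amplitude = 10, bins = 10L, radius = 10,
                         lesion_center = c(8, 4, 0), contrast = 5,
                         noise_ct = 15, noise_pet = 0.05,
                         prescription = 50, falloff = 3, dose_iso = 37.5,
                         airway_center_xy = c(-15, 0), airway_radius = 5,
                         mediastinum_x = c(-32, -20), mediastinum_y = c(-25, 25),
                         grids = phantom_default_grids()) {
  if (radius <= 0) stop("lesion radius must be > 0")
  if (bins < 1) stop("need >= 1 time bin")
  if (amplitude < 0) stop("breathing amplitude must be >= 0")
  if (prescription <= 0 || falloff <= 0)
    stop("prescription and falloff must be > 0")
  structure(list(seed = as.integer(seed), amplitude = amplitude,
                 bins = as.integer(bins), radius = radius,
                 lesion_center = as.numeric(lesion_center),
                 contrast = contrast, noise_ct = noise_ct,
                 noise_pet = noise_pet, prescription = prescription,
                 falloff = falloff, dose_iso = dose_iso,
                 airway_center_xy = as.numeric(airway_center_xy),
                 airway_radius = airway_radius,
                 mediastinum_x = as.numeric(mediastinum_x),
                 mediastinum_y = as.numeric(mediastinum_y),
                 grids = grids),
            class = "phantom_spec")
}

# Centred grids preserving the resolution ratios of a clinical layout:
# CT-class ~1 mm in-plane grids, a 4 mm PET grid with 10 bins, a coarse
# dose grid — all scaled down to keep full-pipeline runs fast.
phantom_default_grids <- function() {
  centred <- function(spacing, dims) {
    grid3d(origin = -(dims - 1) * spacing / 2, spacing = spacing, dims = dims)
  }
  list(body_ct = centred(c(1.4, 1.4, 4), c(64, 64, 40)),
       ct_4d = centred(c(1.2, 1.2, 2), c(56, 56, 48)),
       pet_4d = centred(c(4, 4, 4), c(20, 20, 24)),
       planning_ct = centred(c(1, 1, 3), c(64, 64, 32)),
       dose = centred(c(5, 5, 3), c(16, 12, 32)))
}

#' Sinusoidal cranio-caudal breathing trajectory
#'
#' Per-bin lesion displacement vectors `(0, 0, A * sin(2 * pi * t / B))`
#' for `t = 0 .. B - 1`. Bin 1 has zero displacement; the peak |shift|
#' equals the amplitude whenever `B` is divisible by 4.
#'
#' @param amplitude amplitude, mm.
#' @param bins number of bins B >= 1.
#' @return B x 3 matrix of displacements, mm.
#' @export
make_breathing_trajectory <- function(amplitude, bins) {
  if (bins < 1) stop("need >= 1 time bin")
  t <- seq_len(bins) - 1
  cbind(0, 0, amplitude * sin(2 * pi * t / bins))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Voxel-centre coordinate arrays for a grid (identity-direction fast path).
grid_axes_world <- function(g) {
  list(x = g$origin[1] + (seq_len(g$dims[1]) - 1) * g$spacing[1],
       y = g$origin[2] + (seq_len(g$dims[2]) - 1) * g$spacing[2],
       z = g$origin[3] + (seq_len(g$dims[3]) - 1) * g$spacing[3])
}

# 3D array of squared distances from voxel centres to a point (separable).
dist2_to_point <- function(g, p) {
  ax <- grid_axes_world(g)
  dx2 <- (ax$x - p[1])^2; dy2 <- (ax$y - p[2])^2; dz2 <- (ax$z - p[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

sphere_mask <- function(g, center, radius) {
  dist2_to_point(g, center) <= radius^2
}

tube_mask <- function(g, center_xy, radius) {
  ax <- grid_axes_world(g)
  dx2 <- (ax$x - center_xy[1])^2; dy2 <- (ax$y - center_xy[2])^2
  in2d <- outer(dx2, dy2, `+`) <= radius^2
  array(in2d, dim = g$dims)
}

slab_mask <- function(g, xr, yr) {
  ax <- grid_axes_world(g)
  inx <- ax$x >= xr[1] & ax$x <= xr[2]
  iny <- ax$y >= yr[1] & ax$y <= yr[2]
  array(outer(inx, iny, `&`), dim = g$dims)
}

# CT frame: lung background with mediastinum, airway and (optionally) the
# lesion painted in, plus seeded Gaussian noise.
phantom_ct_frame <- function(g, spec, lesion_center) {
  hu <- array(-750, dim = g$dims)                     # lung parenchyma
  hu[slab_mask(g, spec$mediastinum_x, spec$mediastinum_y)] <- 30
  hu[tube_mask(g, spec$airway_center_xy, spec$airway_radius)] <- -950
  if (!is.null(lesion_center))
    hu[sphere_mask(g, lesion_center, spec$radius)] <- 40
  if (spec$noise_ct > 0)
    hu <- hu + array(rnorm(prod(g$dims), 0, spec$noise_ct), dim = g$dims)
  hu
}

# PET frame: smooth uptake blob (logistic edge profile, ~2 mm edge width)
# at the lesion position over a uniform background, with Gaussian-
# approximated Poisson noise.
phantom_pet_frame <- function(g, spec, lesion_center, edge_mm = 2) {
  d <- sqrt(dist2_to_point(g, lesion_center))
  act <- 1 + (spec$contrast - 1) * stats::plogis((spec$radius - d) / edge_mm)
  if (spec$noise_pet > 0)
    act <- pmax(act + array(rnorm(prod(g$dims), 0, spec$noise_pet) * sqrt(act),
                            dim = g$dims), 0)
  array(act, dim = g$dims)
}

# Circle contours of a sphere on the slice centres of a grid.
sphere_contours <- function(g, center, radius, n_vertices = 48) {
  zs <- grid_axes_world(g)$z
  out <- list()
  for (z in zs) {
    dz <- z - center[3]
    if (abs(dz) >= radius) next
    r2 <- sqrt(radius^2 - dz^2)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    out[[length(out) + 1]] <- planar_contour(
      z = z, vertices = cbind(center[1] + r2 * cos(th),
                              center[2] + r2 * sin(th)))
  }
  out
}

# Union-of-spheres ("cranio-caudal pencil") contours: per slice the circle
# radius is the maximum over bins (motion is along z only).
itv_contours <- function(g, centers, radius, n_vertices = 48) {
  zs <- grid_axes_world(g)$z
  out <- list()
  for (z in zs) {
    r2s <- radius^2 - (z - centers[, 3])^2
    r2 <- suppressWarnings(sqrt(max(r2s)))
    if (!is.finite(r2) || max(r2s) <= 0) next
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    out[[length(out) + 1]] <- planar_contour(
      z = z, vertices = cbind(centers[1, 1] + r2 * cos(th),
                              centers[1, 2] + r2 * sin(th)))
  }
  out
}

#' Generate the synthetic 4D phantom bundle
#'
#' Builds every source of the multi-source layout from a [phantom_spec()]:
#' body CT, 4D-CT and 4D-PET (lesion moving along the breathing
#' trajectory, PET on its own coarse grid), planning CT (bin-1 anatomy),
#' per-bin lesion masks and their union ITV on the planning grid, airway
#' and mediastinum masks, a planar-contour structure set, a dose volume
#' (logistic falloff around the ITV) and a ground-truth manifest.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_bundle`: list with `body_ct`, `ct_4d`, `pet_4d`,
#'   `planning_ct` (scalar volumes), `lesion_bins`, `itv`, `airway`,
#'   `mediastinum` (binary volumes on the planning grid), `contours`
#'   (a [structure_set()]), `dose` (a `dose_volume`) and `manifest`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grids
  traj <- make_breathing_trajectory(spec$amplitude, spec$bins)
  centers <- sweep(traj, 2, spec$lesion_center, `+`)

  # lesion must stay inside the 4D grids at every bin
  for (gr in list(g$ct_4d, g$planning_ct)) {
    ext <- grid_local_extent(gr)
    lo <- gr$origin + ext[1, ]; hi <- gr$origin + ext[2, ]
    if (any(t(centers) - spec$radius < lo) || any(t(centers) + spec$radius > hi))
      stop("lesion leaves the 4D grid extent at some time bin; shrink amplitude/radius")
  }

  with_seed(spec$seed, {
    ct4d <- lapply(seq_len(spec$bins), function(b)
      phantom_ct_frame(g$ct_4d, spec, centers[b, ]))
    pet4d <- lapply(seq_len(spec$bins), function(b)
      phantom_pet_frame(g$pet_4d, spec, centers[b, ]))
    body <- phantom_ct_frame(g$body_ct, spec, centers[1, ])
    plan <- phantom_ct_frame(g$planning_ct, spec, centers[1, ])
  })

  lesion_bins <- lapply(seq_len(spec$bins), function(b)
    array(as.numeric(sphere_mask(g$planning_ct, centers[b, ], spec$radius)),
          dim = g$planning_ct$dims))
  itv_arr <- array(as.numeric(Reduce(`+`, lesion_bins) > 0),
                   dim = g$planning_ct$dims)
  itv <- binary_volume(g$planning_ct, itv_arr, name = "ITV",
                       color = c(1, 1, 0, 0.7))
  lesion <- binary_volume(g$planning_ct, lesion_bins, name = "lesion",
                          color = c(1, 0, 0, 0.8))
  airway <- binary_volume(
    g$planning_ct,
    array(as.numeric(tube_mask(g$planning_ct, spec$airway_center_xy,
                               spec$airway_radius)), dim = g$planning_ct$dims),
    name = "airway", color = c(0.3, 0.8, 1, 0.5))
  medi <- binary_volume(
    g$planning_ct,
    array(as.numeric(slab_mask(g$planning_ct, spec$mediastinum_x,
                               spec$mediastinum_y)), dim = g$planning_ct$dims),
    name = "mediastinum", color = c(0.8, 0.5, 1, 0.5))

  contours <- structure_set(list(
    lesion = list(contours = lapply(seq_len(spec$bins), function(b)
      sphere_contours(g$planning_ct, centers[b, ], spec$radius)),
      color = c(1, 0, 0, 0.8), role = "target"),
    ITV = list(contours = list(itv_contours(g$planning_ct, centers, spec$radius)),
               color = c(1, 1, 0, 0.7), role = "target")))

  dose <- make_dose(itv, prescription = spec$prescription,
                    falloff = spec$falloff, grid = g$dose)

  # ground truth, recorded independently of the analysis modules
  dose_vox_in_itv <- mask_contains(itv, grid_voxel_centers(g$dose))
  dvals <- get_frame(dose, 1L)[array(dose_vox_in_itv, dim = g$dose$dims)]
  manifest <- list(
    seed = spec$seed, amplitude = spec$amplitude, bins = spec$bins,
    radius = spec$radius, centers = centers,
    lesion_volume_mm3 = 4 / 3 * pi * spec$radius^3,
    lesion_bin_voxels = vapply(lesion_bins, sum, 0),
    itv_voxels = sum(itv_arr),
    itv_volume_mm3 = sum(itv_arr) * grid_voxel_volume(g$planning_ct),
    dose_iso = spec$dose_iso,
    dose_coverage = vapply(spec$dose_iso, function(lv) mean(dvals >= lv), 0))

  structure(list(
    spec = spec,
    body_ct = scalar_volume(g$body_ct, body, modality = "CT", units = "HU"),
    ct_4d = scalar_volume(g$ct_4d, ct4d, modality = "CT", units = "HU"),
    pet_4d = scalar_volume(g$pet_4d, pet4d, modality = "PET",
                           units = "activity"),
    planning_ct = scalar_volume(g$planning_ct, plan, modality = "CT",
                                units = "HU"),
    lesion_bins = lesion, itv = itv, airway = airway, mediastinum = medi,
    contours = contours, dose = dose, manifest = manifest),
    class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %d bins, lesion r = %g mm, amplitude %g mm, ITV %d voxels (%.0f mm^3)\n",
              x$spec$bins, x$spec$radius, x$spec$amplitude,
              x$manifest$itv_voxels, x$manifest$itv_volume_mm3))
  invisible(x)
}

#' Synthetic dose distribution around a target
#'
#' Dose falls off with a logistic profile of the signed Euclidean distance
#' to the target surface: `dose(p) = prescription * plogis(-s(p)/falloff)`
#' with `s` negative inside the target, so deep inside the target the dose
#' saturates at the prescription and it decays symmetrically outside over
#' a few falloff lengths. The target is membership-mapped onto the dose
#' grid; signed distances are computed with the exact distance transform.
#'
#' @param target non-empty `binary_volume`.
#' @param prescription prescription dose, Gy.
#' @param falloff falloff length, mm.
#' @param grid dose [grid3d()] (defaults to the target's grid).
#' @return A `dose_volume` on `grid`.
#' @export
make_dose <- function(target, prescription, falloff, grid = NULL) {
  stopifnot(inherits(target, "binary_volume"))
  if (prescription <= 0 || falloff <= 0)
    stop("prescription and falloff must be > 0")
  if (is.null(grid)) grid <- target$grid
  if (same_grid(grid, target$grid)) {
    fg <- get_frame(target, 1L) > 0.5
  } else {
    fg <- array(mask_contains(target, grid_voxel_centers(grid)),
                dim = grid$dims)
  }
  if (!any(fg)) stop("empty target on the dose grid")
  d_out <- distance_transform(fg, grid$spacing)    # 0 inside
  d_in <- distance_transform(!fg, grid$spacing)    # 0 outside
  s <- d_out - d_in                                # signed distance, <0 inside
  dose_volume(grid, array(prescription * stats::plogis(-s / falloff),
                          dim = grid$dims))
}
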