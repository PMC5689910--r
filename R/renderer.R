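#' Pinhole camera
#'
#' @param eye eye position, mm.
#' @param look_at look-at point, mm (must differ from `eye`).
#' @param up up vector (not parallel to the view direction).
#' @param fov vertical field of view, degrees, in (0, 180).
#' @param width,height image size in pixels.
#' @param ortho if `TRUE`, orthographic projection; ray origins are spread
#'   over an image plane of height `ortho_height` mm.
#' @param ortho_height image-plane height for orthographic projection, mm.
#' @return A `camera` object.
#' @export
camera <- function(eye, look_at, up = c(0, 0, 1), fov = 40,
                   width = 128, height = 128,
                   ortho = FALSE, ortho_height = 100) {
  eye <- as.numeric(eye); look_at <- as.numeric(look_at); up <- as.numeric(up)
  stopifnot(length(eye) == 3, length(look_at) == 3, length(up) == 3)
  fwd <- look_at - eye
  if (sqrt(sum(fwd^2)) < 1e-12) stop("camera eye and look-at must differ")
  if (fov <= 0 || fov >= 180) stop("field of view must be in (0, 180) degrees")
  fwd <- fwd / sqrt(sum(fwd^2))
  upn <- up / sqrt(sum(up^2))
  if (abs(sum(fwd * upn)) > 1 - 1e-9)
    stop("up vector must not be parallel to the view direction")
  structure(list(eye = eye, look_at = look_at, up = upn, fov = fov,
                 width = as.integer(width), height = as.integer(height),
                 ortho = isTRUE(ortho), ortho_height = ortho_height),
            class = "camera")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Ray origins and unit directions for pixel centres (row-major over the
# image: x fastest, y top-to-bottom). pixels: optional n x 2 (px, py),
# 1-based pixel indices.
camera_rays <- function(cam, pixels = NULL) {
  fwd <- cam$look_at - cam$eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- cross3(fwd, cam$up)
  right <- right / sqrt(sum(right^2))
  upv <- cross3(right, fwd)
  if (is.null(pixels)) {
    px <- rep(seq_len(cam$width), times = cam$height)
    py <- rep(seq_len(cam$height), each = cam$width)
  } else {
    pixels <- as_matrix2(pixels)
    px <- pixels[, 1]; py <- pixels[, 2]
  }
  xn <- (px - 0.5) / cam$width * 2 - 1
  yn <- 1 - (py - 0.5) / cam$height * 2
  aspect <- cam$width / cam$height
  if (cam$ortho) {
    hh <- cam$ortho_height / 2
    org <- cbind(cam$eye[1] + xn * hh * aspect * right[1] + yn * hh * upv[1],
                 cam$eye[2] + xn * hh * aspect * right[2] + yn * hh * upv[2],
                 cam$eye[3] + xn * hh * aspect * right[3] + yn * hh * upv[3])
    dir <- matrix(fwd, nrow = length(px), ncol = 3, byrow = TRUE)
  } else {
    tf <- tan(cam$fov / 2 * pi / 180)
    dx <- xn * tf * aspect; dy <- yn * tf
    dir <- cbind(dx * right[1] + dy * upv[1] + fwd[1],
                 dx * right[2] + dy * upv[2] + fwd[2],
                 dx * right[3] + dy * upv[3] + fwd[3])
    dir <- dir / sqrt(rowSums(dir^2))
    org <- matrix(cam$eye, nrow = length(px), ncol = 3, byrow = TRUE)
  }
  list(origin = org, dir = dir, px = px, py = py)
}

as_matrix2 <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2) else as.matrix(p)
}

#' Image layer of a scene
#'
#' One image source with its transfer function, fusion weight and optional
#' per-layer masks (names of delineations registered in the scene): where a
#' layer is masked, it only shows inside at least one of its masks.
#'
#' @param volume a `scalar_volume`.
#' @param tf a [transfer_function()].
#' @param weight fusion weight, >= 0 and finite.
#' @param enabled logical.
#' @param masks character vector of scene mask names (empty = unmasked).
#' @param name layer name.
#' @return An `image_layer`.
#' @export
image_layer <- function(volume, tf, weight = 1, enabled = TRUE,
                        masks = character(0), name = volume$modality) {
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(tf, "transfer_function"))
  if (!is.finite(weight) || weight < 0)
    stop("fusion weight must be finite and >= 0")
  structure(list(volume = volume, tf = tf, weight = weight,
                 enabled = isTRUE(enabled), masks = as.character(masks),
                 name = name),
            class = "image_layer")
}

#' Surface layer of a scene
#'
#' An iso-surface rendered directly in the ray-caster: either a delineation
#' (binary volume, iso level 0.5 of the trilinearly interpolated indicator)
#' or an iso-dose surface (dose volume, iso value in Gy).
#'
#' @param source a `binary_volume` or `dose_volume`.
#' @param iso iso value (default 0.5 for binary sources; Gy for dose).
#' @param color RGBA in \[0,1\] (defaults to a binary source's own colour).
#' @param shading Blinn-Phong shading on/off.
#' @param enabled logical.
#' @param name surface name (defaults to a binary source's structure name).
#' @return A `surface_layer`.
#' @export
surface_layer <- function(source, iso = NULL, color = NULL, shading = TRUE,
                          enabled = TRUE, name = NULL) {
  is_bin <- inherits(source, "binary_volume")
  if (!is_bin && !inherits(source, "dose_volume"))
    stop("surface source must be a binary_volume or dose_volume")
  if (is.null(iso)) {
    if (!is_bin) stop("iso-dose surfaces need an explicit iso value in Gy")
    iso <- 0.5
  }
  if (!is_bin && iso < 0) stop("dose iso value must be >= 0 Gy")
  if (is.null(color)) color <- if (is_bin) source$color else c(0, 1, 0, 0.6)
  stopifnot(length(color) == 4, all(color >= 0), all(color <= 1))
  if (is.null(name))
    name <- if (is_bin) source$name else sprintf("isodose_%g_Gy", iso)
  structure(list(source = source, iso = iso, color = as.numeric(color),
                 shading = isTRUE(shading), enabled = isTRUE(enabled),
                 name = name),
            class = "surface_layer")
}

#' Renderable scene
#'
#' Layered sources clipped to a region of interest (ROI) of the reference
#' volume. The ROI is given as per-axis low/high fractions of the reference
#' volume's bounding box (in the reference grid's own axes); all content —
#' image volumes, delineation surfaces and iso-dose surfaces — is clipped
#' to it.
#'
#' @param reference the reference volume (usually the planning CT), a
#'   volume object or a [grid3d()]; defines the clipping bounding box.
#' @param image_layers list of [image_layer()]s.
#' @param surface_layers list of [surface_layer()]s.
#' @param masks named list of `binary_volume`s referenced by layer masks.
#' @param roi 2 x 3 matrix `rbind(low, high)` of fractions in \[0,1\],
#'   `low < high` per axis.
#' @param time_bin time bin (1-based) applied to every 4D source.
#' @param background background RGB.
#' @param light_dir world-space unit vector pointing towards the light, or
#'   `NULL` for a headlight (light at the eye).
#' @param shading list with `ambient`, `diffuse`, `specular`, `shininess`.
#' @param step_mm ray-march step in mm, or `NULL` to use half the smallest
#'   voxel spacing among enabled sources.
#' @param early_termination stop compositing once the remaining
#'   transmittance drops below 1e-6 (accumulated opacity above 1 - 1e-6,
#'   well past the conventional 0.99 saturation point); the result is then
#'   independent of termination to 1e-6 per channel.
#' @return A `scene` object.
#' @export
scene <- function(reference, image_layers = list(), surface_layers = list(),
                  masks = list(), roi = rbind(low = c(0, 0, 0), high = c(1, 1, 1)),
                  time_bin = 1L, background = c(0, 0, 0),
                  light_dir = NULL,
                  shading = list(ambient = 0.25, diffuse = 0.65,
                                 specular = 0.2, shininess = 32),
                  step_mm = NULL, early_termination = TRUE) {
  ref_grid <- if (is_grid3d(reference)) reference else reference$grid
  stopifnot(is_grid3d(ref_grid))
  roi <- as.matrix(roi)
  stopifnot(all(dim(roi) == c(2, 3)))
  if (any(roi[1, ] < 0) || any(roi[2, ] > 1) || any(roi[1, ] >= roi[2, ]))
    stop("ROI fractions must satisfy 0 <= low < high <= 1 per axis")
  for (il in image_layers) stopifnot(inherits(il, "image_layer"))
  for (sl in surface_layers) stopifnot(inherits(sl, "surface_layer"))
  if (!is.null(light_dir)) {
    light_dir <- as.numeric(light_dir)
    light_dir <- light_dir / sqrt(sum(light_dir^2))
  }
  sc <- structure(list(reference = reference, ref_grid = ref_grid,
                       image_layers = image_layers,
                       surface_layers = surface_layers,
                       masks = masks, roi = roi, time_bin = as.integer(time_bin),
                       background = as.numeric(background),
                       light_dir = light_dir, shading = shading,
                       step_mm = step_mm,
                       early_termination = isTRUE(early_termination)),
                  class = "scene")
  validate_scene(sc)
  sc
}

validate_scene <- function(sc) {
  t <- sc$time_bin
  vols <- c(lapply(sc$image_layers, `[[`, "volume"),
            lapply(sc$surface_layers, `[[`, "source"))
  for (v in vols) {
    nf <- n_frames(v)
    if (nf > 1L && (t < 1L || t > nf))
      stop(sprintf("time bin %d invalid: a 4D source has bins 1..%d", t, nf))
  }
  for (il in sc$image_layers)
    for (mn in il$masks)
      if (is.null(sc$masks[[mn]]))
        stop("unknown mask name in image layer: ", mn)
  invisible(sc)
}

#' Point-in-ROI test
#'
#' `TRUE` iff the world point lies inside the closed sub-box of the
#' reference volume's bounding box selected by the scene's per-axis ROI
#' fractions.
#'
#' @param sc a [scene()].
#' @param p world point or n x 3 matrix, mm.
#' @return Logical vector.
#' @export
in_roi <- function(sc, p) {
  ext <- grid_local_extent(sc$ref_grid)
  lo <- ext[1, ] + sc$roi[1, ] * (ext[2, ] - ext[1, ])
  hi <- ext[1, ] + sc$roi[2, ] * (ext[2, ] - ext[1, ])
  pm <- as_point_matrix(p)
  local <- sweep(pm, 2, sc$ref_grid$origin) %*% sc$ref_grid$direction
  ok <- rep(TRUE, nrow(local))
  for (a in 1:3)
    ok <- ok & local[, a] >= lo[a] - 1e-9 & local[, a] <= hi[a] + 1e-9
  ok
}

#' Per-layer mask visibility
#'
#' A layer with no masks is visible everywhere; otherwise a point is
#' visible iff it lies inside at least one of the layer's masks
#' (nearest-neighbour membership, union semantics).
#'
#' @param layer an [image_layer()].
#' @param p world point or n x 3 matrix, mm.
#' @param masks named list of `binary_volume`s (the scene's mask registry).
#' @param t time bin (1-based).
#' @return Logical vector.
#' @export
mask_visibility <- function(layer, p, masks, t = 1L) {
  pm <- as_point_matrix(p)
  if (length(layer$masks) == 0) return(rep(TRUE, nrow(pm)))
  vis <- rep(FALSE, nrow(pm))
  for (mn in layer$masks) {
    m <- masks[[mn]]
    if (is.null(m)) stop("unknown mask name: ", mn)
    vis <- vis | mask_contains(m, pm, t = t)
  }
  vis
}

#' Weighted accumulation-level fusion of one sample
#'
#' Fuses the per-source colours and opacities of the selected images at one
#' ray sample by a weighted linear combination; weights are normalized to
#' sum to one, so only relative weights matter.
#'
#' @param colors k x 3 matrix of per-source RGB.
#' @param opacities length-k opacities in \[0,1\].
#' @param weights length-k non-negative weights, not all zero.
#' @return Length-4 RGBA.
#' @export
fuse_sample <- function(colors, opacities, weights) {
  colors <- if (is.null(dim(colors))) matrix(colors, ncol = 3) else as.matrix(colors)
  k <- nrow(colors)
  stopifnot(length(opacities) == k, length(weights) == k, k >= 1)
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("weights must be finite and >= 0")
  ws <- sum(weights)
  if (ws == 0) stop("fusion weights must not all be zero")
  w <- weights / ws
  c(colSums(colors * w), sum(opacities * w))
}

#' Front-to-back alpha compositing
#'
#' Standard emission-absorption compositing of ordered ray samples:
#' `C += (1 - A) * alpha * color; A += (1 - A) * alpha`. With
#' `early_termination`, accumulation stops once the remaining
#' transmittance `1 - A` drops below 1e-6; every sample skipped afterwards
#' could have contributed at most that transmittance, so the result is
#' independent of termination to 1e-6 per channel.
#'
#' @param samples n x 4 matrix of (R, G, B, alpha) ordered front to back.
#' @param early_termination logical.
#' @return Length-4 accumulated RGBA.
#' @export
composite_front_to_back <- function(samples, early_termination = FALSE) {
  samples <- if (is.null(dim(samples))) matrix(samples, ncol = 4) else as.matrix(samples)
  C <- c(0, 0, 0); A <- 0
  for (i in seq_len(nrow(samples))) {
    a <- samples[i, 4]
    if (a < 0 || a > 1) stop("sample opacities must lie in [0, 1]")
    C <- C + (1 - A) * a * samples[i, 1:3]
    A <- A + (1 - A) * a
    if (early_termination && A > 1 - 1e-6) break
  }
  c(C, A)
}

# Field sampler for surface layers: trilinear indicator / dose value.
surface_field <- function(layer, p, t = 1L) {
  sample_trilinear(layer$source, p, t = t)$value
}

# Central-difference inward gradient -> outward normals for crossing points
# q (m x 3), in the source's own grid axes; rows of zero gradient return 0.
surface_normals <- function(layer, q, t = 1L) {
  g <- layer$source$grid
  m <- nrow(q)
  grad <- matrix(0, m, 3)
  for (a in 1:3) {
    h <- g$spacing[a]
    off <- matrix(g$direction[, a] * h, m, 3, byrow = TRUE)
    fp <- surface_field(layer, q + off, t = t)
    fm <- surface_field(layer, q - off, t = t)
    grad[, a] <- (fp - fm) / (2 * h)
  }
  gw <- grad %*% t(g$direction)  # local axis gradient -> world
  nrm <- sqrt(rowSums(gw^2))
  ok <- nrm > 1e-12
  gw[ok, ] <- -gw[ok, , drop = FALSE] / nrm[ok]
  gw[!ok, ] <- 0
  gw
}

#' Detect an iso-surface crossing between two sample points
#'
#' Reports a crossing iff the (trilinearly interpolated) indicator or dose
#' field crosses the layer's iso value between `p0` and `p1`; the crossing
#' depth is found by inverse linear interpolation and the normal is the
#' normalized negative field gradient (central differences in the source's
#' own grid).
#'
#' @param layer a [surface_layer()].
#' @param p0,p1 consecutive world sample points (distinct), mm.
#' @param t time bin (1-based).
#' @return `NULL` if no crossing; otherwise a list with `fraction` (in
#'   \[0,1\] along `p0 -> p1`), `point` (world mm) and `normal`.
#' @export
detect_surface_crossing <- function(layer, p0, p1, t = 1L) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (sqrt(sum((p1 - p0)^2)) < 1e-15) stop("p0 and p1 must be distinct")
  f0 <- surface_field(layer, p0, t = t)
  f1 <- surface_field(layer, p1, t = t)
  below0 <- f0 < layer$iso
  below1 <- f1 < layer$iso
  if (below0 == below1) return(NULL)
  u <- (layer$iso - f0) / (f1 - f0)
  q <- p0 + u * (p1 - p0)
  n <- drop(surface_normals(layer, matrix(q, 1), t = t))
  list(fraction = u, point = q, normal = n)
}

#' Blinn-Phong shading
#'
#' `(ambient + diffuse * max(n.l, 0)) * base + specular * max(n.h, 0)^shininess`,
#' channel-clamped to \[0,1\]; `h` is the half vector between light and view
#' directions. A zero-length normal (degenerate gradient) returns the
#' unshaded base colour.
#'
#' @param normal surface normal (need not be unit length).
#' @param light_dir unit vector towards the light.
#' @param view_dir unit vector towards the viewer.
#' @param base length-3 base RGB.
#' @param coef list with `ambient`, `diffuse`, `specular`, `shininess`.
#' @return Length-3 shaded RGB in \[0,1\].
#' @export
shade_blinn_phong <- function(normal, light_dir, view_dir, base,
                              coef = list(ambient = 0.25, diffuse = 0.65,
                                          specular = 0.2, shininess = 32)) {
  nl <- sqrt(sum(normal^2))
  if (nl < 1e-12) return(pmin(pmax(base, 0), 1))
  n <- normal / nl
  l <- light_dir / sqrt(sum(light_dir^2))
  v <- view_dir / sqrt(sum(view_dir^2))
  h <- l + v
  hn <- sqrt(sum(h^2))
  ndh <- if (hn < 1e-12) 0 else max(sum(n * (h / hn)), 0)
  ndl <- max(sum(n * l), 0)
  col <- (coef$ambient + coef$diffuse * ndl) * base +
    coef$specular * ndh^coef$shininess
  pmin(pmax(col, 0), 1)
}

# Vectorized shading over rows.
shade_rows <- function(normals, light, view, base_rgb, coef) {
  m <- nrow(normals)
  out <- matrix(0, m, 3)
  for (i in seq_len(m))
    out[i, ] <- shade_blinn_phong(normals[i, ], light[i, ], view[i, ],
                                  base_rgb, coef)
  out
}

default_step <- function(sc) {
  sp <- numeric(0)
  for (il in sc$image_layers) if (il$enabled) sp <- c(sp, il$volume$grid$spacing)
  for (sl in sc$surface_layers) if (sl$enabled) sp <- c(sp, sl$source$grid$spacing)
  if (length(sp) == 0) sp <- sc$ref_grid$spacing
  min(sp) / 2
}

# Step-length opacity correction relative to a 1-mm reference step.
correct_alpha <- function(alpha, step_mm) 1 - (1 - alpha)^step_mm

# Ray / ROI-box intersection in the reference grid's local frame.
# Returns t0, t1 (mm along the unit direction) and a hit flag.
ray_roi_range <- function(sc, org, dir) {
  g <- sc$ref_grid
  ext <- grid_local_extent(g)
  lo <- ext[1, ] + sc$roi[1, ] * (ext[2, ] - ext[1, ])
  hi <- ext[1, ] + sc$roi[2, ] * (ext[2, ] - ext[1, ])
  ol <- sweep(org, 2, g$origin) %*% g$direction
  dl <- dir %*% g$direction
  n <- nrow(org)
  t0 <- rep(0, n); t1 <- rep(Inf, n); hit <- rep(TRUE, n)
  for (a in 1:3) {
    par <- abs(dl[, a]) < 1e-12
    inside_par <- ol[, a] >= lo[a] & ol[, a] <= hi[a]
    hit <- hit & (!par | inside_par)
    ta <- (lo[a] - ol[, a]) / dl[, a]
    tb <- (hi[a] - ol[, a]) / dl[, a]
    tmin <- pmin(ta, tb); tmax <- pmax(ta, tb)
    t0 <- ifelse(par, t0, pmax(t0, tmin))
    t1 <- ifelse(par, t1, pmin(t1, tmax))
  }
  hit <- hit & (t1 >= t0)
  list(t0 = pmax(t0, 0), t1 = t1, hit = hit & (t1 >= 0))
}

#' Render a scene
#'
#' Software ray-casting with accumulation-level intermixing: for every
#' pixel, the ray is marched through the ROI of the reference volume at a
#' fixed world step; at each sample every enabled, mask-visible image layer
#' is evaluated by trilinear interpolation in its own grid (mixed
#' resolutions, no resampling) and fused by [fuse_sample()]; iso-surface
#' crossings of delineations and iso-dose surfaces are inserted as extra
#' shaded samples at their exact depth in compositing order (exclusive
#' opacity). Pixels whose rays miss the ROI show the background. Rendering
#' is fully deterministic.
#'
#' @param sc a [scene()].
#' @param cam a [camera()].
#' @return A `vox_render`: list with `image` (height x width x 4 RGBA
#'   array), `depth` (height x width matrix of first-surface-hit distances
#'   in mm, `Inf` where no surface is hit) and `step_mm`.
#' @export
render <- function(sc, cam) {
  validate_scene(sc)
  rays <- camera_rays(cam)
  n <- nrow(rays$origin)
  rng <- ray_roi_range(sc, rays$origin, rays$dir)
  step <- sc$step_mm %||% default_step(sc)
  t <- sc$time_bin

  ilayers <- Filter(function(l) l$enabled, sc$image_layers)
  slayers <- Filter(function(l) l$enabled, sc$surface_layers)

  Cacc <- matrix(0, n, 3)
  Aacc <- numeric(n)
  depth <- rep(Inf, n)
  done <- !rng$hit
  nsteps <- ifelse(rng$hit, floor((rng$t1 - rng$t0) / step), -1)
  f_prev <- vector("list", length(slayers))
  p_prev <- NULL
  kmax <- max(c(nsteps, 0))

  for (k in 0:kmax) {
    live <- !done & (k <= nsteps)
    if (!any(live)) break
    tk <- rng$t0 + k * step
    p <- rays$origin + rays$dir * tk

    # --- surface crossings in segment (k-1, k) ---
    if (k > 0 && length(slayers) > 0) {
      events <- list()
      for (si in seq_along(slayers)) {
        sl <- slayers[[si]]
        fc <- surface_field(sl, p, t = t)
        fp <- f_prev[[si]]
        crossed <- live & ((fp < sl$iso) != (fc < sl$iso))
        if (any(crossed)) {
          idx <- which(crossed)
          u <- (sl$iso - fp[idx]) / (fc[idx] - fp[idx])
          q <- p_prev[idx, , drop = FALSE] +
            rays$dir[idx, , drop = FALSE] * (u * step)
          rgb <- matrix(sl$color[1:3], length(idx), 3, byrow = TRUE)
          if (sl$shading) {
            normals <- surface_normals(sl, q, t = t)
            view <- -rays$dir[idx, , drop = FALSE]
            light <- if (is.null(sc$light_dir)) view else
              matrix(sc$light_dir, length(idx), 3, byrow = TRUE)
            rgb <- shade_rows(normals, light, view, sl$color[1:3], sc$shading)
          }
          events[[length(events) + 1]] <-
            data.frame(ray = idx, u = u, tdist = tk[idx] - step + u * step,
                       r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                       a = sl$color[4])
        }
        f_prev[[si]] <- fc
      }
      if (length(events) > 0) {
        ev <- do.call(rbind, events)
        ev <- ev[order(ev$ray, ev$u), , drop = FALSE]
        # composite events in depth order; loop over per-ray event rank
        rank_in_ray <- stats::ave(ev$u, ev$ray, FUN = seq_along)
        for (rk in sort(unique(rank_in_ray))) {
          sel <- ev[rank_in_ray == rk, , drop = FALSE]
          act <- !done[sel$ray]
          sel <- sel[act, , drop = FALSE]
          if (nrow(sel) == 0) next
          i <- sel$ray
          trans <- 1 - Aacc[i]
          Cacc[i, ] <- Cacc[i, ] + trans * sel$a * cbind(sel$r, sel$g, sel$b)
          Aacc[i] <- Aacc[i] + trans * sel$a
          newhit <- is.infinite(depth[i])
          depth[i[newhit]] <- sel$tdist[newhit]
          if (sc$early_termination) done[i[Aacc[i] > 1 - 1e-6]] <- TRUE
        }
      }
    } else if (length(slayers) > 0) {
      for (si in seq_along(slayers))
        f_prev[[si]] <- surface_field(slayers[[si]], p, t = t)
    }

    # --- fused volume sample at t_k ---
    if (length(ilayers) > 0) {
      live <- !done & (k <= nsteps)
      if (any(live)) {
        idx <- which(live)
        pm <- p[idx, , drop = FALSE]
        wsum <- numeric(length(idx))
        Cs <- matrix(0, length(idx), 3)
        As <- numeric(length(idx))
        for (il in ilayers) {
          sm <- sample_trilinear(il$volume, pm, t = t)
          contrib <- !sm$outside
          if (length(il$masks) > 0)
            contrib <- contrib & mask_visibility(il, pm, sc$masks, t = t)
          if (!any(contrib)) next
          rgba <- tf_eval(il$tf, sm$value)
          w <- il$weight * as.numeric(contrib)
          wsum <- wsum + w
          Cs <- Cs + rgba[, 1:3, drop = FALSE] * w
          As <- As + rgba[, 4] * w
        }
        pos <- wsum > 0
        if (any(pos)) {
          alpha <- numeric(length(idx))
          alpha[pos] <- As[pos] / wsum[pos]
          col <- matrix(0, length(idx), 3)
          col[pos, ] <- Cs[pos, , drop = FALSE] / wsum[pos]
          seglen <- pmin(step, pmax(rng$t1[idx] - tk[idx], 0))
          alpha <- correct_alpha(alpha, seglen)
          i <- idx
          trans <- 1 - Aacc[i]
          Cacc[i, ] <- Cacc[i, ] + trans * alpha * col
          Aacc[i] <- Aacc[i] + trans * alpha
          if (sc$early_termination) done[i[Aacc[i] > 1 - 1e-6]] <- TRUE
        }
      }
    }
    p_prev <- p
  }

  # composite over background
  bg <- sc$background
  img_flat <- Cacc + (1 - Aacc) * matrix(bg, n, 3, byrow = TRUE)
  image <- array(0, dim = c(cam$height, cam$width, 4))
  for (ch in 1:3)
    image[, , ch] <- matrix(img_flat[, ch], cam$height, cam$width, byrow = TRUE)
  image[, , 4] <- matrix(pmin(Aacc + 0, 1), cam$height, cam$width, byrow = TRUE)
  dep <- matrix(depth, cam$height, cam$width, byrow = TRUE)
  structure(list(image = image, depth = dep, step_mm = step,
                 width = cam$width, height = cam$height),
            class = "vox_render")
}

#' @export
print.vox_render <- function(x, ...) {
  cat(sprintf("<vox_render> %d x %d RGBA, step %.3g mm, %d surface-hit pixel(s)\n",
              x$width, x$height, x$step_mm, sum(is.finite(x$depth))))
  invisible(x)
}

#' Write a rendered image as PNG
#' @param x a `vox_render`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_render_png <- function(x, path) {
  img <- x$image
  img[, , 4] <- 1  # opaque export; compositing already included background
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Pick the nearest delineation surface point under a pixel
#'
#' Casts the pixel's ray and returns the nearest crossing of any enabled
#' delineation (binary-volume) surface layer inside the ROI, for 3D-to-2D
#' slice navigation: the world point is also converted to reference-volume
#' voxel indices.
#'
#' @param sc a [scene()].
#' @param cam a [camera()].
#' @param pixel length-2 `(px, py)` pixel indices, 1-based, within bounds.
#' @return `NULL` if no structure is hit; otherwise a `pick_result`: list
#'   with `structure`, `point` (world mm), `voxel` (1-based reference-grid
#'   indices), `depth_mm`.
#' @export
pick_surface_point <- function(sc, cam, pixel) {
  pixel <- as.numeric(pixel)
  if (pixel[1] < 1 || pixel[1] > cam$width || pixel[2] < 1 || pixel[2] > cam$height)
    stop("pixel out of image bounds")
  rays <- camera_rays(cam, pixels = matrix(pixel, 1))
  rng <- ray_roi_range(sc, rays$origin, rays$dir)
  if (!rng$hit[1]) return(NULL)
  step <- sc$step_mm %||% default_step(sc)
  slayers <- Filter(function(l) l$enabled && inherits(l$source, "binary_volume"),
                    sc$surface_layers)
  if (length(slayers) == 0) return(NULL)
  org <- drop(rays$origin); dir <- drop(rays$dir)
  nst <- floor((rng$t1[1] - rng$t0[1]) / step)
  fp <- lapply(slayers, function(sl)
    surface_field(sl, org + dir * rng$t0[1], t = sc$time_bin))
  for (k in seq_len(max(nst, 0))) {
    tk <- rng$t0[1] + k * step
    pk <- org + dir * tk
    best <- NULL
    for (si in seq_along(slayers)) {
      sl <- slayers[[si]]
      fc <- surface_field(sl, pk, t = sc$time_bin)
      if ((fp[[si]] < sl$iso) != (fc < sl$iso)) {
        u <- (sl$iso - fp[[si]]) / (fc - fp[[si]])
        if (is.null(best) || u < best$u) best <- list(u = u, layer = sl)
      }
      fp[[si]] <- fc
    }
    if (!is.null(best)) {
      tq <- tk - step + best$u * step
      q <- org + dir * tq
      vox <- round(world_to_voxel(sc$ref_grid, q)) + 1
      return(structure(list(structure = best$layer$name, point = q,
                            voxel = as.integer(vox), depth_mm = tq),
                       class = "pick_result"))
    }
  }
  NULL
}

#' @export
print.pick_result <- function(x, ...) {
  cat(sprintf("<pick_result> '%s' at (%.2f, %.2f, %.2f) mm, voxel (%d, %d, %d), depth %.2f mm\n",
              x$structure, x$point[1], x$point[2], x$point[3],
              x$voxel[1], x$voxel[2], x$voxel[3], x$depth_mm))
  invisible(x)
}
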