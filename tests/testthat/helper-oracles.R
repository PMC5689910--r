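# Independent oracles used across the suite. Everything here is written
# from first principles (closed forms, brute force, base R) and never calls
# back into the code path it checks.

# --- back-to-front over-operator compositing oracle --------------------
# over(front, back): C = Cf + (1 - Af) Cb, associative, evaluated from the
# last sample forward.
oracle_composite_btf <- function(samples) {
  samples <- as.matrix(samples)
  C <- c(0, 0, 0)
  A <- 0
  for (i in rev(seq_len(nrow(samples)))) {
    a <- samples[i, 4]
    C <- a * samples[i, 1:3] + (1 - a) * C
    A <- a + (1 - a) * A
  }
  c(C, A)
}

# --- scalar trilinear interpolation (independent) ----------------------
# arr: 3D array; g: list(origin, spacing, dims); identity direction only.
# Returns 0 outside the voxel-centre hull.
oracle_trilinear <- function(arr, origin, spacing, p) {
  v <- (p - origin) / spacing
  d <- dim(arr)
  if (any(v < -1e-12) || any(v > d - 1 + 1e-12)) return(0)
  i0 <- pmin(pmax(floor(v), 0), d - 2)
  f <- v - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
      (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# Vectorised wrapper over rows of pts.
oracle_trilinear_rows <- function(arr, origin, spacing, pts) {
  vapply(seq_len(nrow(pts)), function(i)
    oracle_trilinear(arr, origin, spacing, pts[i, ]), 0)
}

# --- per-pixel closed-form volume-rendering integrator -----------------
# Single image layer, no masks, identity-direction grids. Builds its own
# rays, clips to the ROI box of the reference grid, samples densely at the
# given step, maps values through a piecewise-linear RGBA table (approx),
# applies the declared 1-mm step opacity correction and accumulates with
# the product form  C = sum_i T_i a_i C_i,  T_i = prod_{j<i} (1 - a_j).
oracle_render_volume <- function(arr, origin, spacing, tf_values, tf_colors,
                                 ref_origin, ref_spacing, ref_dims,
                                 roi_low, roi_high, cam, step, background) {
  fwd <- cam$look_at - cam$eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * cam$up[3] - fwd[3] * cam$up[2],
             fwd[3] * cam$up[1] - fwd[1] * cam$up[3],
             fwd[1] * cam$up[2] - fwd[2] * cam$up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  tanf <- tan(cam$fov / 2 * pi / 180)
  aspect <- cam$width / cam$height
  box_lo <- ref_origin - ref_spacing / 2 +
    roi_low * ref_spacing * ref_dims
  box_hi <- ref_origin - ref_spacing / 2 +
    roi_high * ref_spacing * ref_dims
  img <- array(0, dim = c(cam$height, cam$width, 3))
  for (py in seq_len(cam$height)) {
    for (px in seq_len(cam$width)) {
      xn <- (px - 0.5) / cam$width * 2 - 1
      yn <- 1 - (py - 0.5) / cam$height * 2
      dir <- xn * tanf * aspect * right + yn * tanf * upv + fwd
      dir <- dir / sqrt(sum(dir^2))
      t0 <- 0; t1 <- Inf; hit <- TRUE
      for (a in 1:3) {
        if (abs(dir[a]) < 1e-12) {
          if (cam$eye[a] < box_lo[a] || cam$eye[a] > box_hi[a]) hit <- FALSE
        } else {
          ta <- (box_lo[a] - cam$eye[a]) / dir[a]
          tb <- (box_hi[a] - cam$eye[a]) / dir[a]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        }
      }
      if (!hit || t1 < t0) { img[py, px, ] <- background; next }
      ts <- seq(t0, t1, by = step)
      pts <- cbind(cam$eye[1] + ts * dir[1],
                   cam$eye[2] + ts * dir[2],
                   cam$eye[3] + ts * dir[3])
      vals <- oracle_trilinear_rows(arr, origin, spacing, pts)
      rgba <- sapply(1:4, function(ch)
        approx(tf_values, tf_colors[, ch], xout = vals, rule = 2)$y)
      rgba <- matrix(rgba, ncol = 4)
      # zero colour/opacity outside the source hull
      outside <- pts[, 1] < origin[1] - 1e-12 |
        pts[, 1] > origin[1] + (dim(arr)[1] - 1) * spacing[1] + 1e-12 |
        pts[, 2] < origin[2] - 1e-12 |
        pts[, 2] > origin[2] + (dim(arr)[2] - 1) * spacing[2] + 1e-12 |
        pts[, 3] < origin[3] - 1e-12 |
        pts[, 3] > origin[3] + (dim(arr)[3] - 1) * spacing[3] + 1e-12
      rgba[outside, 4] <- 0
      seglen <- pmin(step, t1 - ts)
      alpha <- 1 - (1 - rgba[, 4])^seglen
      Tfull <- cumprod(1 - alpha)
      Ti <- c(1, head(Tfull, -1))
      C <- colSums(Ti * alpha * rgba[, 1:3, drop = FALSE])
      A <- 1 - prod(1 - alpha)
      img[py, px, ] <- C + (1 - A) * background
    }
  }
  img
}

# --- brute-force surface distances -------------------------------------
oracle_surface_voxels <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (m[i, j, k] <= 0.5) next
    nb_bg <- i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3]
    if (!nb_bg) {
      nb_bg <- m[i - 1, j, k] <= 0.5 || m[i + 1, j, k] <= 0.5 ||
        m[i, j - 1, k] <= 0.5 || m[i, j + 1, k] <= 0.5 ||
        m[i, j, k - 1] <= 0.5 || m[i, j, k + 1] <= 0.5
    }
    out[i, j, k] <- nb_bg
  }
  out
}

oracle_hausdorff <- function(ma, mb, spacing) {
  sa <- which(oracle_surface_voxels(ma), arr.ind = TRUE)
  sb <- which(oracle_surface_voxels(mb), arr.ind = TRUE)
  pa <- sweep(sa - 1, 2, spacing, "*")
  pb <- sweep(sb - 1, 2, spacing, "*")
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  a_to_b <- apply(dmat, 1, min)
  b_to_a <- apply(dmat, 2, min)
  pooled <- c(a_to_b, b_to_a)
  list(a_to_b = a_to_b, b_to_a = b_to_a,
       hd_max = max(pooled), hd_avg = mean(pooled),
       hd_95 = unname(quantile(pooled, 0.95, type = 7)))
}

# --- brute-force Euclidean dilation ------------------------------------
oracle_dilate <- function(m, spacing, margin) {
  fg <- which(m > 0.5, arr.ind = TRUE)
  d <- dim(m)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    dx <- (fg[, 1] - i) * spacing[1]
    dy <- (fg[, 2] - j) * spacing[2]
    dz <- (fg[, 3] - k) * spacing[3]
    if (min(dx^2 + dy^2 + dz^2) <= margin^2 + 1e-9) out[i, j, k] <- 1
  }
  out
}

# --- ray / axis-aligned box intersection (static-pixel analysis) -------
ray_hits_aabb <- function(org, dir, lo, hi) {
  t0 <- 0; t1 <- Inf
  for (a in 1:3) {
    if (abs(dir[a]) < 1e-12) {
      if (org[a] < lo[a] || org[a] > hi[a]) return(FALSE)
    } else {
      ta <- (lo[a] - org[a]) / dir[a]
      tb <- (hi[a] - org[a]) / dir[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  t1 >= t0 && t1 >= 0
}
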