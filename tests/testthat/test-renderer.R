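test_that("fuse_sample normalizes weights and averages colour and opacity", {
  one <- fuse_sample(c(0.2, 0.3, 0.4), 0.5, 7)
  expect_equal(one, c(0.2, 0.3, 0.4, 0.5))

  two <- fuse_sample(rbind(c(1, 0, 0), c(0, 0, 1)), c(0.4, 0.8), c(1, 1))
  expect_equal(two, c(0.5, 0, 0.5, 0.6))

  scaled <- fuse_sample(rbind(c(1, 0, 0), c(0, 0, 1)), c(0.4, 0.8), c(2, 2))
  expect_equal(scaled, two)

  expect_error(fuse_sample(rbind(c(1, 0, 0)), 0.4, 0), "not all be zero")
  expect_error(fuse_sample(rbind(c(1, 0, 0)), 0.4, -1), ">= 0")
})

test_that("front-to-back compositing matches closed forms and the over oracle", {
  opaque <- composite_front_to_back(c(0.3, 0.6, 0.9, 1))
  expect_equal(opaque, c(0.3, 0.6, 0.9, 1))

  two <- composite_front_to_back(rbind(c(1, 0, 0, 0.5), c(0, 1, 0, 0.5)))
  expect_equal(two[4], 0.75)
  expect_equal(two[1:3], 0.5 * c(1, 0, 0) + 0.25 * c(0, 1, 0))

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(1:50, 1)
    samples <- cbind(matrix(runif(3 * n), n, 3), runif(n))
    got <- composite_front_to_back(samples)
    want <- oracle_composite_btf(samples)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("early termination changes the result by less than 1e-6 when saturated", {
  set.seed(4)
  samples <- cbind(matrix(runif(300), 100, 3), runif(100, 0.3, 0.9))
  a <- composite_front_to_back(samples, early_termination = FALSE)
  b <- composite_front_to_back(samples, early_termination = TRUE)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("surface crossings are located by inverse interpolation", {
  g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(4, 4, 4))
  ind <- array(0, dim = c(4, 4, 4)); ind[2:4, , ] <- 1  # step at x between 0 and 1
  lay <- surface_layer(binary_volume(g, ind, name = "s"))
  cr <- detect_surface_crossing(lay, c(0, 1, 1), c(1, 1, 1))
  expect_equal(cr$fraction, 0.5)
  expect_equal(cr$point, c(0.5, 1, 1))
  expect_equal(cr$normal, c(-1, 0, 0))  # outward: towards decreasing indicator

  expect_null(detect_surface_crossing(lay, c(2, 1, 1), c(3, 1, 1)))

  dg <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(4, 4, 4))
  dd <- array(rep(c(30, 40, 50, 60), times = 16), dim = c(4, 4, 4))
  dl <- surface_layer(dose_volume(dg, dd), iso = 37.5)
  cd <- detect_surface_crossing(dl, c(0, 2, 2), c(1, 2, 2))
  expect_equal(cd$fraction, 0.75)
})

test_that("Blinn-Phong shading obeys its closed forms and stays in [0,1]", {
  base <- c(0.2, 0.6, 0.9)
  co <- list(ambient = 0.1, diffuse = 0.9, specular = 0, shininess = 16)
  perp <- shade_blinn_phong(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1), base, co)
  expect_equal(perp, 0.1 * base)

  full <- shade_blinn_phong(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1), base, co)
  expect_equal(full, pmin(1, 1.0 * base))

  expect_equal(shade_blinn_phong(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1), base, co),
               base)  # degenerate gradient -> unshaded

  set.seed(9)
  co2 <- list(ambient = 0.3, diffuse = 0.8, specular = 0.6, shininess = 8)
  for (i in 1:50) {
    out <- shade_blinn_phong(rnorm(3), rnorm(3), rnorm(3), runif(3), co2)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("ROI membership uses the closed sub-box of the reference bounds", {
  g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(10, 10, 10))
  ref <- scalar_volume(g, array(0, dim = c(10, 10, 10)))
  sc_full <- scene(ref)
  expect_true(in_roi(sc_full, c(5, 5, 5)))
  expect_true(in_roi(sc_full, c(-0.5, -0.5, -0.5)))   # on the clipping plane
  expect_false(in_roi(sc_full, c(-2, 5, 5)))

  sc_mid <- scene(ref, roi = rbind(low = c(0.4, 0, 0), high = c(0.6, 1, 1)))
  # axis extent is [-0.5, 9.5]; fraction 0.3 -> x = 2.5 (outside 0.4..0.6)
  expect_false(in_roi(sc_mid, c(2.5, 5, 5)))
  expect_true(in_roi(sc_mid, c(4.7, 5, 5)))
  expect_error(scene(ref, roi = rbind(low = c(0.7, 0, 0), high = c(0.6, 1, 1))),
               "low < high")
})

test_that("mask visibility defaults to visible and unions across masks", {
  g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(10, 10, 10))
  vol <- scalar_volume(g, array(1, dim = c(10, 10, 10)))
  tf <- gray_ramp_tf(0, 1)
  m1 <- array(0, dim = c(10, 10, 10)); m1[1:3, , ] <- 1
  m2 <- array(0, dim = c(10, 10, 10)); m2[8:10, , ] <- 1
  masks <- list(a = binary_volume(g, m1, name = "a"),
                b = binary_volume(g, m2, name = "b"))

  free <- image_layer(vol, tf)
  expect_true(all(mask_visibility(free, rbind(c(5, 5, 5), c(50, 0, 0)), masks)))

  gated <- image_layer(vol, tf, masks = c("a", "b"))
  vis <- mask_visibility(gated, rbind(c(1, 5, 5), c(5, 5, 5), c(9, 5, 5)), masks)
  expect_equal(vis, c(TRUE, FALSE, TRUE))

  expect_error(scene(vol, image_layers = list(image_layer(vol, tf, masks = "nope")),
                     masks = masks), "unknown mask")
})

test_that("empty scenes and zero-extent ROIs render pure background", {
  g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(10, 10, 10))
  ref <- scalar_volume(g, array(1, dim = c(10, 10, 10)))
  cam <- camera(eye = c(60, 4, 4), look_at = c(4, 4, 4), width = 8, height = 8)
  sc <- scene(ref, background = c(0.1, 0.2, 0.3))
  r <- render(sc, cam)
  for (ch in 1:3)
    expect_equal(unique(as.vector(r$image[, , ch])), sc$background[ch])
  expect_true(all(is.infinite(r$depth)))

  thin <- scene(ref, image_layers = list(image_layer(ref, gray_ramp_tf(0, 1))),
                roi = rbind(low = c(0, 0, 0), high = c(1e-9, 1, 1)),
                background = c(0.5, 0.5, 0.5))
  r2 <- render(thin, cam)
  expect_equal(max(abs(r2$image[, , 1] - 0.5)), 0, tolerance = 1e-6)
})

test_that("single-layer renders match the independent per-pixel integrator", {
  # ramp volume
  dims <- c(24, 24, 24)
  g <- grid3d(origin = -(dims - 1) / 2, spacing = c(1, 1, 1), dims = dims)
  ramp <- array(rep(seq(0, 1, length.out = 24), times = 576), dim = dims)
  vol <- scalar_volume(g, ramp)
  tf_vals <- c(0, 1); tf_cols <- rbind(c(0, 0, 0.2, 0), c(1, 0.8, 0.2, 0.6))
  tf <- transfer_function(tf_vals, tf_cols)
  cam <- camera(eye = c(70, 25, 18), look_at = c(0, 0, 0), fov = 30,
                width = 32, height = 32)
  sc <- scene(vol, image_layers = list(image_layer(vol, tf)),
              step_mm = 0.8, early_termination = FALSE,
              background = c(0.05, 0.05, 0.05))
  got <- render(sc, cam)
  want <- oracle_render_volume(ramp, g$origin, g$spacing, tf_vals, tf_cols,
                               g$origin, g$spacing, g$dims,
                               c(0, 0, 0), c(1, 1, 1), cam, 0.8,
                               sc$background)
  expect_lt(max(abs(got$image[, , 1:3] - want)), 1e-3)

  # constant-colour sphere indicator volume
  sph <- sphere_indicator(c(0, 0, 0), 9, dims = c(26, 26, 26))
  svol <- scalar_volume(sph$grid, sph$arr)
  tf2v <- c(0, 1); tf2c <- rbind(c(1, 0.2, 0.1, 0), c(1, 0.2, 0.1, 0.5))
  sc2 <- scene(svol, image_layers = list(image_layer(svol, transfer_function(tf2v, tf2c))),
               step_mm = 0.7, early_termination = FALSE)
  cam2 <- camera(eye = c(-60, 30, 22), look_at = c(0, 0, 0), fov = 35,
                 width = 32, height = 32)
  got2 <- render(sc2, cam2)
  want2 <- oracle_render_volume(sph$arr, sph$grid$origin, sph$grid$spacing,
                                tf2v, tf2c, sph$grid$origin, sph$grid$spacing,
                                sph$grid$dims, c(0, 0, 0), c(1, 1, 1),
                                cam2, 0.7, c(0, 0, 0))
  expect_lt(max(abs(got2$image[, , 1:3] - want2)), 1e-3)
})

test_that("an opaque shaded sphere shows the analytic front-pole shade at centre", {
  sph <- sphere_indicator(c(0, 0, 0), 10, dims = c(32, 32, 32))
  bv <- binary_volume(sph$grid, sph$arr, name = "sphere",
                      color = c(0.8, 0.3, 0.2, 1))
  ref <- scalar_volume(sph$grid, array(0, dim = sph$grid$dims))
  sc <- scene(ref, surface_layers = list(surface_layer(bv)), step_mm = 0.25)
  cam <- camera(eye = c(200, 0, 0), look_at = c(0, 0, 0), fov = 12,
                width = 33, height = 33)
  r <- render(sc, cam)
  centre <- r$image[17, 17, 1:3]
  # headlight at the eye: n = l = v at the front pole
  want <- shade_blinn_phong(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0),
                            c(0.8, 0.3, 0.2), sc$shading)
  expect_lt(max(abs(centre - want)), 1e-3)
  # depth buffer: front pole at x = 10 -> 190 mm from the eye
  expect_lt(abs(r$depth[17, 17] - 190), 2 * r$step_mm + 0.25)
})

test_that("mixed-resolution rendering equals a pre-upsampled copy", {
  set.seed(31)
  cdims <- c(12, 12, 12)
  cg <- grid3d(origin = -(cdims - 1) * 4 / 2, spacing = c(4, 4, 4), dims = cdims)
  coarse_arr <- array(runif(prod(cdims), 0, 10), dim = cdims)
  coarse <- scalar_volume(cg, coarse_arr, modality = "PET")

  fdims <- (cdims - 1) * 4L + 1L
  fg <- grid3d(origin = cg$origin, spacing = c(1, 1, 1), dims = fdims)
  pts <- voxray:::grid_voxel_centers(fg)
  fine_arr <- array(sample_trilinear(coarse, pts)$value, dim = fdims)
  fine <- scalar_volume(fg, fine_arr, modality = "PET")

  tf <- tf_from_window(window_level(2, 8), cap = 0.7, color = c(1, 0.4, 0))
  cam <- camera(eye = c(120, 60, 40), look_at = c(0, 0, 0), fov = 30,
                width = 32, height = 32)
  mk <- function(vol) scene(coarse, image_layers = list(image_layer(vol, tf)),
                            step_mm = 1, early_termination = FALSE)
  rc <- render(mk(coarse), cam)
  rf <- render(mk(fine), cam)
  expect_lt(max(abs(rc$image - rf$image)), 1e-3)
})

test_that("time-bin changes leave pixels of static-only coverage untouched", {
  bundle <- phantom_fixture()
  tf_ct <- gray_ramp_tf(-900, 100, 0.4)
  tf_pet <- tf_from_window(window_level(1.5, 4), cap = 0.7)
  sc1 <- scene(bundle$planning_ct,
               image_layers = list(image_layer(bundle$planning_ct, tf_ct),
                                   image_layer(bundle$pet_4d, tf_pet)),
               time_bin = 1, step_mm = 1.5)
  sc2 <- sc1; sc2$time_bin <- 3L
  cam <- camera(eye = c(260, 40, 30), look_at = c(0, 0, 0), fov = 30,
                width = 24, height = 24)
  r1 <- render(sc1, cam); r2 <- render(sc2, cam)

  # pixels whose rays miss the PET bounding box must be bit-identical
  rays <- voxray:::camera_rays(cam)
  pg <- bundle$pet_4d$grid
  lo <- pg$origin - pg$spacing / 2
  hi <- pg$origin + (pg$dims - 0.5) * pg$spacing
  static_only <- !vapply(seq_len(nrow(rays$dir)), function(i)
    ray_hits_aabb(rays$origin[i, ], rays$dir[i, ], lo, hi), TRUE)
  static_mat <- matrix(static_only, cam$height, cam$width, byrow = TRUE)
  expect_gt(sum(static_mat), 0)
  for (ch in 1:4)
    expect_identical(r1$image[, , ch][static_mat], r2$image[, , ch][static_mat])
  # and the moving lesion must change something
  expect_gt(max(abs(r1$image - r2$image)), 0)
})

test_that("disabling a layer equals removing it; empty-mask gating disables", {
  bundle <- phantom_fixture()
  tf_ct <- gray_ramp_tf(-900, 100, 0.4)
  tf_pet <- tf_from_window(window_level(1.5, 4), cap = 0.7)
  cam <- camera(eye = c(250, -60, 40), look_at = c(0, 0, 0), fov = 28,
                width = 16, height = 16)
  ct_layer <- image_layer(bundle$planning_ct, tf_ct)
  pet_layer <- image_layer(bundle$pet_4d, tf_pet)
  pet_off <- pet_layer; pet_off$enabled <- FALSE

  base <- scene(bundle$planning_ct, image_layers = list(ct_layer), step_mm = 1)
  with_off <- scene(bundle$planning_ct, image_layers = list(ct_layer, pet_off),
                    step_mm = 1)
  expect_identical(render(base, cam)$image, render(with_off, cam)$image)

  empty <- binary_volume(bundle$planning_ct$grid,
                         array(0, dim = bundle$planning_ct$grid$dims),
                         name = "empty")
  pet_masked <- image_layer(bundle$pet_4d, tf_pet, masks = "empty")
  gated <- scene(bundle$planning_ct, image_layers = list(ct_layer, pet_masked),
                 masks = list(empty = empty), step_mm = 1)
  expect_identical(render(gated, cam)$image, render(base, cam)$image)
})

test_that("with nested opaque surfaces the outer surface wins every pixel", {
  outer_s <- sphere_indicator(c(0, 0, 0), 10, dims = c(30, 30, 30))
  inner_s <- sphere_indicator(c(0, 0, 0), 5, dims = c(30, 30, 30))
  bo <- binary_volume(outer_s$grid, outer_s$arr, name = "outer",
                      color = c(1, 0, 0, 1))
  bi <- binary_volume(inner_s$grid, inner_s$arr, name = "inner",
                      color = c(0, 0, 1, 1))
  ref <- scalar_volume(outer_s$grid, array(0, dim = outer_s$grid$dims))
  sc <- scene(ref, surface_layers = list(surface_layer(bi, shading = FALSE),
                                         surface_layer(bo, shading = FALSE)),
              step_mm = 0.5)
  cam <- camera(eye = c(120, 10, 5), look_at = c(0, 0, 0), fov = 20,
                width = 16, height = 16)
  r <- render(sc, cam)
  hit <- is.finite(r$depth)
  expect_gt(sum(hit), 10)
  expect_true(all(abs(r$image[, , 1][hit] - 1) < 1e-9))
  expect_true(all(abs(r$image[, , 3][hit]) < 1e-9))
})

test_that("picking returns the nearest structure consistent with the depth buffer", {
  s1 <- sphere_indicator(c(0, 0, 0), 8, dims = c(30, 30, 30))
  s2 <- sphere_indicator(c(-20, 0, 0), 6, dims = c(60, 30, 30),
                         origin = c(-44.5, -14.5, -14.5))
  b1 <- binary_volume(s1$grid, s1$arr, name = "near_sphere")
  b2 <- binary_volume(s2$grid, s2$arr, name = "far_sphere")
  ref_g <- grid3d(origin = c(-50, -15, -15), spacing = c(1, 1, 1),
                  dims = c(70, 31, 31))
  ref <- scalar_volume(ref_g, array(0, dim = ref_g$dims))
  sc <- scene(ref, surface_layers = list(surface_layer(b2), surface_layer(b1)),
              step_mm = 0.5)
  cam <- camera(eye = c(150, 0, 0), look_at = c(-20, 0, 0), fov = 25,
                width = 21, height = 21)
  pk <- pick_surface_point(sc, cam, c(11, 11))
  expect_equal(pk$structure, "near_sphere")  # nearer structure along the ray
  # analytic: front pole of the near sphere at x = 8
  expect_lt(abs(pk$point[1] - 8), 1)
  expect_lt(max(abs(pk$point[2:3])), 1)
  r <- render(sc, cam)
  expect_lt(abs(pk$depth_mm - r$depth[11, 11]), r$step_mm + 1e-9)

  expect_null(pick_surface_point(sc, cam, c(1, 1)))  # background pixel
  expect_error(pick_surface_point(sc, cam, c(99, 1)), "out of image bounds")
})
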