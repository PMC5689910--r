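square_ss <- function(z = 0, half = 5, center = c(4.5, 4.5), role = "target") {
  v <- rbind(center + c(-half, -half), center + c(half, -half),
             center + c(half, half), center + c(-half, half))
  structure_set(list(sq = list(contours = list(list(planar_contour(z, v))),
                               color = c(0, 1, 0, 1), role = role)))
}

test_that("JSON structure sets round-trip exactly", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ss <- structure_set(list(
    circle = list(contours = list(list(
      planar_contour(3, cbind(10 * cos(th), 10 * sin(th))),
      planar_contour(6, cbind(8 * cos(th), 8 * sin(th))))),
      color = c(1, 0, 0, 0.5), role = "target"),
    box = list(contours = list(list(
      planar_contour(0, rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))))),
      color = c(0, 0, 1, 1), role = "OAR")))
  path <- tempfile(fileext = ".json")
  write_structure_set(ss, path)
  back <- read_structure_set(path)
  expect_setequal(names(back$structures), names(ss$structures))
  expect_equal(back$structures$circle$contours[[1]][[1]]$vertices,
               ss$structures$circle$contours[[1]][[1]]$vertices,
               tolerance = 1e-9)
  expect_equal(back$structures$box$role, "OAR")
  expect_equal(back$structures$circle$color, c(1, 0, 0, 0.5))
})

test_that("degenerate structure-set files and polygons are rejected", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(structures = list()), path)
  expect_error(read_structure_set(path), "empty structure set")
  expect_error(read_structure_set(tempfile()), "no such file")
  expect_error(planar_contour(0, rbind(c(0, 0), c(1, 1))), ">= 3 vertices")
  # bow-tie polygon: flagged but representable
  expect_warning(planar_contour(0, rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
                 "self-intersecting")
})

test_that("a voxel-centre aligned square rasterizes to its exact voxel count", {
  g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(12, 12, 3))
  # square covering centres 0..9 in x and y, strictly between centres at edges
  ss <- square_ss(z = 1, half = 5, center = c(4.5, 4.5))
  m <- rasterize(ss, "sq", g, t = 1)
  expect_equal(sum(m$frames[[1]]), 100)
  expect_equal(sum(m$frames[[1]][, , 2]), 100)  # all in slice z = 1
})

test_that("rasterization matches an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  set.seed(21)
  g <- grid3d(origin = c(-10, -10, 0), spacing = c(1, 1, 1), dims = c(21, 21, 1))
  for (rep in 1:5) {
    th <- sort(runif(8, 0, 2 * pi))
    r <- runif(8, 3, 9)
    v <- cbind(r * cos(th), r * sin(th))
    ss <- structure_set(list(poly = list(
      contours = list(list(planar_contour(0, v))),
      color = c(1, 0, 0, 1), role = "target")))
    m <- rasterize(ss, "poly", g, t = 1)
    centers <- expand.grid(x = -10:10, y = -10:10)
    want <- pracma::inpolygon(centers$x, centers$y, v[, 1], v[, 2],
                              boundary = TRUE)
    expect_equal(as.vector(m$frames[[1]][, , 1] > 0.5), want)
  }
})

test_that("a rasterized circle recovers its analytic area within 2%", {
  r <- 20
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  v <- cbind(r * cos(th), r * sin(th))
  ss <- structure_set(list(circ = list(
    contours = list(list(planar_contour(0, v))),
    color = c(1, 0, 0, 1), role = "target")))
  g1 <- grid3d(origin = c(-24, -24, 0), spacing = c(1, 1, 1), dims = c(49, 49, 1))
  m1 <- rasterize(ss, "circ", g1)
  area1 <- sum(m1$frames[[1]]) * 1
  expect_lt(abs(area1 - pi * r^2) / (pi * r^2), 0.02)

  # area estimate converges with resolution
  g2 <- grid3d(origin = c(-24, -24, 0), spacing = c(2, 2, 1), dims = c(25, 25, 1))
  m2 <- rasterize(ss, "circ", g2)
  area2 <- sum(m2$frames[[1]]) * 4
  expect_lte(abs(area1 - pi * r^2), abs(area2 - pi * r^2) + 1e-9)
})

test_that("rasterization is translation-equivariant", {
  shift <- c(3.7, -1.2, 6)
  v <- rbind(c(-4, -3), c(5, -2), c(6, 6), c(-5, 4))
  mk <- function(offset) {
    ss <- structure_set(list(p = list(
      contours = list(list(planar_contour(2 + offset[3],
                                          sweep(v, 2, offset[1:2], `+`)))),
      color = c(1, 0, 0, 1), role = "target")))
    g <- grid3d(origin = c(-10, -10, 2) + offset, spacing = c(1, 1, 2),
                dims = c(21, 21, 2))
    rasterize(ss, "p", g)
  }
  a <- mk(c(0, 0, 0)); b <- mk(shift)
  expect_equal(a$frames[[1]], b$frames[[1]])
})

test_that("contours must land near a slice centre; nested contours cut holes", {
  g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 2), dims = c(12, 12, 4))
  far <- structure_set(list(f = list(
    contours = list(list(planar_contour(90, rbind(c(0, 0), c(3, 0), c(3, 3))))),
    color = c(1, 0, 0, 1), role = "target")))
  expect_error(rasterize(far, "f", g), "farther than half a slice")
  expect_error(rasterize(square_ss(), "nope", g), "no such structure")

  outer_sq <- rbind(c(-0.2, -0.2), c(9.2, -0.2), c(9.2, 9.2), c(-0.2, 9.2))
  inner_sq <- rbind(c(2.8, 2.8), c(5.2, 2.8), c(5.2, 5.2), c(2.8, 5.2))
  ss <- structure_set(list(ring = list(
    contours = list(list(planar_contour(2, outer_sq),
                         planar_contour(2, inner_sq))),
    color = c(1, 0, 0, 1), role = "target")))
  m <- rasterize(ss, "ring", g)
  sl <- m$frames[[1]][, , 2]
  expect_equal(sum(sl), 100 - 9)      # 10x10 outer minus 3x3 hole
  expect_equal(sl[5, 5], 0)           # centre (4,4) inside the hole
  expect_equal(sl[2, 2], 1)
})

test_that("majority vote implements k-of-n semantics exactly", {
  g <- grid3d(dims = c(4, 4, 4))
  mk <- function(val) binary_volume(g, array(val, dim = c(4, 4, 4)))
  # voxel-level construction: counts 0..4 laid out deterministically
  counts <- array(rep(0:4, length.out = 64), dim = c(4, 4, 4))
  masks <- lapply(1:4, function(i) {
    binary_volume(g, array(as.numeric(counts >= i), dim = c(4, 4, 4)))
  })
  mv3 <- majority_vote(masks, k = 3)
  expect_equal(mv3$frames[[1]], array(as.numeric(counts >= 3), dim = c(4, 4, 4)))
  # 3-of-4 voxel with exactly 3 votes is in, exactly 2 votes is out
  expect_true(all((mv3$frames[[1]] == 1) == (counts >= 3)))

  same <- lapply(1:4, function(i) mk(1))
  expect_equal(majority_vote(same, 3)$frames[[1]], mk(1)$frames[[1]])

  expect_error(majority_vote(masks, k = 5), "exceeds")
  g2 <- grid3d(origin = c(1, 0, 0), dims = c(4, 4, 4))
  bad <- c(masks[1:3], list(binary_volume(g2, array(1, dim = c(4, 4, 4)))))
  expect_error(majority_vote(bad, 3), "identical grids")
})

test_that("majority vote reduces to union and intersection at k = 1 and k = n", {
  set.seed(33)
  g <- grid3d(dims = c(6, 6, 6))
  masks <- lapply(1:4, function(i)
    binary_volume(g, array(as.numeric(runif(216) < 0.4), dim = c(6, 6, 6))))
  u <- majority_vote(masks, 1)$frames[[1]]
  itr <- majority_vote(masks, 4)$frames[[1]]
  want_u <- array(as.numeric(Reduce(`|`, lapply(masks, function(m) m$frames[[1]] > 0.5))),
                  dim = c(6, 6, 6))
  want_i <- array(as.numeric(Reduce(`&`, lapply(masks, function(m) m$frames[[1]] > 0.5))),
                  dim = c(6, 6, 6))
  expect_equal(u, want_u)
  expect_equal(itr, want_i)
})
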