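#' Planar contour and structure set containers
#'
#' Radiotherapy structure sets are stacks of closed planar polygons, one or
#' more per axial slab. `planar_contour()` holds one polygon: its slab
#' position `z` (world mm) and its ordered `(x, y)` vertices (world mm,
#' implicitly closed). `structure_set()` collects named structures, each a
#' list of per-time-bin contour lists with a display colour and a role tag.
#'
#' Self-intersecting polygons are detected at construction and flagged with
#' a warning; they are still stored (the even-odd fill rule gives them a
#' well-defined rasterization).
#'
#' @param z slab position, mm.
#' @param vertices n x 2 matrix of polygon vertices (x, y), mm, n >= 3.
#' @return `planar_contour` / `structure_set` objects.
#' @export
planar_contour <- function(z, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(length(z) == 1, ncol(vertices) == 2)
  if (nrow(vertices) < 3) stop("a planar contour needs >= 3 vertices")
  if (polygon_self_intersects(vertices))
    warning("contour polygon is self-intersecting")
  structure(list(z = as.numeric(z), vertices = vertices),
            class = "planar_contour")
}

# Segment-pair intersection scan (small polygons; O(E^2)).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  vv <- rbind(v, v[1, ])
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    s <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    t <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    s > 1e-9 && s < 1 - 1e-9 && t > 1e-9 && t < 1 - 1e-9
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (seg_int(vv[i, ], vv[i + 1, ], vv[j, ], vv[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' @rdname planar_contour
#' @param structures named list; each element a list with fields `contours`
#'   (a list of time bins, each a list of `planar_contour`s), `color`
#'   (RGBA), `role` (one of `"target"`, `"OAR"`, `"margin"`).
#' @export
structure_set <- function(structures) {
  nms <- names(structures)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == ""))
    stop("structure names must be unique and non-empty")
  if (length(structures) == 0) stop("empty structure set")
  for (s in structures) {
    if (!length(s$contours) || !any(vapply(s$contours, length, 1L) > 0))
      stop("each structure needs >= 1 contour in >= 1 time bin")
  }
  structure(list(structures = structures), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structure(s)\n", length(x$structures)))
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    nb <- length(s$contours)
    nc <- sum(vapply(s$contours, length, 1L))
    cat(sprintf("  %s [%s]: %d contour(s) over %d bin(s)\n",
                nm, s$role %||% "target", nc, nb))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

structure_names <- function(ss) names(ss$structures)

#' Read a structure set
#'
#' Reads the plain JSON contour dialect shipped with this package (see
#' [write_structure_set()] for the schema). The dialect stores all vertices
#' in world millimetres in the frame of reference of the referenced image.
#'
#' @param path file path.
#' @param dialect only `"json"` is supported.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(path, dialect = "json") {
  if (!file.exists(path)) stop("cannot read structure set: no such file: ", path)
  dialect <- match.arg(dialect, "json")
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$structures) || length(doc$structures) == 0)
    stop("empty structure set: ", path)
  structs <- list()
  for (s in doc$structures) {
    bins <- lapply(s$bins, function(bin) {
      lapply(bin, function(cn) {
        verts <- do.call(rbind, lapply(cn$vertices, function(v) unlist(v)))
        planar_contour(z = cn$z, vertices = verts)
      })
    })
    structs[[s$name]] <- list(
      contours = bins,
      color = as.numeric(unlist(s$color %||% c(1, 0, 0, 1))),
      role = s$role %||% "target")
  }
  structure_set(structs)
}

#' Write a structure set as JSON
#'
#' Schema: `{"structures": [{"name", "role", "color": [r,g,b,a], "bins":
#' [[{"z": mm, "vertices": [[x, y], ...]}, ...], ...]}]}` — one `bins` entry
#' per time bin, each a list of planar contours with world-mm coordinates.
#'
#' @param ss a [structure_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(ss, path) {
  stopifnot(inherits(ss, "structure_set"))
  doc <- list(structures = lapply(names(ss$structures), function(nm) {
    s <- ss$structures[[nm]]
    list(name = nm, role = s$role %||% "target",
         color = s$color %||% c(1, 0, 0, 1),
         bins = lapply(s$contours, function(bin) {
           lapply(bin, function(cn) {
             list(z = cn$z,
                  vertices = lapply(seq_len(nrow(cn$vertices)),
                                    function(i) as.numeric(cn$vertices[i, ])))
           })
         }))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd point-in-polygon with inclusive boundary.
# px, py: point vectors; v: polygon vertices (closed implicitly).
points_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    # crossing test (half-open in y to avoid double-counting vertices)
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      inside <- xor(inside, crosses & (px < xint))
    }
    # boundary test: distance from point to segment < eps
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(pmax(((px - xi) * dx + (py - yi) * dy) / len2, 0), 1)
      d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize a structure onto a grid
#'
#' Converts the planar contours of one structure into a binary volume with
#' the in-plane resolution of `grid` (typically the planning CT): a voxel is
#' foreground iff its centre lies inside the polygon(s) assigned to its
#' slice, under the even-odd fill rule with inclusive boundaries (nested
#' contours become holes). Each contour is assigned to the nearest slice
#' centre in z within half a slice spacing; a contour farther than that from
#' every slice is an error. By default the output keeps the full grid
#' extent; with `crop = TRUE` the axial extent is reduced to the slab range
#' actually covered by contours.
#'
#' @param ss a [structure_set()].
#' @param name structure name.
#' @param grid reference [grid3d()].
#' @param t time bin (1-based).
#' @param crop crop the output axially to the covered slab range?
#' @return A `binary_volume` on `grid` (or its axial crop).
#' @export
rasterize <- function(ss, name, grid, t = 1L, crop = FALSE) {
  stopifnot(inherits(ss, "structure_set"), is_grid3d(grid))
  s <- ss$structures[[name]]
  if (is.null(s)) stop("no such structure: ", name)
  nb <- length(s$contours)
  tt <- if (nb == 1L) 1L else t
  if (tt < 1L || tt > nb || length(s$contours[[tt]]) == 0)
    stop(sprintf("structure '%s' has no contours for time bin %d", name, t))
  contours <- s$contours[[tt]]

  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  # voxel-centre coordinates in the grid's local frame
  xs <- (seq_len(nx) - 1) * grid$spacing[1]
  ys <- (seq_len(ny) - 1) * grid$spacing[2]
  zs <- (seq_len(nz) - 1) * grid$spacing[3]
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)

  mask <- array(0, dim = grid$dims)
  covered <- rep(FALSE, nz)
  for (cn in contours) {
    # transform vertices (world) into the grid's local frame
    vw <- cbind(cn$vertices, cn$z)
    vl <- sweep(vw, 2, grid$origin) %*% grid$direction
    zl <- mean(vl[, 3])
    k <- which.min(abs(zs - zl))
    if (abs(zs[k] - zl) > grid$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour at z = %g mm is farther than half a slice from every slice centre", cn$z))
    inside <- points_in_polygon(px, py, vl[, 1:2, drop = FALSE])
    sl <- mask[, , k]
    sl <- as.numeric(xor(sl > 0.5, inside))  # even-odd across contours
    mask[, , k] <- sl
    covered[k] <- TRUE
  }
  if (!any(covered))
    stop(sprintf("structure '%s' produced no covered slices on this grid", name))
  bv <- binary_volume(grid, mask, name = name,
                      color = s$color %||% c(1, 0, 0, 1))
  if (crop) {
    k0 <- min(which(covered)); k1 <- max(which(covered))
    new_origin <- voxel_to_world(grid, c(0, 0, k0 - 1))
    g2 <- grid3d(new_origin, grid$spacing, c(nx, ny, k1 - k0 + 1L),
                 grid$direction)
    bv <- binary_volume(g2, mask[, , k0:k1, drop = FALSE], name = name,
                        color = s$color %||% c(1, 0, 0, 1))
  }
  bv
}

#' Majority vote over delineations
#'
#' Combines delineations of the same structure by independent observers: a
#' voxel is foreground iff at least `k` of the input masks mark it. The
#' conventional consensus for four observers is 3-of-4. `k = 1` is the
#' voxelwise union, `k = length(masks)` the intersection.
#'
#' @param masks list of `binary_volume`s on one common grid.
#' @param k minimum number of votes.
#' @param t time bin (1-based) used for multi-bin masks.
#' @return A `binary_volume` on the shared grid.
#' @export
majority_vote <- function(masks, k, t = 1L) {
  if (length(masks) < 1) stop("majority_vote needs >= 1 mask")
  if (k > length(masks))
    stop(sprintf("k = %d exceeds the number of masks (%d)", k, length(masks)))
  if (k < 1) stop("k must be >= 1")
  g <- masks[[1]]$grid
  for (m in masks)
    if (!same_grid(g, m$grid)) stop("majority_vote requires identical grids")
  votes <- Reduce(`+`, lapply(masks, function(m) get_frame(m, t)))
  binary_volume(g, array(as.numeric(votes >= k), dim = g$dims),
                name = sprintf("majority_%d_of_%d", k, length(masks)),
                color = masks[[1]]$color)
}
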