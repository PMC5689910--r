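#' Euclidean dilation of a delineation by a millimetre margin
#'
#' Expands a mask with an isotropic world-space margin: every voxel whose
#' centre lies within `margin` mm (Euclidean, anisotropic spacing respected)
#' of any input foreground voxel centre becomes foreground. `margin = 0` is
#' the identity. Used to build margin volumes around the proximal bronchial
#' tree and the mediastinum for central/peripheral classification.
#'
#' @param b a `binary_volume`.
#' @param margin margin in mm, >= 0.
#' @param t time bin (1-based).
#' @return A `binary_volume` on the same grid.
#' @export
dilate <- function(b, margin, t = 1L) {
  stopifnot(inherits(b, "binary_volume"))
  if (!is.numeric(margin) || length(margin) != 1 || margin < 0)
    stop("margin must be a single non-negative number of millimetres")
  fr <- get_frame(b, t)
  if (margin == 0)
    return(binary_volume(b$grid, fr, name = b$name, color = b$color))
  d <- distance_transform(fr, b$grid$spacing)
  out <- array(as.numeric(d <= margin + 1e-9), dim = b$grid$dims)
  binary_volume(b$grid, out,
                name = sprintf("%s+%gmm", b$name, margin), color = b$color)
}

#' Margin volume around a base structure
#'
#' @param base a `binary_volume` (e.g. bronchial tree or mediastinum mask).
#' @param margin margin in mm.
#' @return A `margin_volume`: list with `name`, `margin`, `mask`.
#' @export
margin_volume <- function(base, margin) {
  mask <- dilate(base, margin)
  structure(list(name = base$name, margin = margin, mask = mask),
            class = "margin_volume")
}

#' Intersection volume of two delineations
#'
#' Reports the overlap between a target and another mask in mm^3. The
#' second mask may live on a different grid: it is membership-tested
#' (nearest neighbour) at the first mask's voxel centres, and the first
#' mask's grid is the reporting grid.
#'
#' @param a reporting-grid `binary_volume`.
#' @param b `binary_volume` on any grid.
#' @param t time bin (1-based).
#' @return List with `volume_mm3` and `mask` (the intersection on `a`'s grid).
#' @export
intersection_volume <- function(a, b, t = 1L) {
  fa <- get_frame(a, t) > 0.5
  if (same_grid(a$grid, b$grid)) {
    inter <- fa & (get_frame(b, t) > 0.5)
  } else {
    centers <- grid_voxel_centers(a$grid)
    memb <- array(mask_contains(b, centers, t = t), dim = a$grid$dims)
    inter <- fa & memb
  }
  list(volume_mm3 = sum(inter) * grid_voxel_volume(a$grid),
       mask = binary_volume(a$grid, array(as.numeric(inter), dim = a$grid$dims),
                            name = paste0(a$name, "&", b$name),
                            color = a$color))
}

#' Classify tumour location as central or peripheral
#'
#' A lesion (ITV) is classified *central* iff it overlaps at least one
#' margin volume (bronchial tree / mediastinum expanded by their margins);
#' otherwise *peripheral*. Any positive overlap counts. Conventional margin
#' defaults in this package are 20 mm around the bronchial tree and 5 mm
#' around the mediastinum, both overridable.
#'
#' @param itv non-empty `binary_volume` of the target.
#' @param margins list of [margin_volume()]s.
#' @param t time bin (1-based).
#' @return List of class `location_report`: `location` (`"central"` /
#'   `"peripheral"`) and `overlaps`, a tibble with per-margin overlap mm^3.
#' @export
classify_location <- function(itv, margins, t = 1L) {
  stopifnot(inherits(itv, "binary_volume"))
  if (!any(get_frame(itv, t) > 0.5)) stop("empty ITV: nothing to classify")
  if (length(margins) < 1) stop("need >= 1 margin volume")
  rows <- lapply(margins, function(m) {
    iv <- intersection_volume(itv, m$mask, t = t)
    tibble::tibble(structure = m$name, margin_mm = m$margin,
                   overlap_mm3 = iv$volume_mm3)
  })
  overlaps <- tibble::as_tibble(do.call(rbind, rows))
  structure(list(
    location = if (any(overlaps$overlap_mm3 > 0)) "central" else "peripheral",
    overlaps = overlaps), class = "location_report")
}

#' @export
print.location_report <- function(x, ...) {
  cat(sprintf("<location_report> %s\n", x$location))
  print(x$overlaps)
  invisible(x)
}
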