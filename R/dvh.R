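#' Cumulative dose-volume histogram
#'
#' The fraction of a structure receiving at least each dose level. Mask
#' membership is evaluated at the dose grid's voxel centres (nearest
#' neighbour; the mask may live on a different grid — no resampling of the
#' dose). The curve is evaluated at bin edges `0, w, 2w, ...` up to the
#' maximum in-structure dose; `fraction(0) = 1` always.
#'
#' Voxel-centre membership means no partial-volume weighting; for very
#' small structures relative to the dose grid this is a known bias.
#'
#' @param dose a `dose_volume`.
#' @param mask a `binary_volume` (any grid).
#' @param bin_width_gy bin width in Gy (default 0.1).
#' @param t time bin for the mask (1-based).
#' @return A tibble of class `dvh_curve` with columns `dose_gy` and
#'   `fraction`; attributes `structure`, `volume_mm3`, `doses_gy` (the raw
#'   in-structure voxel doses).
#' @export
cumulative_dvh <- function(dose, mask, bin_width_gy = 0.1, t = 1L) {
  stopifnot(inherits(dose, "dose_volume"), inherits(mask, "binary_volume"))
  if (bin_width_gy <= 0) stop("bin width must be > 0 Gy")
  dvals <- get_frame(dose, 1L)
  if (same_grid(dose$grid, mask$grid)) {
    memb <- get_frame(mask, t) > 0.5
  } else {
    centers <- grid_voxel_centers(dose$grid)
    memb <- array(mask_contains(mask, centers, t = t), dim = dose$grid$dims)
  }
  doses <- dvals[memb]
  if (length(doses) == 0)
    stop("empty mask after mapping onto the dose grid")
  edges <- seq(0, max(doses) + bin_width_gy, by = bin_width_gy)
  frac <- vapply(edges, function(d) mean(doses >= d), 0)
  out <- tibble::tibble(dose_gy = edges, fraction = frac)
  class(out) <- c("dvh_curve", class(out))
  attr(out, "structure") <- mask$name
  attr(out, "volume_mm3") <- length(doses) * grid_voxel_volume(dose$grid)
  attr(out, "doses_gy") <- doses
  out
}

#' DVH summary statistics
#'
#' Computes `Dmin`, `Dmax`, `Dmean`, coverage fractions `V_x` (fraction of
#' the structure receiving >= x Gy) and dose levels `D_x%` (the smallest
#' evaluated dose received by at most x% of the structure).
#'
#' @param x a `dvh_curve` from [cumulative_dvh()], or a numeric vector of
#'   in-structure voxel doses (Gy).
#' @param v_gy dose levels x (Gy) for `V_x`.
#' @param d_pct volume percentages x for `D_x%`.
#' @return A named list: `d_min`, `d_max`, `d_mean`, `v` (named vector),
#'   `d` (named vector).
#' @export
dvh_stats <- function(x, v_gy = numeric(0), d_pct = numeric(0)) {
  doses <- if (inherits(x, "dvh_curve")) attr(x, "doses_gy") else as.numeric(x)
  if (length(doses) == 0) stop("empty dose sample")
  frac_ge <- function(d) mean(doses >= d)
  vx <- vapply(v_gy, frac_ge, 0)
  dx <- vapply(d_pct, function(pct) {
    cand <- sort(unique(doses))
    ok <- cand[vapply(cand, frac_ge, 0) <= pct / 100]
    if (length(ok)) min(ok) else max(doses)
  }, 0)
  nm_v <- if (length(v_gy)) paste0("V", v_gy, "Gy") else character(0)
  nm_d <- if (length(d_pct)) paste0("D", d_pct, "%") else character(0)
  list(d_min = min(doses), d_max = max(doses), d_mean = mean(doses),
       v = setNames(vx, nm_v), d = setNames(dx, nm_d))
}

#' Plot a DVH curve
#' @param object a `dvh_curve`.
#' @param ... further `dvh_curve`s to overlay.
#' @return A ggplot object.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  curves <- c(list(object), Filter(function(x) inherits(x, "dvh_curve"),
                                   list(...)))
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(structure = attr(cv, "structure") %||% "structure",
               dose_gy = cv$dose_gy, fraction = cv$fraction)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = 100 * .data$fraction,
                                   colour = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Write DVH curves to CSV
#'
#' Columns: `structure`, `dose_gy`, `fraction`.
#' @param curves a `dvh_curve` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(curves, path) {
  if (inherits(curves, "dvh_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(structure = attr(cv, "structure") %||% "structure",
               dose_gy = cv$dose_gy, fraction = cv$fraction)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
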