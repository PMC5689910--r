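#' Window/level intensity range
#'
#' The display window of an image source: values at or below `lower` map to
#' fully transparent, values at or above `upper` to the maximum opacity of
#' the coupled transfer function.
#'
#' @param lower,upper window bounds in source units (`lower < upper`).
#' @return An object of class `window_level`.
#' @export
window_level <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (!(lower < upper)) stop("window requires lower < upper")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "window_level")
}

#' Colour/opacity transfer function
#'
#' Maps voxel values to RGBA by piecewise-linear interpolation between
#' control points, with constant extrapolation beyond the first/last point.
#' All opacities are bounded by `cap`.
#'
#' @param values strictly increasing control-point values (source units).
#' @param colors n x 4 matrix of RGBA at the control points, channels in
#'   \[0,1\]; opacities must not exceed `cap`.
#' @param cap maximum opacity in \[0,1\].
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(values, colors, cap = 1) {
  values <- as.numeric(values)
  colors <- as.matrix(colors)
  stopifnot(ncol(colors) == 4, nrow(colors) == length(values))
  if (length(values) < 1) stop("transfer function needs >= 1 control point")
  if (is.unsorted(values, strictly = TRUE))
    stop("control-point values must be strictly increasing")
  if (!is.numeric(cap) || length(cap) != 1 || cap < 0 || cap > 1)
    stop("opacity cap must be a scalar in [0, 1]")
  if (any(colors < 0) || any(colors[, 1:3] > 1))
    stop("colour channels must lie in [0, 1]")
  if (any(colors[, 4] > cap + 1e-12))
    stop("opacities must not exceed the cap")
  structure(list(values = values, colors = colors, cap = cap),
            class = "transfer_function")
}

#' Evaluate a transfer function at voxel values
#' @param tf a [transfer_function()].
#' @param x numeric vector of voxel values.
#' @return n x 4 matrix of RGBA.
#' @export
tf_eval <- function(tf, x) {
  n <- length(x)
  out <- matrix(0, n, 4)
  if (length(tf$values) == 1L) {
    out[] <- rep(tf$colors[1, ], each = n)
    return(out)
  }
  for (ch in 1:4)
    out[, ch] <- approx(tf$values, tf$colors[, ch], xout = x, rule = 2)$y
  out
}

#' Windowing-coupled transfer function
#'
#' Builds the opacity ramp used for functional (PET) sources: fully
#' transparent at or below the lower window value, constant opacity `cap`
#' at or above the upper window value, and a linear ramp in between; the
#' colour is constant. The conventional default cap is 0.7.
#'
#' @param w a [window_level()].
#' @param cap maximum opacity in \[0,1\] (default 0.7).
#' @param color length-3 RGB in \[0,1\].
#' @return A [transfer_function()].
#' @examples
#' tf <- tf_from_window(window_level(2, 10), cap = 0.7, color = c(1, 0.5, 0))
#' tf_eval(tf, c(1, 6, 12))[, 4]  # 0, 0.35, 0.7
#' @export
tf_from_window <- function(w, cap = 0.7, color = c(1, 0.4, 0)) {
  stopifnot(inherits(w, "window_level"), length(color) == 3)
  if (!is.numeric(cap) || length(cap) != 1 || cap < 0 || cap > 1)
    stop("opacity cap must be a scalar in [0, 1]")
  transfer_function(values = c(w$lower, w$upper),
                    colors = rbind(c(color, 0), c(color, cap)),
                    cap = cap)
}
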