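#' Euclidean distance transform of a mask
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest
#' foreground voxel centre, respecting anisotropic spacing. Computed with a
#' separable exact squared-distance transform.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing numeric length-3 voxel spacing, mm.
#' @return Numeric 3D array of distances (`Inf` if the mask is empty).
#' @export
distance_transform <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3, length(spacing) == 3)
  .edt_cpp(as.logical(mask), as.integer(dim(mask)), as.numeric(spacing))
}

# Foreground voxels with at least one background 6-neighbour; the grid
# border counts as background.
surface_voxels <- function(m) {
  d <- dim(m)
  fg <- m > 0.5
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  fg & !nb
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two delineations on the same grid.
#' Comparing masks living on different grids requires the caller to
#' rasterize/map both onto the reference (planning) grid first — the
#' package never resamples silently.
#'
#' @param a,b `binary_volume`s on identical grids.
#' @param t time bin (1-based).
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b, t = 1L) {
  if (!same_grid(a$grid, b$grid))
    stop("dice requires masks on the same grid; rasterize both onto the reference grid first")
  fa <- get_frame(a, t) > 0.5
  fb <- get_frame(b, t) > 0.5
  na <- sum(fa); nb <- sum(fb)
  if (na + nb == 0) stop("both masks are empty: Dice is undefined")
  2 * sum(fa & fb) / (na + nb)
}

#' Directed surface distances between two masks
#'
#' Surface voxels are foreground voxels with at least one background
#' 6-neighbour (the grid border counts as background). Distances are
#' Euclidean millimetres between voxel centres, from each surface voxel of
#' one mask to the nearest surface voxel of the other.
#'
#' @param a,b `binary_volume`s on identical grids, both non-empty.
#' @param t time bin (1-based).
#' @return List with numeric vectors `a_to_b` and `b_to_a` (mm).
#' @export
surface_distances <- function(a, b, t = 1L) {
  if (!same_grid(a$grid, b$grid))
    stop("surface_distances requires masks on the same grid")
  fa <- get_frame(a, t); fb <- get_frame(b, t)
  if (!any(fa > 0.5) || !any(fb > 0.5))
    stop("surface distances need two non-empty masks")
  sa <- surface_voxels(fa); sb <- surface_voxels(fb)
  sp <- a$grid$spacing
  da <- distance_transform(sb, sp)  # distance to b's surface
  db <- distance_transform(sa, sp)  # distance to a's surface
  list(a_to_b = da[sa], b_to_a = db[sb])
}

#' Hausdorff distance statistics
#'
#' Maximum, average and 95th-percentile surface distances between two
#' delineations. The maximum is taken over both directed distance lists;
#' the average and the 95% value (linear-interpolation percentile) are
#' computed on the pooled, symmetrized list.
#'
#' @inheritParams surface_distances
#' @return List with `hd_max`, `hd_avg`, `hd_95` (mm).
#' @export
hausdorff_stats <- function(a, b, t = 1L) {
  sd <- surface_distances(a, b, t = t)
  pooled <- c(sd$a_to_b, sd$b_to_a)
  list(hd_max = max(pooled),
       hd_avg = mean(pooled),
       hd_95 = unname(quantile(pooled, 0.95, type = 7)))
}

#' Full contour-quality report
#'
#' Dice plus Hausdorff statistics and voxel counts for a test delineation
#' against a reference (e.g. the planning ITV), on the reference grid.
#'
#' @inheritParams surface_distances
#' @return A `metrics_report` (list) with fields `dice`, `hd_avg`, `hd_95`,
#'   `hd_max`, `n_voxels_a`, `n_voxels_b`, `grid`.
#' @export
assess_contours <- function(a, b, t = 1L) {
  d <- dice(a, b, t = t)
  h <- hausdorff_stats(a, b, t = t)
  structure(list(dice = d, hd_avg = h$hd_avg, hd_95 = h$hd_95,
                 hd_max = h$hd_max,
                 n_voxels_a = sum(get_frame(a, t) > 0.5),
                 n_voxels_b = sum(get_frame(b, t) > 0.5),
                 grid = a$grid),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Dice %.3f | HD avg %.2f mm, 95%% %.2f mm, max %.2f mm\n",
              x$dice, x$hd_avg, x$hd_95, x$hd_max))
  invisible(x)
}

#' Tidy a metrics report into a one-row tibble
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return A tibble with one row per report.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(dice = x$dice, hd_avg = x$hd_avg, hd_95 = x$hd_95,
                 hd_max = x$hd_max, n_voxels_test = x$n_voxels_a,
                 n_voxels_ref = x$n_voxels_b)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Inter-rater rating set
#'
#' Per-case integer quality ratings (1 = excellent ... 5 = poor) given by
#' two raters, with optional certainty flags.
#'
#' @param case case identifiers.
#' @param r1,r2 integer ratings in 1..5 for raters 1 and 2.
#' @param certain1,certain2 optional logical certainty flags.
#' @return A tibble of class `rating_set`.
#' @export
rating_set <- function(case, r1, r2, certain1 = NA, certain2 = NA) {
  if (length(case) < 1) stop("empty rating set")
  if (!all(r1 %in% 1:5) || !all(r2 %in% 1:5))
    stop("ratings must be integers in 1..5")
  out <- tibble::tibble(case = case, r1 = as.integer(r1), r2 = as.integer(r2),
                        certain1 = certain1, certain2 = certain2)
  class(out) <- c("rating_set", class(out))
  out
}

#' Conformity index of two raters
#'
#' The average absolute difference between the two raters' ratings over all
#' cases; 0 means perfect agreement, larger values more disagreement.
#'
#' @param r a [rating_set()].
#' @return Scalar >= 0.
#' @export
conformity_index <- function(r) {
  if (!inherits(r, "rating_set")) stop("expected a rating_set")
  if (nrow(r) < 1) stop("empty rating set")
  mean(abs(r$r1 - r$r2))
}

#' Acceptance decision from a quality rating
#'
#' A delineation or dose distribution is accepted iff its rating is at most
#' 3 ("acceptable") on the 1 (excellent) to 5 (poor) scale.
#'
#' @param rating integer vector of ratings in 1..5.
#' @return Logical vector.
#' @export
acceptance_decision <- function(rating) {
  if (!all(rating %in% 1:5)) stop("ratings must be integers in 1..5")
  rating <= 3
}

#' Batch contour assessment over a manifest
#'
#' Runs [assess_contours()] for every row of a manifest tibble/data frame
#' with columns `case`, `test` and `ref` (paths to NIfTI masks, all
#' comparable on the reference grid). If a [rating_set()] is supplied, a
#' summary of Dice/HD by accepted vs rejected cases (min/max/avg/SD) is
#' attached as attribute `"summary"`.
#'
#' @param manifest data frame with columns `case`, `test`, `ref`.
#' @param ratings optional [rating_set()] matched by `case`; the decision
#'   uses rater 1's rating.
#' @return A tibble with one row per case and the metric columns.
#' @export
assess_batch <- function(manifest, ratings = NULL) {
  stopifnot(all(c("case", "test", "ref") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    a <- read_mask(manifest$test[i])
    b <- read_mask(manifest$ref[i])
    cbind(tibble::tibble(case = manifest$case[i]), tidy(assess_contours(a, b)))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  if (!is.null(ratings)) {
    m <- match(out$case, ratings$case)
    out$rating <- ratings$r1[m]
    out$accepted <- acceptance_decision(out$rating)
    smry <- do.call(rbind, lapply(c(TRUE, FALSE), function(acc) {
      sub <- out[out$accepted == acc, ]
      if (nrow(sub) == 0) return(NULL)
      do.call(rbind, lapply(c("dice", "hd_avg", "hd_max", "hd_95"), function(mn) {
        v <- sub[[mn]]
        tibble::tibble(metric = mn, accepted = acc, min = min(v), max = max(v),
                       avg = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
      }))
    }))
    attr(out, "summary") <- tibble::as_tibble(smry)
  }
  out
}
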