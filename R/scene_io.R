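#' Read a scene and camera from a YAML/JSON config
#'
#' The config maps directly onto [scene()] and [camera()]. Volume paths are
#' resolved relative to the config file. Image layers give either an
#' explicit transfer function (`tf: {values: [...], colors: [[r,g,b,a],..],
#' cap: ...}`) or a windowing-coupled one (`window: {lower, upper}`, `cap`,
#' `color`). Surface layers reference a `mask` (NIfTI path, iso 0.5) or a
#' `dose` path with an `iso` value in Gy. An example:
#'
#' ```yaml
#' reference: planning_ct.nii.gz
#' time_bin: 3
#' roi: {low: [0, 0, 0.2], high: [1, 1, 0.8]}
#' image_layers:
#'   - volume: pet_4d/pet_manifest.json
#'     modality: PET
#'     weight: 1
#'     window: {lower: 1.5, upper: 4}
#'     cap: 0.7
#'     color: [1, 0.4, 0]
#' surface_layers:
#'   - mask: itv.nii.gz
#'   - dose: dose.nii.gz
#'     iso: 37.5
#' camera: {eye: [250, 0, 0], look_at: [0, 0, 0], fov: 35,
#'          width: 256, height: 256}
#' ```
#'
#' @param path YAML (or JSON) scene description.
#' @return List with elements `scene` and `camera`.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("no such scene file: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)

  load_any <- function(p, type = "scalar", ...) {
    p <- rel(p)
    if (grepl("\\.json$", p)) read_volume_4d(p, type = type, ...)
    else read_volume(p, type = type, ...)
  }

  reference <- load_any(cfg$reference, "scalar", modality = "CT")

  masks <- list()
  for (mn in names(cfg$masks %||% list()))
    masks[[mn]] <- load_any(cfg$masks[[mn]], "mask", name = mn)

  ilayers <- lapply(cfg$image_layers %||% list(), function(l) {
    vol <- load_any(l$volume, "scalar", modality = l$modality %||% "other")
    tf <- if (!is.null(l$tf)) {
      transfer_function(values = unlist(l$tf$values),
                        colors = do.call(rbind, lapply(l$tf$colors, unlist)),
                        cap = l$tf$cap %||% 1)
    } else if (!is.null(l$window)) {
      tf_from_window(window_level(l$window$lower, l$window$upper),
                     cap = l$cap %||% 0.7,
                     color = unlist(l$color %||% c(1, 0.4, 0)))
    } else stop("image layer needs either 'tf' or 'window'")
    image_layer(vol, tf, weight = l$weight %||% 1,
                enabled = l$enabled %||% TRUE,
                masks = unlist(l$masks %||% character(0)))
  })

  slayers <- lapply(cfg$surface_layers %||% list(), function(l) {
    if (!is.null(l$mask)) {
      src <- load_any(l$mask, "mask",
                      name = l$name %||% sub("\\.nii(\\.gz)?$", "", basename(l$mask)))
      surface_layer(src, iso = 0.5,
                    color = if (!is.null(l$color)) unlist(l$color),
                    shading = l$shading %||% TRUE)
    } else if (!is.null(l$dose)) {
      src <- read_volume(rel(l$dose), "dose")
      surface_layer(src, iso = l$iso,
                    color = if (!is.null(l$color)) unlist(l$color),
                    shading = l$shading %||% TRUE)
    } else stop("surface layer needs either 'mask' or 'dose'")
  })

  roi <- rbind(low = unlist(cfg$roi$low %||% c(0, 0, 0)),
               high = unlist(cfg$roi$high %||% c(1, 1, 1)))
  sc <- scene(reference, image_layers = ilayers, surface_layers = slayers,
              masks = masks, roi = roi,
              time_bin = cfg$time_bin %||% 1L,
              background = unlist(cfg$background %||% c(0, 0, 0)),
              light_dir = if (!is.null(cfg$light_dir)) unlist(cfg$light_dir),
              step_mm = cfg$step_mm)

  cc <- cfg$camera %||% stop("scene config needs a 'camera' block")
  cam <- camera(eye = unlist(cc$eye), look_at = unlist(cc$look_at),
                up = unlist(cc$up %||% c(0, 0, 1)), fov = cc$fov %||% 40,
                width = cc$width %||% 128, height = cc$height %||% 128,
                ortho = cc$ortho %||% FALSE,
                ortho_height = cc$ortho_height %||% 100)
  list(scene = sc, camera = cam)
}
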