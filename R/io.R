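#' Read and write volumes as NIfTI
#'
#' Single-frame volumes map to one `.nii`/`.nii.gz` file; the grid geometry
#' is carried in the sform/qform affine (0-based voxel index to world mm,
#' matching this package's voxel-centre convention). 4D volumes are written
#' as one file per time bin plus a JSON manifest listing the bin order.
#'
#' @param vol a volume object.
#' @param path output file path (3D) or manifest path (4D read).
#' @param type what to construct on read: `"scalar"`, `"mask"` or `"dose"`.
#' @param ... passed to the constructors (e.g. `modality`, `name`).
#' @return The path (writers, invisibly) or a volume object (readers).
#' @name nifti_io
NULL

grid_affine <- function(grid) {
  rbind(cbind(grid$direction %*% diag(grid$spacing), grid$origin),
        c(0, 0, 0, 1))
}

affine_to_grid <- function(aff, dims) {
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  direction <- sweep(m, 2, spacing, "/")
  grid3d(origin = aff[1:3, 4], spacing = spacing, dims = dims,
         direction = direction)
}

write_nifti_frame <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  aff <- structure(grid_affine(grid), code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
write_volume <- function(vol, path) {
  if (n_frames(vol) != 1L)
    stop("use write_volume_4d() for multi-bin volumes")
  write_nifti_frame(vol$frames[[1]], vol$grid, path)
}

#' @rdname nifti_io
#' @param dir output directory for the per-bin files.
#' @param prefix file-name prefix.
#' @export
write_volume_4d <- function(vol, dir, prefix = "bin") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n_frames(vol))
  for (b in seq_len(n_frames(vol))) {
    files[b] <- sprintf("%s_%03d.nii.gz", prefix, b)
    write_nifti_frame(vol$frames[[b]], vol$grid, file.path(dir, files[b]))
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(bins = files), manifest, auto_unbox = FALSE)
  invisible(manifest)
}

read_nifti_frame <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  arr <- array(as.numeric(img), dim = dim(img))
  list(arr = arr, grid = affine_to_grid(unclass(aff), dim(img)))
}

#' @rdname nifti_io
#' @export
read_volume <- function(path, type = c("scalar", "mask", "dose"), ...) {
  type <- match.arg(type)
  fr <- read_nifti_frame(path)
  switch(type,
         scalar = scalar_volume(fr$grid, fr$arr, ...),
         mask = binary_volume(fr$grid,
                              array(as.numeric(fr$arr > 0.5), dim = dim(fr$arr)),
                              ...),
         dose = dose_volume(fr$grid, pmax(fr$arr, 0)))
}

#' @rdname nifti_io
#' @export
read_mask <- function(path, ...) read_volume(path, type = "mask", ...)

#' @rdname nifti_io
#' @export
read_dose <- function(path) read_volume(path, type = "dose")

#' @rdname nifti_io
#' @param manifest_path path of a 4D bin manifest JSON.
#' @export
read_volume_4d <- function(manifest_path, type = c("scalar", "mask"), ...) {
  type <- match.arg(type)
  doc <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(doc$bins) || length(doc$bins) == 0)
    stop("4D manifest lists no bins: ", manifest_path)
  dir <- dirname(manifest_path)
  frames <- list()
  grid <- NULL
  for (f in doc$bins) {
    fr <- read_nifti_frame(file.path(dir, f))
    if (is.null(grid)) grid <- fr$grid
    else if (!same_grid(grid, fr$grid))
      stop("4D bins disagree on grid geometry")
    frames[[length(frames) + 1]] <- fr$arr
  }
  if (type == "mask")
    frames <- lapply(frames, function(a) array(as.numeric(a > 0.5), dim = dim(a)))
  switch(type,
         scalar = scalar_volume(grid, frames, ...),
         mask = binary_volume(grid, frames, ...))
}

#' Write a phantom bundle to disk
#'
#' Writes every source of a [make_phantom()] bundle: static volumes and
#' masks as NIfTI, 4D sources as per-bin NIfTI files with JSON manifests,
#' the structure set in the JSON contour dialect, and the ground-truth
#' manifest as `manifest.json`.
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$body_ct, file.path(dir, "body_ct.nii.gz"))
  write_volume(bundle$planning_ct, file.path(dir, "planning_ct.nii.gz"))
  write_volume_4d(bundle$ct_4d, file.path(dir, "ct_4d"), prefix = "ct")
  write_volume_4d(bundle$pet_4d, file.path(dir, "pet_4d"), prefix = "pet")
  for (nm in c("itv", "airway", "mediastinum"))
    write_volume(bundle[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  write_volume_4d(bundle$lesion_bins, file.path(dir, "lesion_4d"),
                  prefix = "lesion")
  write_volume(bundle$dose, file.path(dir, "dose.nii.gz"))
  write_structure_set(bundle$contours, file.path(dir, "contours.json"))
  man <- bundle$manifest
  man$centers <- apply(man$centers, 1, function(r) as.numeric(r),
                       simplify = FALSE)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
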