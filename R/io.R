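#' Read and write 3-D image volumes
#'
#' Supported formats, chosen by file extension:
#' \describe{
#'   \item{NIfTI-1 (`.nii`, `.nii.gz`)}{The canonical format: 32-bit-float
#'     round trips are bitwise lossless and the isotropic voxel size is
#'     carried in the header (written in micrometre units).}
#'   \item{multi-page TIFF (`.tif`, `.tiff`)}{One page per z slice. The
#'     underlying TIFF library stores floating-point samples faithfully
#'     only inside `[0, 1]`, so `write_volume` rescales intensities to
#'     that range and records the affine map together with the voxel size
#'     in a JSON sidecar (`<path>.json`), which `read_volume` applies
#'     transparently. Without a sidecar, the voxel size is taken from TIFF
#'     resolution tags when present, else from `voxel_size_um`.}
#' }
#' Axis order is normalized to the package convention `[iz, iy, ix]`.
#'
#' @param path file path ending in a supported extension.
#' @param voxel_size_um optional isotropic voxel-size override (µm); takes
#'   precedence over header metadata. Required when the file carries no
#'   voxel size. Anisotropic NIfTI headers are rejected unless overridden.
#' @return `read_volume` returns an [image_volume]; `write_volume`
#'   invisibly returns `path`.
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    read_volume_nifti(path, voxel_size_um)
  } else if (ext %in% c(".tif", ".tiff")) {
    read_volume_tiff(path, voxel_size_um)
  } else {
    stop("unknown volume format '", ext,
         "': supported formats are NIfTI-1 (.nii, .nii.gz) and ",
         "multi-page TIFF (.tif, .tiff)", call. = FALSE)
  }
}

#' @rdname read_volume
#' @param volume an [image_volume] to write.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_image_volume(volume))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    write_volume_nifti(volume, path)
  } else if (ext %in% c(".tif", ".tiff")) {
    write_volume_tiff(volume, path)
  } else {
    stop("unknown volume format '", ext,
         "': supported formats are NIfTI-1 (.nii, .nii.gz) and ",
         "multi-page TIFF (.tif, .tiff)", call. = FALSE)
  }
  invisible(path)
}

read_volume_nifti <- function(path, voxel_size_um) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3-D NIfTI volume", call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  un <- RNifti::pixunits(img)[1]
  scale <- switch(un, mm = 1000, um = 1, m = 1e6, 1) # unknown: treat as um
  pd_um <- pd * scale
  if (is.null(voxel_size_um)) {
    if (diff(range(pd_um)) > 1e-4 * max(pd_um))
      stop(sprintf(
        "anisotropic voxels (%.4g x %.4g x %.4g um): resample first or pass voxel_size_um",
        pd_um[1], pd_um[2], pd_um[3]), call. = FALSE)
    voxel_size_um <- pd_um[1]
  }
  image_volume(aperm(a, c(3, 2, 1)), voxel_size_um)
}

write_volume_nifti <- function(volume, path) {
  v <- volume$voxel_size_um
  img <- RNifti::asNifti(
    structure(aperm(volume$data, c(3, 2, 1)),
              pixdim = rep(v, 3), pixunits = c("um", "s")),
    datatype = "float")
  RNifti::writeNifti(img, path)
}

tiff_sidecar <- function(path) paste0(path, ".json")

write_volume_tiff <- function(volume, path) {
  a <- volume$data
  rng <- range(a)
  if (rng[2] > rng[1]) {
    slope <- rng[2] - rng[1]; intercept <- rng[1]
  } else {
    slope <- 1; intercept <- rng[1]
  }
  scaled <- (a - intercept) / slope
  pages <- lapply(seq_len(dim(a)[1]), function(iz)
    matrix(scaled[iz, , ], dim(a)[2], dim(a)[3]))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size_um,
         intensity_slope = slope, intensity_intercept = intercept),
    tiff_sidecar(path), auto_unbox = TRUE, digits = NA)
}

read_volume_tiff <- function(path, voxel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L)
    stop("multi-channel TIFF volumes are not supported", call. = FALSE)
  slope <- 1; intercept <- 0
  sc <- tiff_sidecar(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    slope <- meta$intensity_slope %||% 1
    intercept <- meta$intensity_intercept %||% 0
    if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
  }
  if (is.null(voxel_size_um)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && xres > 0) {
      per_um <- switch(ifelse(is.null(unit), "inch", unit),
                       inch = xres / 25400, cm = xres / 1e4, xres / 1e4)
      voxel_size_um <- 1 / per_um
    }
  }
  if (is.null(voxel_size_um))
    stop("TIFF carries no voxel size (no sidecar or resolution tags): ",
         "pass voxel_size_um", call. = FALSE)
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(0, d)
  for (iz in seq_len(d[1])) a[iz, , ] <- pages[[iz]]
  image_volume(a * slope + intercept, voxel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit-float NIfTI writer for derived maps where NaN encodes invalid
# voxels (helix-angle maps); image_volume itself requires finite data
write_float_nifti <- function(a, voxel_size_um, path) {
  img <- RNifti::asNifti(
    structure(aperm(array(as.numeric(a), dim(a)), c(3, 2, 1)),
              pixdim = rep(voxel_size_um, 3), pixunits = c("um", "s")),
    datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write label maps
#'
#' Label maps use the same formats as [read_volume()] but are stored as
#' unsigned 8-bit; labels must fit in 0–255.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param labels a [label_map] (or integer array with a `voxel_size_um`
#'   attribute).
#' @param voxel_size_um optional voxel-size override (µm).
#' @return `read_labels` returns a [label_map].
#' @export
read_labels <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    v <- read_volume_nifti(path, voxel_size_um)
    label_map(array(as.integer(round(v$data)), dim(v$data)), v$voxel_size_um)
  } else if (ext %in% c(".tif", ".tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sc <- tiff_sidecar(path)
    if (is.null(voxel_size_um) && file.exists(sc))
      voxel_size_um <- jsonlite::read_json(sc,
                                           simplifyVector = TRUE)$voxel_size_um
    if (is.null(voxel_size_um))
      stop("TIFF carries no voxel size: pass voxel_size_um", call. = FALSE)
    d <- c(length(pages), dim(pages[[1]]))
    a <- array(0L, d)
    for (iz in seq_len(d[1])) a[iz, , ] <- as.integer(pages[[iz]])
    label_map(a, voxel_size_um)
  } else {
    stop("unknown label-map format '", ext, "'", call. = FALSE)
  }
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  v <- vol_voxel(labels)
  a <- vol_data(labels)
  if (any(a < 0) || any(a > 255))
    stop("labels must fit in 0-255 for 8-bit storage", call. = FALSE)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(
      structure(aperm(array(as.integer(a), dim(a)), c(3, 2, 1)),
                pixdim = rep(v, 3), pixunits = c("um", "s")),
      datatype = "uint8")
    RNifti::writeNifti(img, path)
  } else if (ext %in% c(".tif", ".tiff")) {
    pages <- lapply(seq_len(dim(a)[1]), function(iz)
      matrix(a[iz, , ] / 255, dim(a)[2], dim(a)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    jsonlite::write_json(list(voxel_size_um = v, intensity_slope = 255,
                              intensity_intercept = 0),
                         tiff_sidecar(path), auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown label-map format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write an orientation field to disk
#'
#' Stores the three vector components as a 4-D 32-bit-float NIfTI volume
#' (last dimension = component `x, y, z`) and the validity mask as an
#' 8-bit companion (`<stem>_valid.nii[.gz]`).
#'
#' @param orientation an `orientation_field`.
#' @param path NIfTI path for the vector volume.
#' @export
write_orientation <- function(orientation, path) {
  stopifnot(inherits(orientation, "orientation_field"))
  vec <- aperm(orientation$vectors, c(3, 2, 1, 4))
  img <- RNifti::asNifti(
    structure(vec, pixdim = c(rep(orientation$voxel_size_um, 3), 1),
              pixunits = c("um", "s")),
    datatype = "float")
  RNifti::writeNifti(img, path)
  vpath <- sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)
  write_labels(label_map(array(as.integer(orientation$valid),
                               dim(orientation$valid)),
                         orientation$voxel_size_um), vpath)
  invisible(path)
}
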