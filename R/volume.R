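#' Image volume container
#'
#' A 3-D scalar intensity grid with isotropic voxel size in micrometres —
#' the substrate of every analysis in the package. The array is indexed
#' `[iz, iy, ix]`; see [myomap-package] for the coordinate conventions.
#'
#' @param data numeric 3-D array, dim `c(nz, ny, nx)`, all values finite.
#' @param voxel_size_um positive scalar, isotropic voxel edge length (µm).
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `voxel_size_um` and `axis_order` (fixed to `"zyx"`).
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)), voxel_size_um = 20)
#' dim(v$data)
#' @export
image_volume <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all three dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number", call. = FALSE)
  if (!all(is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         axis_order = "zyx"),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels (z, y, x), %.4g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

is_image_volume <- function(x) inherits(x, "image_volume")

# coerce an array-or-volume argument to a plain 3-D array
vol_data <- function(x) {
  if (is_image_volume(x)) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected an image_volume or a 3-D array", call. = FALSE)
}

vol_voxel <- function(x, voxel_size_um = NULL) {
  if (!is.null(voxel_size_um)) return(as.numeric(voxel_size_um))
  if (is_image_volume(x)) return(x$voxel_size_um)
  vs <- attr(x, "voxel_size_um")
  if (is.null(vs))
    stop("voxel size unknown: supply `voxel_size_um`", call. = FALSE)
  as.numeric(vs)
}

#' Label map container
#'
#' An integer 3-D array delineating tissue compartments (e.g. wall layers,
#' blood pool, background) on the same grid as an [image_volume].
#'
#' @param data integer-valued 3-D array of non-negative labels.
#' @param voxel_size_um isotropic voxel size (µm), stored as an attribute.
#' @return An integer array with class `label_map` and attribute
#'   `voxel_size_um`.
#' @export
label_map <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers", call. = FALSE)
  storage.mode(data) <- "integer"
  attr(data, "voxel_size_um") <- as.numeric(voxel_size_um)
  class(data) <- c("label_map", class(data))
  data
}

#' Add Gaussian noise to a volume
#'
#' Additive zero-mean Gaussian noise with standard deviation `sd`,
#' deterministic for a fixed `seed`. Used to set the signal-to-noise ratio
#' of phantom recovery experiments.
#'
#' @param volume an [image_volume].
#' @param sd noise standard deviation (intensity units), `>= 0`.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A new [image_volume] with noise added.
#' @export
add_noise <- function(volume, sd, seed) {
  stopifnot(is_image_volume(volume))
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("`sd` must be a single non-negative number", call. = FALSE)
  if (sd == 0) return(volume)
  out <- volume
  out$data <- volume$data + with_seed(seed, {
    array(rnorm(length(volume$data), mean = 0, sd = sd), dim(volume$data))
  })
  out
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
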