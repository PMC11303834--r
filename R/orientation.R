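#' Configuration of the structure-tensor orientation estimator
#'
#' The structure tensor at a voxel is the Gaussian-smoothed outer product
#' of the intensity gradient, `T = G_{sigma_s} * (grad I grad I^T)`, with
#' the gradient itself computed by Gaussian derivatives at scale
#' `sigma_g`. Its eigenvector with the smallest eigenvalue points along
#' the direction of least intensity change — the myocyte long axis, since
#' intensity is not expected to vary along it.
#'
#' The scales are expressed in voxels. `sigma_s > sigma_g` is needed for a
#' non-degenerate tensor; the defaults suit laminar textures with
#' wavelengths of roughly 4–12 voxels.
#'
#' @param sigma_g gradient (derivative) scale in voxels, `> 0`.
#' @param sigma_s tensor smoothing scale in voxels, `>= 0`.
#' @param eps_lambda relative degeneracy tolerance in `(0, 1)`: a voxel is
#'   flagged invalid when `(lambda2 - lambda3) / lambda1 < eps_lambda`,
#'   i.e. when the two smallest eigenvalues are too close to define a
#'   unique fiber direction.
#' @param mask optional logical array; voxels outside it are flagged
#'   invalid in the extracted orientation field.
#' @return A list of class `orientation_config`.
#' @export
orientation_config <- function(sigma_g = 1.0, sigma_s = 2.5,
                               eps_lambda = 0.05, mask = NULL) {
  stopifnot(sigma_g > 0, sigma_s >= 0)
  if (!(eps_lambda > 0 && eps_lambda < 1))
    stop("`eps_lambda` must lie in (0, 1)", call. = FALSE)
  structure(list(sigma_g = sigma_g, sigma_s = sigma_s,
                 eps_lambda = eps_lambda, mask = mask),
            class = "orientation_config")
}

# 1-D Gaussian kernel, order 0 (smoothing, unit sum) or 1 (derivative,
# normalized so the response to a unit-slope ramp is exactly 1)
gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0) return(g / sum(g))
  h <- x * g
  h / sum(x * h)
}

# separable Gaussian filtering of a 3-D array; per-axis derivative orders
gauss_filter3 <- function(a, sigma, orders = c(0, 0, 0)) {
  d <- dim(a)
  if (sigma == 0 && all(orders == 0)) return(a)
  for (ax in 1:3) {
    if (sigma == 0 && orders[ax] == 0) next
    a <- .conv3_axis(a, d, gauss_kernel(sigma, orders[ax]), ax)
  }
  array(a, d)
}

#' Compute the per-voxel structure tensor of a volume
#'
#' Intensity gradients are taken along the three orthogonal grid axes by
#' Gaussian derivatives at scale `sigma_g`; the outer-product components
#' are then smoothed with a Gaussian of scale `sigma_s`. All filtering
#' uses mirror-reflect boundary handling. Tensor components are stored in
#' world `(x, y, z)` component order.
#'
#' @param volume an [image_volume] with at least 8 voxels per axis.
#' @param config an [orientation_config()].
#' @return An object of class `structure_tensor_field`: list with `t` (the
#'   six unique components `xx, xy, xz, yy, yz, zz`, each a 3-D array),
#'   the scales used, `voxel_size_um`, and `all_constant` (TRUE when the
#'   input had no intensity variation at all — the tensors are then zero).
#' @export
compute_structure_tensor <- function(volume, config = orientation_config()) {
  stopifnot(is_image_volume(volume), inherits(config, "orientation_config"))
  d <- dim(volume$data)
  if (any(d < 8L))
    stop("volume must be at least 8 voxels along every axis", call. = FALSE)
  a <- volume$data
  all_constant <- (max(a) == min(a))
  if (all_constant)
    warning("volume has constant intensity: structure tensor is zero everywhere")

  sg <- config$sigma_g
  # array axes: 1 = z, 2 = y, 3 = x
  gx <- gauss_filter3(a, sg, orders = c(0, 0, 1)) / volume$voxel_size_um
  gy <- gauss_filter3(a, sg, orders = c(0, 1, 0)) / volume$voxel_size_um
  gz <- gauss_filter3(a, sg, orders = c(1, 0, 0)) / volume$voxel_size_um

  sm <- function(p) gauss_filter3(p, config$sigma_s)
  t6 <- list(xx = sm(gx * gx), xy = sm(gx * gy), xz = sm(gx * gz),
             yy = sm(gy * gy), yz = sm(gy * gz), zz = sm(gz * gz))
  structure(
    list(t = t6, sigma_g = sg, sigma_s = config$sigma_s,
         voxel_size_um = volume$voxel_size_um, dim = d,
         all_constant = all_constant),
    class = "structure_tensor_field"
  )
}

#' @export
print.structure_tensor_field <- function(x, ...) {
  cat(sprintf(
    "<structure_tensor_field> %d x %d x %d voxels, sigma_g = %g, sigma_s = %g\n",
    x$dim[1], x$dim[2], x$dim[3], x$sigma_g, x$sigma_s))
  invisible(x)
}

#' Extract per-voxel fiber directions from a structure-tensor field
#'
#' Eigendecomposes every tensor and selects the eigenvector of the
#' smallest eigenvalue as the fiber direction (intensity changes least
#' along the myocyte long axis). Eigenvalues are sorted descending
#' (`l1 >= l2 >= l3`). A voxel is flagged invalid when its tensor is
#' degenerate (`(l2 - l3)/l1 < eps_lambda`, or `l1 = 0`, or any component
#' non-finite), when it lies within `ceiling(3 * max(sigma_s, sigma_g))`
#' voxels of the volume border (filter support is incomplete there), or
#' when it falls outside the configured mask.
#'
#' The fiber direction is defined only up to sign; for storage it is
#' canonicalized so its largest-magnitude component is positive, and all
#' consumers in the package are sign-invariant.
#'
#' @param tensors a `structure_tensor_field` from
#'   [compute_structure_tensor()].
#' @param config an [orientation_config()] (degeneracy tolerance, mask).
#' @return An object of class `orientation_field`: list with `vectors`
#'   (array `c(nz, ny, nx, 3)`, unit `(x, y, z)` vectors, NaN where
#'   invalid), `eigenvalues` (list of arrays `l1, l2, l3`), `valid`
#'   (logical array) and `voxel_size_um`.
#' @export
extract_fiber_orientation <- function(tensors, config = orientation_config()) {
  stopifnot(inherits(tensors, "structure_tensor_field"))
  d <- tensors$dim
  tt <- tensors$t
  eig <- .eig3_smallest(tt$xx, tt$xy, tt$xz, tt$yy, tt$yz, tt$zz)
  l1 <- array(eig$l1, d); l2 <- array(eig$l2, d); l3 <- array(eig$l3, d)

  finite <- is.finite(l1) & is.finite(l2) & is.finite(l3)
  valid <- finite & (l1 > 0)
  sep <- array(FALSE, d)
  sep[valid] <- (l2[valid] - l3[valid]) / l1[valid] >= config$eps_lambda
  valid <- valid & sep

  margin <- as.integer(ceiling(3 * max(tensors$sigma_s, tensors$sigma_g)))
  if (margin > 0) {
    keep <- array(FALSE, d)
    i1 <- seq.int(margin + 1L, max(d[1] - margin, margin))
    i2 <- seq.int(margin + 1L, max(d[2] - margin, margin))
    i3 <- seq.int(margin + 1L, max(d[3] - margin, margin))
    if (d[1] > 2 * margin && d[2] > 2 * margin && d[3] > 2 * margin)
      keep[i1, i2, i3] <- TRUE
    valid <- valid & keep
  }
  if (!is.null(config$mask)) valid <- valid & config$mask

  vectors <- array(NaN, c(d, 3L))
  put <- function(comp) { a <- array(comp, d); a[!valid] <- NaN; a }
  vectors[, , , 1] <- put(eig$e3_1)
  vectors[, , , 2] <- put(eig$e3_2)
  vectors[, , , 3] <- put(eig$e3_3)

  structure(
    list(vectors = vectors, eigenvalues = list(l1 = l1, l2 = l2, l3 = l3),
         valid = valid, voxel_size_um = tensors$voxel_size_um),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$valid)
  cat(sprintf("<orientation_field> %d x %d x %d voxels, %d valid (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Estimate fiber orientation from a volume in one call
#'
#' Convenience wrapper: [compute_structure_tensor()] followed by
#' [extract_fiber_orientation()].
#'
#' @inheritParams compute_structure_tensor
#' @return An `orientation_field`.
#' @export
estimate_orientation <- function(volume, config = orientation_config()) {
  extract_fiber_orientation(compute_structure_tensor(volume, config), config)
}
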