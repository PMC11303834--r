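#' Left-ventricular centerline
#'
#' The centerline is the origin of the cylindrical coordinate system in
#' which helical angles are defined. [estimate_centerline()] fits it from
#' a mask (per-slice centroids + least-squares line); [centerline()]
#' builds one directly from a point and direction (e.g. read from file).
#'
#' @param origin point on the axis, `(x, y, z)` µm.
#' @param direction axis direction `(x, y, z)`; normalized internally and
#'   oriented with a non-negative z component (base-to-apex convention is
#'   up to the caller's data layout; flip `direction` to change the sign
#'   convention of the helix angle).
#' @param z_range_um optional validity range along the axis (µm).
#' @return An object of class `centerline`.
#' @export
centerline <- function(origin, direction, z_range_um = c(-Inf, Inf)) {
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("direction must be nonzero", call. = FALSE)
  direction <- direction / n
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction),
                 z_range_um = z_range_um, points = NULL),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> origin (%.1f, %.1f, %.1f) um, direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  if (!is.null(x$points))
    cat(sprintf("  fitted from %d slice centroids\n", nrow(x$points)))
  invisible(x)
}

#' Estimate the LV centerline from a mask
#'
#' Computes the centroid of the mask in every z slice (slices with no mask
#' voxels are skipped), then fits a least-squares straight line through
#' the centroids: `x(z)` and `y(z)` by ordinary regression on the slice
#' z coordinate. The mask is typically the blood-pool (lumen) label —
#' giving the lumen-weighted cavity centroid — or the wall annulus, whose
#' centroid coincides with the cavity center for closed annuli.
#'
#' @param mask logical 3-D array, or a [label_map] together with `label`.
#' @param voxel_size_um isotropic voxel size (µm); taken from the label
#'   map attribute when available.
#' @param label when `mask` is a label map, the label value to select.
#' @param min_slice_fraction slices whose mask area falls below this
#'   fraction of the median slice area are excluded from the fit: for a
#'   tilted chamber the end slices cut the cavity only partially and
#'   their centroids are biased off-axis.
#' @return A [centerline()] whose `points` element records the per-slice
#'   centroids used in the fit.
#' @export
estimate_centerline <- function(mask, voxel_size_um = NULL, label = NULL,
                                min_slice_fraction = 0.9) {
  v <- vol_voxel(mask, voxel_size_um)
  m <- vol_data(mask)
  if (!is.null(label)) m <- (m == label)
  m <- (m != 0)
  d <- dim(m)
  cz <- cx <- cy <- nvox <- numeric(0)
  for (iz in seq_len(d[1])) {
    sl <- m[iz, , ]
    n <- sum(sl)
    if (n == 0) next                       # empty slices are skipped
    idx <- which(sl, arr.ind = TRUE)       # (iy, ix)
    cz <- c(cz, (iz - 1) * v)
    cy <- c(cy, (mean(idx[, 1]) - 1) * v)
    cx <- c(cx, (mean(idx[, 2]) - 1) * v)
    nvox <- c(nvox, n)
  }
  keep <- nvox >= min_slice_fraction * median(nvox)
  if (sum(keep) >= 3L) {
    cz <- cz[keep]; cy <- cy[keep]; cx <- cx[keep]
  }
  if (length(cz) < 3L)
    stop(sprintf("mask present in only %d slice(s); need >= 3", length(cz)),
         call. = FALSE)
  fx <- lm(cx ~ cz); fy <- lm(cy ~ cz)
  z0 <- mean(cz)
  origin <- c(unname(coef(fx)[1] + coef(fx)[2] * z0),
              unname(coef(fy)[1] + coef(fy)[2] * z0), z0)
  dirn <- c(unname(coef(fx)[2]), unname(coef(fy)[2]), 1)
  cl <- centerline(origin, dirn, z_range_um = range(cz))
  cl$points <- data.frame(z_um = cz, x_um = cx, y_um = cy)
  cl
}

#' Local cylindrical frame at world-space points
#'
#' For each point, builds the right-handed orthonormal triad of the
#' cylindrical system centered on the centerline: longitudinal
#' `z_hat` = axis direction, radial `r_hat` = unit perpendicular from the
#' axis to the point, circumferential `c_hat = z_hat x r_hat` (so that
#' `r_hat x c_hat = z_hat`). Points closer to the axis than
#' `min_radius_um` get an undefined frame (flagged).
#'
#' @param points n x 3 matrix of `(x, y, z)` positions (µm).
#' @param cl a [centerline()].
#' @param min_radius_um exclusion radius around the axis (µm); typically
#'   one voxel.
#' @return A list with n x 3 matrices `r_hat`, `c_hat`, `z_hat` (rows NaN
#'   where undefined) and logical `valid`.
#' @export
local_cylindrical_frame <- function(points, cl, min_radius_um) {
  stopifnot(inherits(cl, "centerline"))
  points <- matrix(points, ncol = 3L)
  ax <- cl$direction
  dp <- sweep(points, 2, cl$origin)
  s <- drop(dp %*% ax)
  r <- dp - s %o% ax
  rho <- sqrt(rowSums(r^2))
  valid <- rho > min_radius_um
  r_hat <- r / rho
  c_hat <- cbind(ax[2] * r_hat[, 3] - ax[3] * r_hat[, 2],
                 ax[3] * r_hat[, 1] - ax[1] * r_hat[, 3],
                 ax[1] * r_hat[, 2] - ax[2] * r_hat[, 1])
  z_hat <- matrix(ax, nrow(points), 3, byrow = TRUE)
  r_hat[!valid, ] <- NaN
  c_hat[!valid, ] <- NaN
  z_hat[!valid, ] <- NaN
  list(r_hat = r_hat, c_hat = c_hat, z_hat = z_hat, valid = valid)
}

#' Per-voxel helical angle map
#'
#' Projects each fiber direction onto the local tangential plane (spanned
#' by the circumferential and longitudinal directions of the cylindrical
#' frame) and reports the angle of that projection from the transverse
#' plane: `alpha_h = atan2(longitudinal component, circumferential
#' component)` folded into `[-90, 90]` degrees so the result is invariant
#' under fiber sign flips. Positive angles mean the fiber climbs along
#' `+z_hat` while advancing in the `+c_hat` sense (a right-handed helix).
#'
#' Voxels are flagged invalid (NaN) when the orientation voxel is invalid,
#' outside the mask, within `min_radius_um` of the axis, or when the
#' tangential projection norm falls below `tangential_min` (near-radial
#' fibers have no meaningful helical angle).
#'
#' @param orientation an `orientation_field`.
#' @param cl a [centerline()].
#' @param mask optional logical array or [label_map] (nonzero = keep)
#'   restricting the map, typically the wall mask.
#' @param tangential_min minimum tangential projection norm in `[0, 1)`.
#' @param min_radius_um on-axis exclusion radius (µm); defaults to one
#'   voxel.
#' @return An object of class `helix_map`: the angle array (degrees, NaN
#'   where invalid) with attributes `voxel_size_um`.
#' @export
compute_helix_angle_map <- function(orientation, cl, mask = NULL,
                                    tangential_min = 0.2,
                                    min_radius_um = orientation$voxel_size_um) {
  stopifnot(inherits(orientation, "orientation_field"),
            inherits(cl, "centerline"))
  d <- dim(orientation$valid)
  keep <- orientation$valid
  if (!is.null(mask)) keep <- keep & (vol_data(mask) != 0)
  out <- array(NaN, d)
  idx <- which(keep)
  if (length(idx) == 0L) return(new_helix_map(out, orientation$voxel_size_um))

  ai <- arrayInd(idx, d)                        # (iz, iy, ix)
  v <- orientation$voxel_size_um
  pts <- cbind((ai[, 3] - 1) * v, (ai[, 2] - 1) * v, (ai[, 1] - 1) * v)
  fr <- local_cylindrical_frame(pts, cl, min_radius_um)

  n <- length(idx)
  vec <- cbind(orientation$vectors[idx],
               orientation$vectors[idx + prod(d)],
               orientation$vectors[idx + 2 * prod(d)])
  vc <- rowSums(vec * fr$c_hat)
  vz <- rowSums(vec * fr$z_hat)
  tang <- sqrt(vc^2 + vz^2)
  ok <- fr$valid & tang >= tangential_min
  # fold into [-90, 90]: flip the (sign-ambiguous) fiber so vc >= 0
  flip <- !is.na(vc) & vc < 0
  vc[flip] <- -vc[flip]; vz[flip] <- -vz[flip]
  ang <- atan2(vz, vc) * 180 / pi
  out[idx[ok]] <- ang[ok]
  new_helix_map(out, v)
}

new_helix_map <- function(a, voxel_size_um) {
  attr(a, "voxel_size_um") <- voxel_size_um
  class(a) <- c("helix_map", class(a))
  a
}

#' @export
print.helix_map <- function(x, ...) {
  d <- dim(x)
  n <- sum(!is.nan(x))
  cat(sprintf("<helix_map> %d x %d x %d voxels, %d valid (%.1f%%)\n",
              d[1], d[2], d[3], n, 100 * n / length(x)))
  if (n > 0)
    cat(sprintf("  angle range [%.1f, %.1f] deg, median %.1f deg\n",
                min(x, na.rm = TRUE), max(x, na.rm = TRUE),
                median(x, na.rm = TRUE)))
  invisible(x)
}

#' Mid-slice rendering of a helix-angle map
#'
#' Displays one z slice with a diverging colormap over `[-90, 90]`
#' degrees, the conventional presentation of transmural helix maps.
#'
#' @param x a `helix_map`.
#' @param slice z-slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.helix_map <- function(x, slice = NULL, ...) {
  d <- dim(x)
  if (is.null(slice)) slice <- (d[1] + 1L) %/% 2L
  sl <- t(x[slice, , ])           # x horizontal, y vertical
  image(z = sl, zlim = c(-90, 90),
        col = hcl.colors(91, "RdYlBu", rev = TRUE),
        xlab = "x", ylab = "y",
        main = sprintf("Helical angle, z slice %d (deg)", slice),
        useRaster = TRUE, ...)
  invisible(x)
}

#' Normalized transmural depth from compartment masks
#'
#' Depth at a wall voxel is `D_endo / (D_endo + D_epi)`, where `D_endo`
#' and `D_epi` are Euclidean distances to the nearest voxel of the
#' endocardial-side and epicardial-side compartments (e.g. lumen and
#' background). This two-distance normalization is well defined for
#' curved walls and reduces to linear depth in flat slabs: 0 on the
#' endocardial surface, 1 on the epicardial surface, monotone along
#' radial rays.
#'
#' @param wall logical array marking the wall.
#' @param inner logical array marking the endocardial-side compartment.
#' @param outer logical array marking the epicardial-side compartment.
#' @return Array of depths in `[0, 1]` (NaN outside the wall).
#' @export
transmural_depth <- function(wall, inner, outer) {
  d <- dim(wall)
  stopifnot(identical(d, dim(inner)), identical(d, dim(outer)))
  if (!any(inner) || !any(outer))
    stop("both the inner and outer compartments must be nonempty",
         call. = FALSE)
  de <- .edt3(as.logical(inner), d)
  dp <- .edt3(as.logical(outer), d)
  out <- array(NaN, d)
  out[wall] <- de[wall] / (de[wall] + dp[wall])
  out
}

#' Binned transmural helix-angle profile
#'
#' Averages the helix-angle map in equal-width transmural-depth bins —
#' the quantitative form of the endocardium-to-epicardium helix-angle
#' transition.
#'
#' @param helix a `helix_map`.
#' @param depth a depth array as from [transmural_depth()] (same grid).
#' @param n_bins number of equal-width depth bins.
#' @return A data frame with columns `depth_mid`, `mean_deg`,
#'   `median_deg`, `sd_deg`, `n`.
#' @export
transmural_profile <- function(helix, depth, n_bins = 10) {
  stopifnot(identical(dim(helix), dim(depth)), n_bins >= 2)
  ok <- !is.nan(unclass(helix)) & is.finite(depth)
  h <- helix[ok]; dd <- depth[ok]
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(dd, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  res <- data.frame(
    depth_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    mean_deg = NA_real_, median_deg = NA_real_, sd_deg = NA_real_,
    n = 0L
  )
  for (b in seq_len(n_bins)) {
    hb <- h[bin == b]
    res$n[b] <- length(hb)
    if (length(hb) > 0) {
      res$mean_deg[b] <- mean(hb)
      res$median_deg[b] <- median(hb)
      res$sd_deg[b] <- sd(hb)
    }
  }
  res
}
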