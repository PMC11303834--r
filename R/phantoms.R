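#' Specification of a left-ventricle-like annular phantom
#'
#' Describes a cylindrical-annulus wall ("LV wall") with a fiber texture
#' following a prescribed linear transmural helix-angle law
#' `alpha(d) = alpha_endo + (alpha_epi - alpha_endo) * d`, where `d` is the
#' normalized transmural depth (0 at the endocardium, 1 at the epicardium).
#' The texture is built from sinusoidal laminae whose intensity is constant
#' along the local fiber direction, matching the premise of structure-tensor
#' fiber estimation: intensity does not vary along the myocyte long axis.
#'
#' @param shape integer length-3, grid size `c(nz, ny, nx)` in voxels.
#' @param voxel_size_um isotropic voxel size (µm).
#' @param inner_radius_um,outer_radius_um endocardial and epicardial radii
#'   (µm); `0 < inner < outer` and the wall must be at least 3 voxels thick.
#' @param height_um axial extent of the annulus (µm), centered on the axis
#'   position; `Inf` spans the whole grid.
#' @param center world-space point on the axis `(x, y, z)` in µm; default is
#'   the grid center.
#' @param axis axis direction `(x, y, z)`; default `+z`.
#' @param alpha_endo_deg,alpha_epi_deg helix angles at the endocardial and
#'   epicardial surfaces, each in `[-90, 90]` degrees.
#' @param wavelength_um texture wavelength (µm); must be at least 2 voxels
#'   (Nyquist).
#' @param wall_level,lumen_level,background_level mean intensities of the
#'   three compartments (arbitrary units).
#' @param texture_amplitude peak amplitude of the laminar texture added to
#'   `wall_level`.
#' @param shell_width_voxels radial coherence length of the helical
#'   laminae, in voxels. The helix phase is frozen over radial shells of
#'   this width (see [generate_lv_phantom()]); wider shells are more
#'   coherent under the orientation estimator's smoothing scales but
#'   quantize the helix law more coarsely across the wall.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none).
#' @param seed integer seed controlling texture phases and noise.
#' @return A list of class `lv_phantom_spec`.
#' @seealso [generate_lv_phantom()]
#' @export
lv_phantom_spec <- function(shape = c(128, 128, 128),
                            voxel_size_um = 20,
                            inner_radius_um = 30 * voxel_size_um,
                            outer_radius_um = 55 * voxel_size_um,
                            height_um = Inf,
                            center = NULL,
                            axis = c(0, 0, 1),
                            alpha_endo_deg = 60,
                            alpha_epi_deg = -60,
                            wavelength_um = 8 * voxel_size_um,
                            wall_level = 100,
                            lumen_level = 40,
                            background_level = 0,
                            texture_amplitude = 50,
                            shell_width_voxels = 2,
                            noise_sd = 0,
                            seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_size_um > 0)
  if (!(inner_radius_um > 0 && inner_radius_um < outer_radius_um))
    stop("need 0 < inner_radius_um < outer_radius_um", call. = FALSE)
  if ((outer_radius_um - inner_radius_um) / voxel_size_um < 3)
    stop("wall thinner than 3 voxels", call. = FALSE)
  if (abs(alpha_endo_deg) > 90 || abs(alpha_epi_deg) > 90)
    stop("helix angles must lie in [-90, 90] degrees", call. = FALSE)
  if (wavelength_um < 2 * voxel_size_um)
    stop("texture wavelength under 2 voxels would alias", call. = FALSE)
  if (is.null(center))
    center <- c((shape[3] - 1) / 2, (shape[2] - 1) / 2,
                (shape[1] - 1) / 2) * voxel_size_um
  axis <- axis / sqrt(sum(axis^2))
  structure(
    list(shape = shape, voxel_size_um = voxel_size_um,
         inner_radius_um = inner_radius_um, outer_radius_um = outer_radius_um,
         height_um = height_um, center = center, axis = axis,
         alpha_endo_deg = alpha_endo_deg, alpha_epi_deg = alpha_epi_deg,
         wavelength_um = wavelength_um, wall_level = wall_level,
         lumen_level = lumen_level, background_level = background_level,
         texture_amplitude = texture_amplitude,
         shell_width_voxels = shell_width_voxels, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "lv_phantom_spec"
  )
}

# world-coordinate grids (µm) for a zyx-shaped grid; returns list X, Y, Z
coordinate_grids <- function(shape, voxel_size_um) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  xs <- (seq_len(nx) - 1) * voxel_size_um
  ys <- (seq_len(ny) - 1) * voxel_size_um
  zs <- (seq_len(nz) - 1) * voxel_size_um
  list(
    X = array(rep(xs, each = nz * ny), shape),
    Y = array(rep(rep(ys, each = nz), times = nx), shape),
    Z = array(rep(zs, times = ny * nx), shape)
  )
}

# two unit vectors spanning the plane orthogonal to unit vector `ax`
orthobasis <- function(ax) {
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * ax) * ax
  u <- u / sqrt(sum(u^2))
  v <- c(ax[2] * u[3] - ax[3] * u[2],   # v = ax x u, so (u, v, ax) is
         ax[3] * u[1] - ax[1] * u[3],   # right-handed: u x v = ax
         ax[1] * u[2] - ax[2] * u[1])
  list(u = u, v = v)
}

#' Generate the annular left-ventricle phantom
#'
#' Builds the image volume, compartment label map, and per-voxel ground
#' truth (fiber direction, wall mask, normalized transmural depth) from an
#' [lv_phantom_spec()]. The wall texture is the sum of two sinusoidal
#' laminar systems whose gradients are everywhere orthogonal to the local
#' fiber direction: radial laminae, plus helical laminae with phase
#' `-sin(alpha) * rho * theta + cos(alpha) * z` in cylindrical coordinates
#' (the directional derivative of that phase along the fiber is identically
#' zero). The helical phase is discontinuous across one azimuthal
#' half-plane (the branch cut of `theta`); voxels on that thin sheet carry
#' a corrupted texture, which median-based recovery statistics tolerate.
#'
#' @param spec an [lv_phantom_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{volume}{[image_volume] with texture and noise.}
#'     \item{labels}{[label_map]: 0 background, 1 lumen, 2 wall.}
#'     \item{truth}{list with `vectors` (array `c(nz, ny, nx, 3)` of unit
#'       fiber directions in `(x, y, z)` components, NaN outside the wall),
#'       `mask` (logical wall mask), `depth` (normalized transmural depth,
#'       NaN outside) and `alpha_deg` (prescribed helix angle, NaN outside).}
#'   }
#' @export
generate_lv_phantom <- function(spec) {
  stopifnot(inherits(spec, "lv_phantom_spec"))
  sh <- spec$shape; v <- spec$voxel_size_um
  g <- coordinate_grids(sh, v)
  az <- spec$axis
  dx <- g$X - spec$center[1]; dy <- g$Y - spec$center[2]
  dz <- g$Z - spec$center[3]
  s <- dx * az[1] + dy * az[2] + dz * az[3]      # axial coordinate
  rx <- dx - s * az[1]; ry <- dy - s * az[2]; rz <- dz - s * az[3]
  rho <- sqrt(rx^2 + ry^2 + rz^2)

  in_height <- abs(s) <= spec$height_um / 2
  wall <- rho >= spec$inner_radius_um & rho <= spec$outer_radius_um & in_height
  lumen <- rho < spec$inner_radius_um & in_height

  labels <- array(0L, sh)
  labels[lumen] <- 1L
  labels[wall] <- 2L

  d <- (rho - spec$inner_radius_um) /
    (spec$outer_radius_um - spec$inner_radius_um)
  alpha <- (spec$alpha_endo_deg +
              (spec$alpha_epi_deg - spec$alpha_endo_deg) * d) * pi / 180

  # local frame on wall voxels (all arrays; rho > 0 on the wall)
  rhatx <- rx / rho; rhaty <- ry / rho; rhatz <- rz / rho
  chatx <- az[2] * rhatz - az[3] * rhaty        # c = z_axis x r_hat
  chaty <- az[3] * rhatx - az[1] * rhatz
  chatz <- az[1] * rhaty - az[2] * rhatx
  fx <- cos(alpha) * chatx + sin(alpha) * az[1]
  fy <- cos(alpha) * chaty + sin(alpha) * az[2]
  fz <- cos(alpha) * chatz + sin(alpha) * az[3]

  ob <- orthobasis(az)
  theta <- atan2(rx * ob$v[1] + ry * ob$v[2] + rz * ob$v[3],
                 rx * ob$u[1] + ry * ob$u[2] + rz * ob$u[3])

  # Helical laminae, frozen per radial shell: within a shell the phase
  # -sin(a)*rho_mid*theta + cos(a)*z has gradient
  # -sin(a)*(rho_mid/rho)*c_hat + cos(a)*z_hat — bounded, and orthogonal
  # to the shell's fiber direction to O(|rho - rho_mid| / rho). Phase
  # jumps between shells lie on rho = const surfaces, so they only add
  # radial gradient energy, which is also orthogonal to the fiber.
  sw <- spec$shell_width_voxels * v
  shell <- pmax(floor(rho / sw), 0)
  nsh <- max(shell) + 1L
  phases <- with_seed(spec$seed, stats::runif(nsh + 1L, 0, 2 * pi))
  rho_mid <- (shell + 0.5) * sw
  d_sh <- pmin(pmax((rho_mid - spec$inner_radius_um) /
                      (spec$outer_radius_um - spec$inner_radius_um), 0), 1)
  alpha_sh <- (spec$alpha_endo_deg +
                 (spec$alpha_epi_deg - spec$alpha_endo_deg) * d_sh) * pi / 180
  lam <- spec$wavelength_um
  phi_helical <- -sin(alpha_sh) * rho_mid * theta + cos(alpha_sh) * s
  tex <- 0.5 * spec$texture_amplitude *
    (cos(2 * pi * phi_helical / lam + phases[shell + 1L]) +
       cos(2 * pi * rho / lam + phases[nsh + 1L]))

  data <- array(spec$background_level, sh)
  data[lumen] <- spec$lumen_level
  data[wall] <- spec$wall_level + tex[wall]
  vol <- image_volume(data, v)
  if (spec$noise_sd > 0)
    vol <- add_noise(vol, spec$noise_sd, seed = spec$seed + 1L)

  vectors <- array(NaN, c(sh, 3L))
  vsel <- function(comp) { a <- array(NaN, sh); a[wall] <- comp[wall]; a }
  vectors[, , , 1] <- vsel(fx)
  vectors[, , , 2] <- vsel(fy)
  vectors[, , , 3] <- vsel(fz)
  depth <- array(NaN, sh); depth[wall] <- d[wall]
  alpha_deg <- array(NaN, sh); alpha_deg[wall] <- alpha[wall] * 180 / pi

  list(
    volume = vol,
    labels = label_map(labels, v),
    truth = list(vectors = vectors, mask = wall, depth = depth,
                 alpha_deg = alpha_deg)
  )
}

#' Specification of a layered wall slab phantom
#'
#' A three-sublayer wall (endocardium, myocardium, epicardium) stacked
#' along a normal direction, optionally bent into a cylindrical shell —
#' the fixture for wall-thickness morphometry.
#'
#' @param shape grid size `c(nz, ny, nx)` in voxels.
#' @param voxel_size_um isotropic voxel size (µm).
#' @param thickness_um length-3 positive vector: endocardial, myocardial,
#'   epicardial thickness (µm); each layer must span at least 2 voxels.
#' @param levels length-3 intensity per layer; `background_level` elsewhere.
#' @param curvature_radius_um radius (µm) of the endocardial surface when
#'   the wall is a cylindrical shell bent about a z-parallel line through
#'   the grid center; `Inf` gives a flat slab.
#' @param normal unit normal `(x, y, z)` of a flat slab (ignored when
#'   curved); layers stack from endocardium outward along it.
#' @param background_level intensity outside the wall.
#' @param noise_sd additive Gaussian noise sd (0 = none).
#' @param seed integer seed for the noise.
#' @return A list of class `wall_slab_spec`.
#' @export
wall_slab_spec <- function(shape = c(48, 48, 160),
                           voxel_size_um = 20,
                           thickness_um = c(200, 2000, 400),
                           levels = c(120, 80, 150),
                           curvature_radius_um = Inf,
                           normal = c(1, 0, 0),
                           background_level = 0,
                           noise_sd = 0,
                           seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_size_um > 0,
            length(thickness_um) == 3L, length(levels) == 3L)
  if (any(thickness_um <= 0))
    stop("all sublayer thicknesses must be > 0", call. = FALSE)
  if (any(thickness_um / voxel_size_um < 2))
    stop("every sublayer must span at least 2 voxels", call. = FALSE)
  if (is.finite(curvature_radius_um) && curvature_radius_um <= 0)
    stop("curvature radius must be positive or Inf", call. = FALSE)
  normal <- normal / sqrt(sum(normal^2))
  structure(
    list(shape = shape, voxel_size_um = voxel_size_um,
         thickness_um = as.numeric(thickness_um), levels = as.numeric(levels),
         curvature_radius_um = curvature_radius_um, normal = normal,
         background_level = background_level, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "wall_slab_spec"
  )
}

#' Generate the layered wall slab phantom
#'
#' Labels voxels by the signed distance `s` from the endocardial surface:
#' layer k occupies `s` in `[b_{k-1}, b_k)` with boundaries at cumulative
#' thicknesses. For a flat axis-aligned slab with layer thicknesses that
#' are whole multiples of the voxel size, boundaries are snapped to
#' half-voxel positions so label runs along the normal are exact.
#'
#' @param spec a [wall_slab_spec()].
#' @return A list with `volume` ([image_volume]), `labels` ([label_map];
#'   0 background, 1 endocardium, 2 myocardium, 3 epicardium) and
#'   `geometry` (list describing the analytic layer surfaces: `type`,
#'   `normal` or `center`, and boundary offsets `boundaries_um`).
#' @export
generate_wall_slab <- function(spec) {
  stopifnot(inherits(spec, "wall_slab_spec"))
  sh <- spec$shape; v <- spec$voxel_size_um
  g <- coordinate_grids(sh, v)
  total <- sum(spec$thickness_um)

  if (is.finite(spec$curvature_radius_um)) {
    cx <- (sh[3] - 1) / 2 * v; cy <- (sh[2] - 1) / 2 * v
    R0 <- spec$curvature_radius_um
    s <- sqrt((g$X - cx)^2 + (g$Y - cy)^2) - R0
    geom <- list(type = "shell", center = c(cx, cy),
                 inner_radius_um = R0)
  } else {
    n <- spec$normal
    ctr <- c((sh[3] - 1) / 2, (sh[2] - 1) / 2, (sh[1] - 1) / 2) * v
    s0 <- sum(ctr * n) - total / 2
    if (sum(abs(n) > 1e-12) == 1L) # axis-aligned: snap to half-voxel grid
      s0 <- (floor(s0 / v) + 0.5) * v
    s <- (g$X * n[1] + g$Y * n[2] + g$Z * n[3]) - s0
    geom <- list(type = "flat", normal = n, origin_offset_um = s0)
  }
  b <- cumsum(spec$thickness_um)
  geom$boundaries_um <- c(0, b)

  labels <- array(0L, sh)
  labels[s >= 0 & s < b[1]] <- 1L
  labels[s >= b[1] & s < b[2]] <- 2L
  labels[s >= b[2] & s < b[3]] <- 3L

  data <- array(spec$background_level, sh)
  for (k in 1:3) data[labels == k] <- spec$levels[k]
  vol <- image_volume(data, v)
  if (spec$noise_sd > 0) vol <- add_noise(vol, spec$noise_sd, spec$seed)

  list(volume = vol, labels = label_map(labels, v), geometry = geom)
}

#' Specification of a mitral-annular-disjunction landmark phantom
#'
#' A pair of landmark curves around an annulus: the "crest" of the
#' ventricular myocardium on a circle about the annular axis, and the
#' valve "hinge" displaced from it along the axis by a prescribed
#' per-angle disjunction function.
#'
#' @param center annulus center `(x, y, z)` (µm).
#' @param axis annular axis direction `(x, y, z)`.
#' @param radius_um annulus radius (µm).
#' @param arc_span_deg arc covered by the mural leaflet, in `(0, 360]`.
#' @param displacement either a single non-negative number (µm) or a
#'   function of angle (degrees, measured from `start_angle_deg`) returning
#'   the axial disjunction in µm; must be `>= 0` everywhere sampled.
#' @param start_angle_deg angular origin of the arc (degrees).
#' @param step_deg sampling resolution of the generated curves (degrees);
#'   the default 1 makes any 5-degree analysis grid a sub-sampling.
#' @return A list of class `mad_phantom_spec`.
#' @export
mad_phantom_spec <- function(center = c(0, 0, 0),
                             axis = c(0, 0, 1),
                             radius_um = 15000,
                             arc_span_deg = 180,
                             displacement = 0,
                             start_angle_deg = 0,
                             step_deg = 1) {
  if (!(arc_span_deg > 0 && arc_span_deg <= 360))
    stop("arc span must lie in (0, 360] degrees", call. = FALSE)
  stopifnot(radius_um > 0, step_deg > 0)
  dispfun <- if (is.function(displacement)) displacement
             else function(theta_deg) rep(displacement, length(theta_deg))
  structure(
    list(center = center, axis = axis / sqrt(sum(axis^2)),
         radius_um = radius_um, arc_span_deg = arc_span_deg,
         displacement = dispfun, start_angle_deg = start_angle_deg,
         step_deg = step_deg),
    class = "mad_phantom_spec"
  )
}

#' Generate hinge and crest landmark curves with known disjunction
#'
#' @param spec a [mad_phantom_spec()].
#' @return A list with `hinge` and `crest`, each a [landmark_curve];
#'   hinge points sit `displacement(theta)` µm along the axis from the
#'   crest point at the same angle.
#' @export
generate_mad_phantom <- function(spec) {
  stopifnot(inherits(spec, "mad_phantom_spec"))
  theta_rel <- seq(0, spec$arc_span_deg, by = spec$step_deg)
  disp <- spec$displacement(theta_rel)
  if (length(disp) != length(theta_rel))
    disp <- vapply(theta_rel, spec$displacement, numeric(1))
  if (any(!is.finite(disp)) || any(disp < 0))
    stop("displacement must be finite and >= 0 over the arc", call. = FALSE)

  ob <- orthobasis(spec$axis)
  th <- (spec$start_angle_deg + theta_rel) * pi / 180
  crest_pts <- spec$radius_um *
    (cos(th) %o% ob$u + sin(th) %o% ob$v)
  crest_pts <- sweep(crest_pts, 2, spec$center, "+")
  hinge_pts <- crest_pts + disp %o% spec$axis

  ang <- spec$start_angle_deg + theta_rel
  list(
    hinge = landmark_curve(hinge_pts[, 1], hinge_pts[, 2], hinge_pts[, 3],
                           angle_deg = ang),
    crest = landmark_curve(crest_pts[, 1], crest_pts[, 2], crest_pts[, 3],
                           angle_deg = ang)
  )
}
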